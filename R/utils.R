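# Internal helpers shared across modules.

#' Evaluate an expression under a local, seeded RNG
#'
#' Saves and restores the caller's RNG state so that seeded package functions
#' never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed from a base seed plus string labels. Used to split
# one dataset-level stream hierarchically by (species, kit, replicate) so that
# appending a kit or species never perturbs draws for the existing ones.
derive_seed <- function(seed, ...) {
  parts <- paste(c(format(as.integer(seed)), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147480707
  as.integer(h)
}

# A scalar finite number?
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# A single non-NA character string?
is_label <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

stop_if_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

# The six taxonomic ranks carried by every taxonomy table, in order.
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

# Reserved species label for negative extraction controls.
CONTROL_SPECIES <- "control"

# Valid PCR dilution-factor tokens.
DILUTION_LEVELS <- c("1", "10", "100", "failed")
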