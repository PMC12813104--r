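# QC-criterion derivation and the four kit-ranking rules, plus aggregation
# into Total and Quality ranks. All rules use the minimum-rank tie
# convention with skipping (1, 1, 3): tied kits share the best rank of the
# tied block and the next kit resumes after it, so summed ranks stay
# comparable across criteria.

#' DNA yield per gram of input material
#'
#' `yield = concentration * elution_volume / input_mass` (ng/g). The
#' concentration is floored at the 0.1 ng/uL fluorometric detection limit
#' before use.
#'
#' @param conc DNA concentration, ng/uL (vectorised).
#' @param elution_volume elution volume in uL (default 60).
#' @param input_mass input material mass in g, must be positive.
#' @return yield in ng per gram of input.
#' @examples
#' yield_per_gram(10, input_mass = 1)  # 600
#' @export
yield_per_gram <- function(conc, elution_volume = 60, input_mass) {
  if (any(!is.finite(input_mass)) || any(input_mass <= 0)) {
    stop("`input_mass` must be positive", call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("`conc` must be non-negative", call. = FALSE)
  }
  pmax(conc, 0.1) * elution_volume / input_mass
}

#' Absorbance-ratio purity flags
#'
#' A DNA extract counts as pure when the 260/230 ratio lies in `[2.0, 2.2]`
#' (organic impurities) and the 260/280 ratio in `[1.7, 2.0]` (protein
#' contamination), bounds inclusive.
#'
#' @param a260_280,a260_230 absorbance ratios (vectorised, positive).
#' @return data.frame with logical columns `a260_280_ok`, `a260_230_ok`,
#'   `pure`.
#' @export
purity_flags <- function(a260_280, a260_230) {
  if (any(a260_280 <= 0, na.rm = TRUE) || any(a260_230 <= 0, na.rm = TRUE)) {
    stop("absorbance ratios must be positive", call. = FALSE)
  }
  ok280 <- a260_280 >= 1.7 & a260_280 <= 2.0
  ok230 <- a260_230 >= 2.0 & a260_230 <= 2.2
  data.frame(a260_280_ok = ok280, a260_230_ok = ok230,
             pure = ok280 & ok230)
}

mean_of <- function(x) mean(x, na.rm = TRUE)

#' Rank kits by their mean value
#'
#' Rank 1 goes to the kit with the best mean: the highest mean when
#' `higher_is_better`, the lowest otherwise. Ties share the minimum rank and
#' subsequent ranks skip. Kits whose values are entirely missing either
#' raise an error (default) or, with `missing = "worst"`, are excluded from
#' the comparison and assigned one rank below the worst measured kit -- the
#' treatment used for kits on which a QC assay fails outright.
#'
#' @param values named list of per-replicate numeric vectors (or a named
#'   numeric vector of scalars), one entry per kit.
#' @param higher_is_better logical.
#' @param missing `"error"` or `"worst"`.
#' @return named integer rank vector; if any ranks were imputed, they are
#'   listed in the `"imputed"` attribute.
#' @examples
#' rank_by_mean(c(a = 5, b = 5, c = 3))  # a=1, b=1, c=3
#' @export
rank_by_mean <- function(values, higher_is_better = TRUE,
                         missing = c("error", "worst")) {
  missing <- match.arg(missing)
  values <- as_value_list(values)
  means <- vapply(values, mean_of, 0)
  absent <- !is.finite(means)
  if (any(absent) && missing == "error") {
    stop("no values for kit(s): ",
         paste(names(values)[absent], collapse = ", "), call. = FALSE)
  }
  ranks <- stats::setNames(rep(NA_integer_, length(values)), names(values))
  measured <- means[!absent]
  if (length(measured)) {
    key <- if (higher_is_better) -measured else measured
    ranks[names(measured)] <- as.integer(rank(key, ties.method = "min"))
  }
  if (any(absent)) {
    worst <- if (length(measured)) max(ranks, na.rm = TRUE) else 0L
    ranks[absent] <- worst + 1L
    attr(ranks, "imputed") <- names(values)[absent]
  }
  ranks
}

as_value_list <- function(values) {
  if (is.numeric(values)) values <- as.list(values)
  if (length(values) == 0) stop("need at least one kit", call. = FALSE)
  if (is.null(names(values)) || anyDuplicated(names(values)) ||
      any(!nzchar(names(values)))) {
    stop("`values` must carry unique kit names", call. = FALSE)
  }
  lapply(values, function(v) {
    if (!is.numeric(v)) stop("values must be numeric", call. = FALSE)
    v
  })
}

#' Rank kits by contamination level with a cleanliness threshold
#'
#' Kits whose contamination stays below `threshold` in *every* replicate all
#' receive the top rank 1; the remaining kits are ranked by ascending mean
#' contamination starting immediately after the qualifying block. With no
#' qualifying kit the rule degenerates to a plain mean ranking.
#'
#' @param values named list of per-replicate contamination proportions.
#' @param threshold cleanliness threshold (default 0.01, i.e. 1%).
#' @return named integer rank vector.
#' @examples
#' rank_contamination(list(a = c(0.005, 0.008, 0.009),
#'                         b = c(0.001, 0.002, 0.003),
#'                         c = c(0.02, 0.02, 0.02),
#'                         d = c(0.05, 0.05, 0.05)))  # 1, 1, 3, 4
#' @export
rank_contamination <- function(values, threshold = 0.01) {
  values <- as_value_list(values)
  if (any(vapply(values, length, 0L) == 0)) {
    stop("every kit needs replicate values", call. = FALSE)
  }
  qualifies <- vapply(values, function(v) all(v < threshold), TRUE)
  ranks <- stats::setNames(rep(NA_integer_, length(values)), names(values))
  ranks[qualifies] <- 1L
  if (any(!qualifies)) {
    means <- vapply(values[!qualifies], mean_of, 0)
    ranks[!qualifies] <- as.integer(rank(means, ties.method = "min")) +
      sum(qualifies)
  }
  ranks
}

#' Rank kits by reproducibility using equal-width bins
#'
#' The range between the lowest and highest reproducibility value is divided
#' into `n_bins` equal bins (half-open from below, top bin closed). Kits in
#' the highest-value bin receive rank 1, the next bin rank 2, and so on;
#' empty bins still consume a rank number. A degenerate range (all values
#' equal, or a single kit) puts every kit at rank 1.
#'
#' @param values named numeric vector of reproducibility proportions in
#'   `[0, 1]` (percentages are accepted and treated on their own scale).
#' @param n_bins number of bins (default 6).
#' @return named integer rank vector.
#' @examples
#' rank_reproducibility(c(a = 0, b = .1, c = .2, d = .3, e = .4, f = 1))
#' @export
rank_reproducibility <- function(values, n_bins = 6L) {
  if (!is.numeric(values) || length(values) == 0) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("`values` must carry unique kit names", call. = FALSE)
  }
  if (anyNA(values)) stop("missing reproducibility values", call. = FALSE)
  rng <- range(values)
  if (diff(rng) == 0) {
    return(stats::setNames(rep(1L, length(values)), names(values)))
  }
  # explicit boundaries keep bin membership exact at bin edges
  bounds <- rng[1] + diff(rng) * seq_len(n_bins - 1) / n_bins
  bin <- 1L + findInterval(values, bounds)
  stats::setNames(as.integer(n_bins - bin + 1L), names(values))
}

#' Rank kits by PCR dilution factor
#'
#' Lower dilution factors indicate fewer PCR inhibitors and rank better;
#' `"failed"` (no amplification at any dilution) is ordered strictly worst.
#' Ties share the minimum rank with skipping.
#'
#' @param values named character (or numeric) vector of dilution factors,
#'   each one of `"1"`, `"10"`, `"100"`, `"failed"`.
#' @return named integer rank vector.
#' @examples
#' rank_dilution(c(a = "1", b = "1", c = "failed"))  # 1, 1, 3
#' @export
rank_dilution <- function(values) {
  if (length(values) == 0) stop("need at least one kit", call. = FALSE)
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("`values` must carry unique kit names", call. = FALSE)
  }
  kit_names <- names(values)
  values <- as.character(values)
  bad <- !values %in% DILUTION_LEVELS
  if (any(bad)) {
    stop("unknown dilution factor token: ",
         paste(unique(values[bad]), collapse = ", "), call. = FALSE)
  }
  key <- match(values, DILUTION_LEVELS)
  stats::setNames(as.integer(rank(key, ties.method = "min")), kit_names)
}

#' Aggregate per-criterion ranks into Total and Quality ranks
#'
#' Sums integer ranks across criteria per kit. The Total rank sums every
#' criterion; the Quality rank excludes the bench-side `simplicity` and
#' `cost` criteria, isolating data-quality performance. Kits are sorted by
#' ascending rank sum; tied sums share a position (minimum-rank convention)
#' and are reported explicitly.
#'
#' @param per_criterion named list of named integer rank vectors (one per
#'   criterion, each covering every kit) or an equivalent criteria x kits
#'   matrix.
#' @param include_cost_simplicity if `FALSE`, the `simplicity` and `cost`
#'   criteria are dropped entirely, making Total and Quality coincide.
#' @param species optional species label carried through to the result.
#' @return object of class `rank_table`.
#' @export
aggregate_ranks <- function(per_criterion, include_cost_simplicity = TRUE,
                            species = NA_character_) {
  if (is.matrix(per_criterion)) {
    per_criterion <- stats::setNames(
      lapply(seq_len(nrow(per_criterion)), function(i) per_criterion[i, ]),
      rownames(per_criterion))
  }
  if (length(per_criterion) == 0) stop("no criteria", call. = FALSE)
  kit_names <- names(per_criterion[[1]])
  if (is.null(kit_names)) stop("ranks must carry kit names", call. = FALSE)
  for (cr in names(per_criterion)) {
    miss <- setdiff(kit_names, names(per_criterion[[cr]]))
    extra <- setdiff(names(per_criterion[[cr]]), kit_names)
    if (length(miss) || length(extra)) {
      stop(sprintf("criterion '%s' does not cover the same kits (missing: %s)",
                   cr, paste(c(miss, extra), collapse = ", ")),
           call. = FALSE)
    }
  }
  bench_criteria <- c("simplicity", "cost", "cost_per_sample")
  if (!include_cost_simplicity) {
    per_criterion <- per_criterion[!names(per_criterion) %in% bench_criteria]
    if (length(per_criterion) == 0) {
      stop("no criteria left after excluding cost and simplicity",
           call. = FALSE)
    }
  }
  mat <- do.call(rbind, lapply(per_criterion, function(r) r[kit_names]))
  rownames(mat) <- names(per_criterion)
  quality_rows <- !rownames(mat) %in% bench_criteria

  total <- colSums(mat)
  quality <- colSums(mat[quality_rows, , drop = FALSE])
  order_of <- function(sums) names(sort(sums))
  position_of <- function(sums) {
    stats::setNames(as.integer(rank(sums, ties.method = "min")), names(sums))
  }
  structure(
    list(species = species,
         per_criterion_ranks = mat,
         total = total, quality = quality,
         total_position = position_of(total),
         quality_position = position_of(quality),
         total_rank_order = order_of(total),
         quality_rank_order = order_of(quality),
         notes = character(0)),
    class = "rank_table"
  )
}

#' @export
print.rank_table <- function(x, ...) {
  if (!is.na(x$species)) cat(sprintf("Kit ranking for %s\n", x$species))
  cat("Per-criterion ranks:\n")
  print(x$per_criterion_ranks)
  cat("\nTotal rank sums:  ")
  cat(paste(sprintf("%s=%d(pos %d)", names(x$total), x$total,
                    x$total_position), collapse = "  "), "\n")
  cat("Quality rank sums:")
  cat(paste(sprintf(" %s=%d(pos %d)", names(x$quality), x$quality,
                    x$quality_position), collapse = " "), "\n")
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
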