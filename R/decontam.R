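# Contamination handling: chloroplast read removal, kitome-driven
# contaminant calling, and per-sample contamination summaries.

#' Remove chloroplast OTUs from a count table
#'
#' Universal bacterial 16S primers co-amplify the host plastid 16S gene, so
#' algae-associated libraries carry a species-specific load of chloroplast
#' reads. Removal subtracts exactly the OTUs whose order-level taxonomy is
#' the literal string `"Chloroplast"`; counts of retained OTUs are left
#' untouched. The per-sample chloroplast fraction (chloroplast reads over
#' total reads, 0 for empty samples) is reported as a proxy for host-DNA
#' contamination.
#'
#' @param otu samples x OTUs count matrix.
#' @param taxonomy taxonomy data.frame covering every OTU in `otu`.
#' @return list with `otu` (filtered matrix) and `chloroplast_fraction`
#'   (named per-sample vector).
#' @examples
#' tax <- data.frame(otu_id = c("a", "b"), domain = "Bacteria", phylum = "",
#'                   class = "", order = c("Chloroplast", "Vibrionales"),
#'                   family = "", genus = "")
#' m <- matrix(c(40L, 60L), 1, 2, dimnames = list("s1", c("a", "b")))
#' remove_chloroplast(m, tax)$chloroplast_fraction
#' @export
remove_chloroplast <- function(otu, taxonomy) {
  check_otu_matrix(otu)
  check_taxonomy(taxonomy)
  missing <- setdiff(colnames(otu), taxonomy$otu_id)
  if (length(missing)) {
    stop("OTUs without taxonomy rows: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- taxonomy$order[match(colnames(otu), taxonomy$otu_id)]
  is_chl <- !is.na(ord) & ord == "Chloroplast"
  totals <- rowSums(otu)
  chl_reads <- rowSums(otu[, is_chl, drop = FALSE])
  frac <- ifelse(totals > 0, chl_reads / totals, 0)
  list(otu = otu[, !is_chl, drop = FALSE],
       chloroplast_fraction = stats::setNames(frac, rownames(otu)))
}

#' Call kit-reagent contaminant OTUs from negative controls
#'
#' A two-score contaminant classifier in the spirit of negative-control
#' decontamination tools. For each OTU two evidence scores are computed and
#' the OTU is flagged when *either* falls below `threshold`:
#'
#' * `score_p` (prevalence): one-sided Fisher exact p-value testing whether
#'   the OTU is more prevalent (presence = count >= 1) in negative controls
#'   than in true samples. A small score means control enrichment, i.e.
#'   contaminant-like.
#' * `score_f` (frequency): permutation p-value (default 999 permutations,
#'   seeded) for a *negative* Spearman correlation between the OTU's relative
#'   abundance and sample DNA concentration across true samples. Reagent
#'   contaminants enter at a roughly fixed mass, so their proportion rises as
#'   template DNA falls; a small score means contaminant-like.
#'
#' By default all controls and samples are pooled, which gives the frequency
#' score the full cross-kit DNA-concentration gradient to work with. With
#' `per_kit = TRUE` each kit is tested against its own control only and an
#' OTU is flagged if any kit flags it.
#'
#' This is not a reimplementation of any published decontamination algorithm;
#' both tests are fully specified here and deliberately simple.
#'
#' @param otu samples x OTUs count matrix including control samples.
#' @param metadata sample metadata with `is_control` and `dna_conc`.
#' @param threshold score threshold for flagging (default 0.3).
#' @param n_perm permutations for the frequency score (default 999).
#' @param seed integer seed for the permutation null.
#' @param per_kit logical; test each kit against its own control only.
#' @return data.frame with columns `otu_id`, `score_p`, `score_f`,
#'   `contaminant`.
#' @export
call_contaminants <- function(otu, metadata, threshold = 0.3,
                              n_perm = 999L, seed = 1L, per_kit = FALSE) {
  check_otu_matrix(otu)
  check_metadata(metadata)
  meta <- metadata[match(rownames(otu), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("samples missing from metadata: ",
         paste(setdiff(rownames(otu), metadata$sample_id), collapse = ", "),
         call. = FALSE)
  }
  if (!any(meta$is_control)) stop("no control samples", call. = FALSE)
  if (all(meta$is_control)) stop("no true samples", call. = FALSE)
  if (!is_number(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }

  if (per_kit) {
    kits <- unique(meta$kit[meta$is_control])
    per_kit_scores <- lapply(kits, function(k) {
      idx <- meta$kit == k
      contaminant_scores(otu[idx, , drop = FALSE], meta[idx, ],
                         n_perm = n_perm,
                         seed = derive_seed(seed, "kit", k))
    })
    score_p <- do.call(pmin, lapply(per_kit_scores, `[[`, "score_p"))
    score_f <- do.call(pmin, lapply(per_kit_scores, `[[`, "score_f"))
  } else {
    sc <- contaminant_scores(otu, meta, n_perm = n_perm, seed = seed)
    score_p <- sc$score_p
    score_f <- sc$score_f
  }

  data.frame(otu_id = colnames(otu), score_p = score_p, score_f = score_f,
             contaminant = score_p < threshold | score_f < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Both scores for one control/sample split. Vectorised over OTUs: the
# frequency permutation null shares one set of concentration permutations
# across all OTUs, and Spearman correlations are computed as crossproducts
# of standardised rank matrices.
contaminant_scores <- function(otu, meta, n_perm, seed) {
  is_ctrl <- meta$is_control
  n_ctrl <- sum(is_ctrl)
  n_samp <- sum(!is_ctrl)
  present <- otu >= 1

  ctrl_pres <- colSums(present[is_ctrl, , drop = FALSE])
  samp_pres <- colSums(present[!is_ctrl, , drop = FALSE])
  score_p <- vapply(seq_len(ncol(otu)), function(j) {
    m <- matrix(c(ctrl_pres[j], n_ctrl - ctrl_pres[j],
                  samp_pres[j], n_samp - samp_pres[j]), 2, 2)
    # alternative "greater": odds of presence higher in controls
    stats::fisher.test(m, alternative = "greater")$p.value
  }, 0)

  samp_otu <- otu[!is_ctrl, , drop = FALSE]
  totals <- rowSums(samp_otu)
  ra <- samp_otu / ifelse(totals > 0, totals, 1)
  conc <- meta$dna_conc[!is_ctrl]

  rra <- apply(ra, 2, rank)                    # ties: average rank
  rra <- scale(rra)                            # columns sd-standardised
  rra[is.na(rra)] <- 0                         # constant OTUs: no evidence
  rconc <- as.vector(scale(rank(conc)))
  n <- nrow(samp_otu)
  if (all(rconc == 0) || anyNA(rconc)) {
    score_f <- rep(1, ncol(otu))
  } else {
    obs <- as.vector(crossprod(rra, rconc)) / (n - 1)
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample(rconc), numeric(n))
    })
    rho_perm <- crossprod(rra, perm) / (n - 1)     # OTUs x n_perm
    score_f <- (1 + rowSums(rho_perm <= obs)) / (1 + n_perm)
    score_f[apply(rra, 2, function(z) all(z == 0))] <- 1
  }
  list(score_p = unname(score_p), score_f = unname(score_f))
}

#' Per-sample contamination level
#'
#' Total relative abundance of a set of contaminant OTUs in each sample.
#' Additive over disjoint contaminant sets; 0 everywhere for an empty set.
#'
#' @param otu samples x OTUs count matrix.
#' @param contaminants character vector of contaminant OTU ids (must all be
#'   columns of `otu`).
#' @return named per-sample proportion vector.
#' @export
contamination_level <- function(otu, contaminants) {
  check_otu_matrix(otu)
  unknown <- setdiff(contaminants, colnames(otu))
  if (length(unknown)) {
    stop("unknown OTU ids in contaminant set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  totals <- rowSums(otu)
  cont <- rowSums(otu[, contaminants, drop = FALSE])
  stats::setNames(ifelse(totals > 0, cont / totals, 0), rownames(otu))
}

#' Sample-to-kitome read-yield ratio (M/C ratio)
#'
#' Mean read total of a kit's true-sample replicates divided by the read
#' total of its matched kitome control. A ratio above 1 indicates that
#' biological signal dominates reagent contamination. A kitome with zero
#' reads makes the ratio undefined; `Inf` is returned and treated as the
#' best possible outcome by the ranking stage.
#'
#' @param sample_reads numeric vector of per-replicate read totals.
#' @param kitome_reads read total of the kitome control.
#' @return a single number (possibly `Inf`).
#' @examples
#' mc_ratio(c(100, 200, 300), 100)  # 2
#' @export
mc_ratio <- function(sample_reads, kitome_reads) {
  if (length(sample_reads) == 0) {
    stop("`sample_reads` must be non-empty", call. = FALSE)
  }
  if (any(sample_reads < 0) || kitome_reads < 0) {
    stop("read totals must be non-negative", call. = FALSE)
  }
  if (kitome_reads == 0) return(Inf)
  mean(sample_reads) / kitome_reads
}
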