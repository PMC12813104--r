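# Alpha/beta diversity, replicate reproducibility, OTU sharing and
# taxonomic summaries on (filtered) count tables.

#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` over the non-zero relative abundances, natural
#' log. Incorporates both richness and dominance; invariant to rescaling of
#' counts and bounded above by `log(richness)` with equality at uniformity.
#'
#' @param counts non-negative count (or abundance) vector with positive
#'   total.
#' @return Shannon index (dimensionless).
#' @examples
#' shannon(rep(5, 4))  # log(4)
#' @export
shannon <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be non-negative numbers", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("cannot compute Shannon index of an empty sample",
                       call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))` on raw counts
#' (no rarefaction by default). Returns a `dist` object labelled with sample
#' ids; all values lie in `[0, 1]`.
#'
#' @param otu samples x OTUs count matrix with at least 2 samples, each with
#'   a positive total.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(otu) {
  check_otu_matrix(otu)
  if (nrow(otu) < 2) stop("need at least 2 samples", call. = FALSE)
  empty <- rowSums(otu) == 0
  if (any(empty)) {
    stop("empty sample(s): ", paste(rownames(otu)[empty], collapse = ", "),
         call. = FALSE)
  }
  vegan::vegdist(otu, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling (double-centred Gower matrix eigendecomposition)
#' of a dissimilarity matrix. Axes with negative eigenvalues -- which arise
#' for non-Euclidean dissimilarities such as Bray-Curtis -- are reported but
#' dropped from the returned coordinates.
#'
#' @param d a `dist` object or symmetric dissimilarity matrix.
#' @param k number of coordinate axes requested, `k < n` samples.
#' @return list with `points` (n x <= k coordinate matrix), `eig` (all
#'   eigenvalues, non-increasing) and `negative_eig` (the negative ones).
#' @export
pcoa <- function(d, k = 2) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (!is_number(k) || k < 1 || k >= n) {
    stop("`k` must satisfy 1 <= k < number of samples", call. = FALSE)
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pts <- fit$points
  if (!is.null(pts) && ncol(pts) > 0) {
    keep <- fit$eig[seq_len(ncol(pts))] > sqrt(.Machine$double.eps)
    pts <- pts[, keep, drop = FALSE]
    if (ncol(pts) > 0) colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  }
  list(points = pts, eig = eig, negative_eig = eig[eig < 0])
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Single-factor PERMANOVA on a dissimilarity matrix. The pseudo-F statistic
#' compares among-group to within-group sums of squared dissimilarities:
#' `F = ((SS_T - SS_W) / (a - 1)) / (SS_W / (n - a))` with
#' `SS_T = sum_{i<j} d_ij^2 / n` and `SS_W` the analogous within-group sum,
#' each within-group term divided by its group size. Significance comes from
#' free permutation of the group labels (no strata):
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d a `dist` object or symmetric dissimilarity matrix.
#' @param groups group labels, one per sample; at least 2 groups with at
#'   least 2 samples each.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return object of class `permanova_result`: list with `pseudo_f`,
#'   `p_value`, `n_permutations`, `df_among`, `df_within`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  a <- nlevels(droplevels(groups))
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 samples", call. = FALSE)
  }
  D2 <- as.matrix(d)^2
  ss_total <- sum(D2) / (2 * n)

  members <- split(seq_len(n), groups)
  sizes <- unname(lengths(members))
  # within-group SS for a permutation of sample indices: permuting labels is
  # equivalent to permuting which samples fall in each (fixed-size) group
  ssw <- function(idx) {
    s <- 0
    for (g in seq_along(members)) {
      ii <- idx[members[[g]]]
      s <- s + sum(D2[ii, ii]) / (2 * sizes[g])
    }
    s
  }
  pseudo_f <- function(sw) ((ss_total - sw) / (a - 1)) / (sw / (n - a))
  f_obs <- pseudo_f(ssw(seq_len(n)))

  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) pseudo_f(ssw(sample.int(n))), 0)
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  structure(
    list(pseudo_f = f_obs, p_value = p, n_permutations = as.integer(n_perm),
         df_among = a - 1L, df_within = n - a),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.4f, p = %.4g (%d permutations)\n",
              x$df_among, x$df_within, x$pseudo_f, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Technical-replicate reproducibility rate
#'
#' Fraction of OTUs detected in *all* technical replicates of a group,
#' relative to the OTUs detected in at least one of them (denominator
#' `"union"`, the default) or to all OTU columns of the table
#' (`"total"`). Presence means count >= 1; the rate depends only on
#' presence, never on count magnitudes.
#'
#' @param otu samples x OTUs count matrix.
#' @param replicate_ids sample ids of the replicate group (>= 2).
#' @param denominator `"union"` or `"total"`.
#' @return proportion in `[0, 1]`.
#' @export
reproducibility_rate <- function(otu, replicate_ids,
                                 denominator = c("union", "total")) {
  check_otu_matrix(otu)
  denominator <- match.arg(denominator)
  if (length(replicate_ids) < 2) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  missing <- setdiff(replicate_ids, rownames(otu))
  if (length(missing)) {
    stop("replicates missing from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  present <- otu[replicate_ids, , drop = FALSE] >= 1
  if (any(rowSums(present) == 0)) {
    warning("replicate with no detected OTUs; reproducibility rate is 0",
            call. = FALSE)
    return(0)
  }
  shared <- sum(colSums(present) == length(replicate_ids))
  denom <- switch(denominator,
                  union = sum(colSums(present) > 0),
                  total = ncol(otu))
  if (denom == 0) 0 else shared / denom
}

#' OTU sharing across kits
#'
#' For one host species, an OTU counts as detected by a kit if it is present
#' (count >= 1) in at least one of that kit's replicates. Returns how many
#' OTUs are detected by exactly `m` kits for `m = 1..K`, plus the fractions
#' of universal (all kits), unique (exactly one kit) and other OTUs.
#'
#' @param otu samples x OTUs count matrix.
#' @param metadata sample metadata.
#' @param species host species label to analyse.
#' @return list with `counts` (named vector over `1..K`), `fractions`
#'   (`universal`, `unique`, `other`), `total_detected` and `n_kits`.
#' @export
otu_sharing <- function(otu, metadata, species) {
  check_otu_matrix(otu)
  check_metadata(metadata)
  meta <- metadata[match(rownames(otu), metadata$sample_id), ]
  sel <- !meta$is_control & meta$species == species
  if (!any(sel, na.rm = TRUE)) {
    stop("unknown species label: ", species, call. = FALSE)
  }
  kits <- unique(meta$kit[sel])
  detect <- vapply(kits, function(k) {
    idx <- sel & meta$kit == k
    colSums(otu[idx, , drop = FALSE] >= 1) > 0
  }, logical(ncol(otu)))
  m <- rowSums(detect)
  detected <- m > 0
  counts <- stats::setNames(
    vapply(seq_along(kits), function(i) sum(m == i), 0L),
    as.character(seq_along(kits)))
  total <- sum(detected)
  frac <- function(x) if (total == 0) 0 else x / total
  list(
    counts = counts,
    fractions = c(universal = frac(sum(m == length(kits))),
                  unique = frac(sum(m == 1)),
                  other = frac(sum(m > 1 & m < length(kits)))),
    total_detected = total,
    n_kits = length(kits)
  )
}

#' Aggregate a count table to a taxonomic rank
#'
#' Sums relative abundances within each taxon at the requested rank and
#' pools low-abundance taxa into `"other"`: a taxon is kept only if its
#' abundance reaches `min_display` in at least one sample (the conventional
#' ">1%" display rule). Empty rank labels are grouped as `"unclassified"`.
#' Columns sum to 1 for every non-empty sample.
#'
#' @param otu samples x OTUs count matrix.
#' @param taxonomy taxonomy data.frame covering every OTU.
#' @param level one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param min_display pooling threshold on per-sample maximum relative
#'   abundance (default 0.01; 0 disables pooling).
#' @return taxa x samples relative-abundance matrix.
#' @export
aggregate_taxa <- function(otu, taxonomy, level, min_display = 0.01) {
  check_otu_matrix(otu)
  check_taxonomy(taxonomy)
  if (!level %in% TAX_RANKS) {
    stop("unknown rank: ", level, "; expected one of ",
         paste(TAX_RANKS, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(colnames(otu), taxonomy$otu_id)
  if (length(missing)) {
    stop("OTUs without taxonomy rows: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels <- taxonomy[[level]][match(colnames(otu), taxonomy$otu_id)]
  labels[is.na(labels) | labels == ""] <- "unclassified"
  totals <- rowSums(otu)
  ra <- otu / ifelse(totals > 0, totals, 1)
  agg <- t(rowsum(t(ra), group = labels))        # samples x taxa
  keep <- apply(agg, 2, max) >= min_display
  if (min_display <= 0) keep[] <- TRUE
  pooled <- rowSums(agg[, !keep, drop = FALSE])
  out <- agg[, keep, drop = FALSE]
  if (any(!keep)) out <- cbind(out, other = pooled)
  t(out)
}
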