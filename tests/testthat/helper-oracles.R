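# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Bray-Curtis by explicit double loop over sample pairs and OTUs.
brute_bray <- function(otu) {
  n <- nrow(otu)
  m <- matrix(0, n, n, dimnames = list(rownames(otu), rownames(otu)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- 0
      for (k in seq_len(ncol(otu))) shared <- shared + min(otu[i, k], otu[j, k])
      m[i, j] <- 1 - 2 * shared / (sum(otu[i, ]) + sum(otu[j, ]))
    }
  }
  m
}

# Minimum-rank-with-skip by counting strictly better competitors.
oracle_rank_by_mean <- function(values, higher_is_better = TRUE) {
  means <- vapply(values, mean, 0)
  sapply(names(values), function(k) {
    if (higher_is_better) 1L + sum(means > means[k])
    else 1L + sum(means < means[k])
  })
}

oracle_rank_contamination <- function(values, threshold = 0.01) {
  qual <- vapply(values, function(v) all(v < threshold), TRUE)
  means <- vapply(values, mean, 0)
  sapply(names(values), function(k) {
    if (qual[k]) return(1L)
    as.integer(sum(qual) + 1L + sum(means[!qual] < means[k]))
  })
}

oracle_rank_reproducibility <- function(values, n_bins = 6) {
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(stats::setNames(rep(1L, length(values)), names(values)))
  bounds <- lo + (hi - lo) * seq_len(n_bins - 1) / n_bins
  sapply(names(values), function(k) {
    b <- 1L
    for (bd in bounds) if (values[k] >= bd) b <- b + 1L
    as.integer(n_bins - b + 1L)
  })
}

oracle_rank_dilution <- function(values) {
  ord <- c("1" = 1, "10" = 2, "100" = 3, failed = 4)
  key <- ord[as.character(values)]
  sapply(seq_along(values), function(i) 1L + sum(key < key[i])) |>
    stats::setNames(names(values))
}

# Minimal valid metadata data.frame for hand-built tables.
make_metadata <- function(sample_id, species, kit, replicate,
                          is_control = FALSE, dna_conc = 1,
                          dilution_factor = "1") {
  data.frame(sample_id = sample_id, species = species, kit = kit,
             replicate = replicate, is_control = is_control,
             dna_conc = dna_conc, input_mass = 2, din = 5,
             a260_280 = 1.8, a260_230 = 2.1,
             dilution_factor = dilution_factor, stringsAsFactors = FALSE)
}

# Small random OTU matrix with valid dimnames.
random_otu <- function(n_samples, n_otus, lambda = 10) {
  matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus,
         dimnames = list(paste0("s", seq_len(n_samples)),
                         paste0("otu", seq_len(n_otus))))
}

# Taxonomy covering a set of OTU ids with a fixed order label.
flat_taxonomy <- function(otu_ids, order = "Vibrionales") {
  data.frame(otu_id = otu_ids, domain = "Bacteria", phylum = "p", class = "c",
             order = order, family = "f",
             genus = paste0("g", seq_along(otu_ids)),
             stringsAsFactors = FALSE)
}

# tempdir scoped to the calling test
withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Kit panel with one kit ("Winner") given strictly dominant values on every
# ranking criterion: best yield, DIN, dilution, contamination, chloroplast
# capture, unbiased community (highest Shannon), simplest and cheapest.
planted_kit_specs <- function() {
  loser <- function(name, template, dil, cost, din) {
    kit_spec(name, capture_bias_sd = 1.0, dropout_rate = 0.2,
             contaminant_load_ng = 2, mean_template_ng = template,
             dilution_factor = dil, simplicity = 2L, cost_per_sample = cost,
             din = din, chloroplast_affinity = 1.2)
  }
  specs <- list(
    kit_spec("Winner", capture_bias_sd = 0, dropout_rate = 0,
             contaminant_load_ng = 0.2, mean_template_ng = 100,
             dilution_factor = "1", simplicity = 1L, cost_per_sample = 3,
             din = 8, chloroplast_affinity = 0.3),
    loser("KitB", 40, "10", 6, 3.0),
    loser("KitC", 35, "10", 7, 3.5),
    loser("KitD", 30, "100", 8, 4.0),
    loser("KitE", 25, "10", 9, 5.0),
    loser("KitF", 20, "100", 12, 6.5)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}
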