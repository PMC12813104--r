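test_that("base profiles respect chloroplast mass and determinism", {
  spec <- species_spec("sp", n_otus = 50, chloroplast_fraction = 0.3,
                       n_chloroplast_otus = 5)
  p1 <- generate_base_profile(spec, seed = 11)
  p2 <- generate_base_profile(spec, seed = 11)
  expect_identical(p1, p2)
  expect_equal(sum(p1$proportions), 1)
  chl <- p1$taxonomy$otu_id[p1$taxonomy$order == "Chloroplast"]
  expect_length(chl, 5)
  expect_setequal(chl, p1$chloroplast_otu_ids)
  expect_equal(sum(p1$proportions[chl]), 0.3)

  none <- generate_base_profile(species_spec("sp", 20), seed = 1)
  expect_false(any(none$taxonomy$order == "Chloroplast"))

  flat <- generate_base_profile(
    species_spec("sp", 10, abundance_log_sd = 0), seed = 1)
  expect_equal(unname(flat$proportions), rep(0.1, 10))
})

test_that("species_spec rejects invalid configurations", {
  expect_error(species_spec("x", 0), "positive")
  expect_error(species_spec("x", 5, chloroplast_fraction = 1), "\\[0, 1\\)")
  expect_error(species_spec("x", 5, chloroplast_fraction = 0.2,
                            n_chloroplast_otus = 6), "exceed")
})

test_that("kit bias is identity at zero parameters and rejects full dropout", {
  p <- stats::setNames(rep(0.25, 4), paste0("o", 1:4))
  kit0 <- kit_spec("k", capture_bias_sd = 0, dropout_rate = 0)
  out <- apply_kit_bias(p, kit0, seed = 3)
  expect_equal(out$proportions, p)
  expect_length(out$dropped_otu_ids, 0)
  expect_error(kit_spec("k", dropout_rate = 1), "\\[0, 1\\)")
})

test_that("kit bias log-ratio distortion matches capture_bias_sd", {
  # sd over OTUs of log(out/in) equals the multiplier log-sd up to an
  # additive renormalisation constant; checked by Monte Carlo
  sd_target <- 0.4
  kit <- kit_spec("k", capture_bias_sd = sd_target, dropout_rate = 0)
  p <- generate_base_profile(species_spec("sp", 500), seed = 5)$proportions
  sds <- vapply(1:100, function(s) {
    out <- apply_kit_bias(p, kit, seed = s)$proportions
    stats::sd(log(out / p))
  }, 0)
  expect_equal(mean(sds), sd_target, tolerance = 0.05)
})

test_that("contaminant spiking follows the closed-form mixing rule", {
  p <- stats::setNames(c(0.6, 0.4), c("a", "b"))
  cp <- stats::setNames(c(0.7, 0.3), c("c1", "c2"))

  none <- spike_contaminants(p, kit_spec("k", contaminant_load_ng = 0), cp)
  expect_equal(sum(none[c("c1", "c2")]), 0)

  even <- spike_contaminants(
    p, kit_spec("k", contaminant_load_ng = 10, mean_template_ng = 10), cp)
  expect_equal(sum(even[c("c1", "c2")]), 0.5)
  expect_equal(sum(even), 1)

  f1 <- sum(spike_contaminants(
    p, kit_spec("k", contaminant_load_ng = 2, mean_template_ng = 10),
    cp)[c("c1", "c2")])
  f2 <- sum(spike_contaminants(
    p, kit_spec("k", contaminant_load_ng = 2, mean_template_ng = 20),
    cp)[c("c1", "c2")])
  expect_lt(f2, f1)

  expect_error(spike_contaminants(
    p, kit_spec("k", contaminant_load_ng = 0, mean_template_ng = 0), cp),
    "zero")
})

test_that("multinomial sampling is exact at the edges and unbiased", {
  p <- stats::setNames(c(0.1, 0.2, 0.3, 0.4), paste0("o", 1:4))
  expect_equal(unname(sample_counts(p, 0, seed = 1)), rep(0L, 4))
  single <- stats::setNames(1, "only")
  expect_equal(sample_counts(single, 100, seed = 1),
               stats::setNames(100L, "only"))
  expect_error(sample_counts(p, -1, seed = 1), "non-negative")

  depth <- 1000
  draws <- vapply(1:500, function(s) sample_counts(p, depth, s) / depth,
                  numeric(4))
  se <- sqrt(p * (1 - p) / depth / 500)
  expect_true(all(abs(rowMeans(draws) - p) < 3 * se))
})

test_that("benchmark dataset has the study design's shape and ground truth", {
  ds <- generate_benchmark_dataset(
    species = default_species_specs(), kits = default_kit_specs(),
    n_replicates = 3, depth = 500, seed = 2)
  # 3 species x 6 kits x 3 reps + 6 kitomes
  expect_equal(nrow(ds$otu), 3 * 6 * 3 + 6)
  expect_equal(nrow(ds$metadata), nrow(ds$otu))
  expect_true(validate_dataset(ds$otu, ds$taxonomy, ds$metadata))
  expect_equal(sum(ds$metadata$is_control), 6)

  ds2 <- generate_benchmark_dataset(
    species = default_species_specs(), kits = default_kit_specs(),
    n_replicates = 3, depth = 500, seed = 2)
  expect_identical(ds$otu, ds2$otu)
  expect_identical(ds$metadata, ds2$metadata)

  # kitomes draw from the contaminant support only (disjoint by construction)
  kitome_rows <- ds$metadata$sample_id[ds$metadata$is_control]
  non_contam <- setdiff(colnames(ds$otu), ds$truth$contaminant_otu_ids)
  expect_true(all(ds$otu[kitome_rows, non_contam] == 0))

  # contaminant and chloroplast truth sets are disjoint and tagged in taxonomy
  expect_length(intersect(ds$truth$contaminant_otu_ids,
                          ds$truth$chloroplast_otu_ids), 0)
  chl_tax <- ds$taxonomy$otu_id[ds$taxonomy$order == "Chloroplast"]
  expect_setequal(chl_tax, ds$truth$chloroplast_otu_ids)
  cont_tax <- ds$taxonomy$otu_id[grepl("-like$", ds$taxonomy$genus)]
  expect_setequal(cont_tax, ds$truth$contaminant_otu_ids)

  expect_error(generate_benchmark_dataset(species = list(),
                                          kits = default_kit_specs()),
               "non-empty")
})

test_that("hierarchical seeding isolates kits from each other", {
  sp <- default_species_specs()[1]
  kits <- default_kit_specs()
  ds_a <- generate_benchmark_dataset(species = sp, kits = kits[1:2],
                                     n_replicates = 2, depth = 300, seed = 9)
  ds_b <- generate_benchmark_dataset(species = sp, kits = kits[1:3],
                                     n_replicates = 2, depth = 300, seed = 9)
  shared <- intersect(rownames(ds_a$otu), rownames(ds_b$otu))
  expect_gt(length(shared), 0)
  expect_identical(ds_a$otu[shared, colnames(ds_a$otu)],
                   ds_b$otu[shared, colnames(ds_a$otu)])
})

test_that("QC concentrations are consistent with kit template masses", {
  ds <- generate_benchmark_dataset(
    species = default_species_specs()[1], kits = default_kit_specs(),
    n_replicates = 3, depth = 200, seed = 4)
  meta <- ds$metadata[!ds$metadata$is_control, ]
  for (k in unique(meta$kit)) {
    template <- default_kit_specs()[[k]]$mean_template_ng
    conc <- meta$dna_conc[meta$kit == k]
    expect_true(all(conc >= 0.1))
    # elution volume 60 uL, multiplicative noise ~10%
    expect_equal(mean(conc), max(template / 60, 0.1), tolerance = 0.35)
  }
  qia <- meta$din[meta$kit == "QiaSto"]
  expect_true(all(is.na(qia)))
})
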