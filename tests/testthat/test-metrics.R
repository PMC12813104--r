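test_that("shannon matches closed forms and scale invariance", {
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(rep(3, 4)), log(4))
  # direct evaluation of -sum p log p for (1,2,3)
  p <- c(1, 2, 3) / 6
  expect_equal(shannon(c(1, 2, 3)), -sum(p * log(p)))
  expect_equal(shannon(c(1, 2, 3)), 1.0114043, tolerance = 1e-6)
  expect_equal(shannon(c(1, 2, 3)), shannon(c(10, 20, 30)))
  expect_error(shannon(c(0, 0)), "empty")
})

test_that("shannon is bounded by log richness with equality at uniformity", {
  set.seed(10)
  for (i in 1:20) {
    x <- rpois(sample(3:30, 1), 5) + 1
    expect_lte(shannon(x), log(length(x)) + 1e-12)
  }
  expect_equal(shannon(rep(2, 17)), log(17))
})

test_that("bray-curtis matches its definition and the brute-force loop", {
  m <- rbind(s1 = c(1L, 1L), s2 = c(1L, 0L), s3 = c(1L, 1L))
  colnames(m) <- c("a", "b")
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s2"], 1 / 3)
  disjoint <- rbind(s1 = c(5L, 0L), s2 = c(0L, 3L))
  colnames(disjoint) <- c("a", "b")
  expect_equal(as.matrix(bray_curtis(disjoint))["s1", "s2"], 1)

  set.seed(3)
  for (i in 1:10) {
    x <- random_otu(5, 8)
    x[1, ] <- x[1, ] + 1L  # guard against empty samples
    expect_equal(as.matrix(bray_curtis(x)), brute_bray(x), tolerance = 1e-12)
  }
  expect_error(bray_curtis(rbind(s1 = c(a = 0L), s2 = c(a = 1L))), "empty")
})

test_that("pcoa reproduces Euclidean geometry and reports negative eigenvalues", {
  # collinear points: one positive eigenvalue, gaps recovered up to sign
  pts <- matrix(c(0, 3, 10), ncol = 1)
  d <- stats::dist(pts)
  fit <- pcoa(d, k = 2)
  expect_equal(sum(fit$eig > 1e-9), 1)
  expect_equal(as.vector(stats::dist(fit$points[, 1])), as.vector(d),
               tolerance = 1e-9)

  # 2-D cloud: distances reproduced to 1e-9, positive inertia on two axes
  set.seed(4)
  cloud <- matrix(rnorm(12), ncol = 2)
  d2 <- stats::dist(cloud)
  fit2 <- pcoa(d2, k = 3)
  expect_equal(as.matrix(stats::dist(fit2$points[, 1:2])), as.matrix(d2),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(fit2$eig[1:2]), sum(fit2$eig[fit2$eig > 1e-9]),
               tolerance = 1e-9)
  expect_equal(sort(fit2$eig, decreasing = TRUE), fit2$eig)

  zero <- matrix(0, 3, 3)
  expect_equal(max(abs(pcoa(stats::as.dist(zero), k = 1)$eig)), 0)
  expect_error(pcoa(d2, k = 6), "k <")
})

test_that("permanova separates planted clusters and is null-calibrated", {
  # two tight, well-separated clusters: p hits the permutation floor
  # (groups of 8 so no random relabelling recreates the exact split)
  m <- rbind(matrix(rep(c(100L, 0L), each = 24), 8, 6),
             matrix(rep(c(0L, 100L), each = 24), 8, 6))
  dimnames(m) <- list(paste0("s", 1:16), paste0("o", 1:6))
  m <- m + 1L
  res <- permanova(bray_curtis(m), rep(c("a", "b"), each = 8),
                   n_perm = 199, seed = 1)
  expect_equal(res$p_value, 1 / 200)
  expect_gt(res$pseudo_f, 10)

  # duplicating every sample into both groups removes between-group structure
  dup <- rbind(m, m)
  rownames(dup) <- paste0("s", seq_len(nrow(dup)))
  res0 <- permanova(bray_curtis(dup), rep(c("g1", "g2"), each = nrow(m)),
                    n_perm = 99, seed = 1)
  expect_lt(res0$pseudo_f, 1e-6)

  expect_error(permanova(bray_curtis(m), rep("a", 16)), "2 groups")
  expect_error(permanova(bray_curtis(m), c("a", rep("b", 15))), "2 samples")
})

test_that("permanova pseudo-F agrees with vegan::adonis2", {
  set.seed(8)
  x <- random_otu(12, 15)
  x[, 1] <- x[, 1] + rep(c(0L, 30L), each = 6)
  g <- rep(c("a", "b"), each = 6)
  d <- bray_curtis(x)
  mine <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(mine$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("reproducibility rate is intersection over union of presence sets", {
  m <- rbind(r1 = c(1L, 1L, 0L), r2 = c(5L, 0L, 9L), r3 = c(2L, 3L, 0L))
  colnames(m) <- c("A", "B", "C")
  # presence sets {A,B},{A,C},{A,B} -> 1/3
  expect_equal(reproducibility_rate(m, rownames(m)), 1 / 3)
  ident <- rbind(r1 = c(1L, 2L), r2 = c(9L, 1L))
  colnames(ident) <- c("A", "B")
  expect_equal(reproducibility_rate(ident, rownames(ident)), 1)
  disj <- rbind(r1 = c(1L, 0L), r2 = c(0L, 1L))
  colnames(disj) <- c("A", "B")
  expect_equal(reproducibility_rate(disj, rownames(disj)), 0)

  # invariant to replicate order and count magnitude
  expect_equal(reproducibility_rate(m, c("r3", "r1", "r2")),
               reproducibility_rate(m * 1000L, rownames(m)))
  expect_warning(
    rate <- reproducibility_rate(rbind(m, r4 = c(0L, 0L, 0L)),
                                 c("r1", "r4")), "no detected")
  expect_equal(rate, 0)
  expect_error(reproducibility_rate(m, "r1"), "2 replicates")
})

test_that("otu sharing counts kits per OTU and classifies fractions", {
  # 2 kits, detection sets {A,B} and {B,C}
  ids <- paste0("s", 1:4)
  meta <- make_metadata(ids, "sp", rep(c("k1", "k2"), each = 2), c(1, 2, 1, 2))
  m <- matrix(0L, 4, 3, dimnames = list(ids, c("A", "B", "C")))
  m[1, "A"] <- 1L; m[2, "B"] <- 1L   # kit1 detects A, B
  m[3, "B"] <- 1L; m[4, "C"] <- 1L   # kit2 detects B, C
  sh <- otu_sharing(m, meta, "sp")
  expect_equal(sh$counts, c("1" = 2L, "2" = 1L))
  expect_equal(unname(sh$fractions["universal"]), 1 / 3)
  expect_equal(unname(sh$fractions["unique"]), 2 / 3)
  expect_equal(sh$total_detected, 3)

  same <- m; same[] <- 1L
  expect_equal(unname(otu_sharing(same, meta, "sp")$fractions["universal"]), 1)
  expect_error(otu_sharing(m, meta, "nope"), "unknown species")
})

test_that("taxonomic aggregation pools sub-threshold taxa into 'other'", {
  tax <- rbind(flat_taxonomy("a", order = "Ord1"),
               flat_taxonomy("b", order = "Ord2"),
               flat_taxonomy("c", order = "Rare"))
  m <- matrix(c(600L, 395L, 5L), 1, 3,
              dimnames = list("s1", c("a", "b", "c")))
  agg <- aggregate_taxa(m, tax, "order", min_display = 0.01)
  expect_setequal(rownames(agg), c("Ord1", "Ord2", "other"))
  expect_equal(sum(agg[, "s1"]), 1)
  expect_equal(agg["other", "s1"], 0.005)

  nopool <- aggregate_taxa(m, tax, "order", min_display = 0)
  expect_setequal(rownames(nopool), c("Ord1", "Ord2", "Rare"))

  single <- aggregate_taxa(m[, "a", drop = FALSE], tax, "order")
  expect_equal(unname(single["Ord1", "s1"]), 1)
  expect_error(aggregate_taxa(m, tax, "kingdom"), "unknown rank")
})
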