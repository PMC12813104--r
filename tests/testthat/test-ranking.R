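test_that("yield per gram follows the elution formula with the 0.1 floor", {
  expect_equal(yield_per_gram(10, input_mass = 1), 600)
  expect_equal(yield_per_gram(0.02, input_mass = 2), 0.1 * 60 / 2)
  expect_equal(yield_per_gram(5, elution_volume = 100, input_mass = 2), 250)
  expect_error(yield_per_gram(5, input_mass = 0), "positive")
})

test_that("purity windows are inclusive on both ratios", {
  expect_true(purity_flags(1.8, 2.1)$pure)
  expect_false(purity_flags(1.8, 1.0)$pure)
  expect_false(purity_flags(1.8, 1.0)$a260_230_ok)
  expect_true(purity_flags(2.0, 2.0)$pure)    # boundary values count as pure
  expect_true(purity_flags(1.7, 2.2)$pure)
  expect_false(purity_flags(2.01, 2.1)$pure)
  expect_error(purity_flags(-1, 2), "positive")
})

test_that("mean ranking uses minimum-rank ties with skipping", {
  expect_equal(rank_by_mean(c(a = 10, b = 5, c = 1)),
               c(a = 1L, b = 2L, c = 3L))
  expect_equal(rank_by_mean(c(a = 2, b = 2, c = 2)),
               c(a = 1L, b = 1L, c = 1L))
  expect_equal(rank_by_mean(c(a = 5, b = 5, c = 3)),
               c(a = 1L, b = 1L, c = 3L))
  expect_equal(rank_by_mean(c(a = 5, b = 5, c = 3), higher_is_better = FALSE),
               c(a = 2L, b = 2L, c = 1L))
  expect_equal(rank_by_mean(list(a = c(1, 3), b = c(2, 2.1))),
               c(a = 2L, b = 1L))
  expect_error(rank_by_mean(list(a = numeric(0), b = 1)), "a")
})

test_that("missing-value kits can be imputed one rank below the worst", {
  r <- rank_by_mean(list(a = c(5, 6), b = NA_real_, c = c(1, 2)),
                    missing = "worst")
  expect_equal(r[c("a", "c")], c(a = 1L, c = 2L))
  expect_equal(unname(r["b"]), 3L)
  expect_equal(attr(r, "imputed"), "b")
})

test_that("mean ranking is invariant under strictly monotone transforms", {
  set.seed(21)
  for (i in 1:50) {
    v <- stats::setNames(rnorm(6), letters[1:6])
    expect_equal(rank_by_mean(v), rank_by_mean(exp(v)))
    expect_equal(rank_by_mean(v, FALSE), rank_by_mean(2 * v - 7, FALSE))
  }
})

test_that("contamination rule: qualifying block at rank 1, rest by mean", {
  expect_equal(unname(rank_contamination(
    list(a = c(0.005, 0.008, 0.009)))[1]), 1L)
  r <- rank_contamination(list(q1 = c(0.001, 0.002, 0.003),
                               q2 = c(0.005, 0.008, 0.009),
                               m1 = c(0.02, 0.02, 0.02),
                               m2 = c(0.05, 0.05, 0.05)))
  expect_equal(r, c(q1 = 1L, q2 = 1L, m1 = 3L, m2 = 4L))
  # no qualifier -> plain ascending mean ranking
  r2 <- rank_contamination(list(a = c(0.05, 0.05), b = c(0.02, 0.02)))
  expect_equal(r2, c(a = 2L, b = 1L))
  # a replicate at the threshold disqualifies (strictly below required)
  r3 <- rank_contamination(list(a = c(0.005, 0.01), b = c(0.002, 0.003)))
  expect_equal(r3, c(a = 2L, b = 1L))
})

test_that("qualifying kits are never outranked by non-qualifying kits", {
  set.seed(31)
  for (i in 1:100) {
    vals <- stats::setNames(
      lapply(1:6, function(j) runif(3, 0, 0.03)), letters[1:6])
    r <- rank_contamination(vals)
    qual <- vapply(vals, function(v) all(v < 0.01), TRUE)
    if (any(qual) && any(!qual)) expect_lt(max(r[qual]), min(r[!qual]))
  }
})

test_that("reproducibility binning follows the six-equal-bin rule", {
  v <- c(a = 0, b = 10, c = 20, d = 30, e = 40, f = 100)
  expect_equal(rank_reproducibility(v),
               c(a = 6L, b = 6L, c = 5L, d = 5L, e = 4L, f = 1L))
  expect_equal(rank_reproducibility(c(x = 0.4, y = 0.4, z = 0.4)),
               c(x = 1L, y = 1L, z = 1L))
  expect_equal(unname(rank_reproducibility(c(solo = 0.7))), 1L)
  # the maximum always lands in the top bin
  set.seed(41)
  for (i in 1:100) {
    vals <- stats::setNames(runif(6), letters[1:6])
    r <- rank_reproducibility(vals)
    expect_equal(unname(r[which.max(vals)]), 1L)
    # higher value never gets a numerically larger rank
    o <- order(vals)
    expect_true(all(diff(r[o]) <= 0))
  }
})

test_that("dilution ranking orders factors ascending with failed last", {
  expect_equal(rank_dilution(c(a = "1", b = "10", c = "100")),
               c(a = 1L, b = 2L, c = 3L))
  expect_equal(rank_dilution(c(a = "1", b = "1", c = "1")),
               c(a = 1L, b = 1L, c = 1L))
  expect_equal(rank_dilution(c(a = "1", b = "1", c = "failed")),
               c(a = 1L, b = 1L, c = 3L))
  expect_equal(unname(rank_dilution(c(a = "failed", b = "100"))[["a"]]), 2L)
  expect_error(rank_dilution(c(a = "20")), "unknown dilution")
})

test_that("rank aggregation sums criteria and reports tied positions", {
  one <- list(crit = c(x = 1L, y = 2L, z = 3L))
  agg1 <- aggregate_ranks(one)
  expect_equal(agg1$total_rank_order, c("x", "y", "z"))

  opp <- list(a = c(x = 1L, y = 2L), b = c(x = 2L, y = 1L))
  agg2 <- aggregate_ranks(opp)
  expect_equal(unname(agg2$total_position), c(1L, 1L))

  three <- list(a = c(x = 1L, y = 2L, z = 3L), b = c(x = 2L, y = 1L, z = 3L))
  agg3 <- aggregate_ranks(three)
  expect_equal(agg3$total, c(x = 3, y = 3, z = 6))
  expect_equal(agg3$total_position, c(x = 1L, y = 1L, z = 3L))

  # quality excludes simplicity and cost; include flag drops them entirely
  crits <- list(shannon = c(x = 1L, y = 2L), cost = c(x = 2L, y = 1L),
                simplicity = c(x = 2L, y = 1L))
  agg4 <- aggregate_ranks(crits)
  expect_equal(agg4$quality, c(x = 1, y = 2))
  expect_equal(agg4$total, c(x = 5, y = 4))
  agg5 <- aggregate_ranks(crits, include_cost_simplicity = FALSE)
  expect_equal(agg5$total, agg5$quality)

  expect_error(aggregate_ranks(list(a = c(x = 1L), b = c(y = 1L))),
               "does not cover")
})
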