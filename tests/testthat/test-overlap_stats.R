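test_that("shuffling preserves lengths and chromosomes and is seed-deterministic", {
  ivs <- data.frame(chrom = c("c1", "c1", "c2"), start = c(0, 500, 100),
                    end = c(10, 600, 400), stringsAsFactors = FALSE)
  sizes <- c(c1 = 1000, c2 = 2000)
  s1 <- shuffle_intervals(ivs, sizes, rng_seed = 5)
  s2 <- shuffle_intervals(ivs, sizes, rng_seed = 5)
  expect_identical(s1, s2)
  expect_equal(s1$end - s1$start, ivs$end - ivs$start)
  expect_equal(s1$chrom, ivs$chrom)
  expect_true(all(s1$start >= 0 & s1$end <= sizes[s1$chrom]))
  expect_error(shuffle_intervals(data.frame(chrom = "c1", start = 0, end = 2000),
                                 sizes), "longer than its chromosome")
})

test_that("placement is uniform over all legal starts", {
  ivs <- data.frame(chrom = "c1", start = 0, end = 10, stringsAsFactors = FALSE)
  sizes <- c(c1 = 1000)
  set.seed(61)
  starts <- replicate(4000, shuffle_intervals(ivs, sizes)$start)
  expect_gte(min(starts), 0)
  expect_lte(max(starts), 990)
  expect_gt(stats::chisq.test(table(cut(starts, seq(0, 991, length.out = 10))))$p.value,
            0.001)
})

test_that("mc_overlap_test counts base-pair overlaps and reports pseudocount p", {
  sizes <- c(c1 = 1000)
  a <- data.frame(chrom = "c1", start = 0, end = 100)
  b <- data.frame(chrom = "c1", start = 50, end = 60)
  r <- mc_overlap_test(a, b, sizes, n_iter = 500, rng_seed = 17)
  expect_equal(r$observed, 1)
  expect_length(r$null_counts, 500)
  expect_gt(r$p_value, 0)
  expect_lte(r$p_value, 1)
  # disjoint chromosome: observed 0, p = 1
  b2 <- data.frame(chrom = "c1", start = 900, end = 910)
  a2 <- data.frame(chrom = "c1", start = 0, end = 1)
  r2 <- mc_overlap_test(a2, b2, sizes, n_iter = 99, rng_seed = 1)
  expect_equal(r2$observed, 0)
  expect_equal(r2$p_value, 1)
  expect_error(mc_overlap_test(a[0, ], b, sizes), "non-empty")
})

test_that("distance profile measures to the nearest contained base", {
  anchors <- data.frame(chrom = "c1", pos = 100)
  peaks <- data.frame(chrom = "c1", start = c(90, 150), end = c(95, 160))
  d <- distance_profile(anchors, peaks, max_dist = 500)
  expect_equal(d$distances, 6)   # nearest contained base is 94, not 95
  anchors2 <- data.frame(chrom = "c1", pos = 92)
  expect_equal(distance_profile(anchors2, peaks, max_dist = 500)$distances, 0)
  far <- data.frame(chrom = "c1", pos = 5000)
  expect_length(distance_profile(far, peaks, max_dist = 100)$distances, 0)
})

test_that("rolling mean is centered, length-preserving, identity at window 1", {
  expect_equal(rolling_mean(rep(3, 10), 8), rep(3, 10))
  x <- c(4, 8, 15, 16, 23, 42)
  expect_equal(rolling_mean(x, 1), x)
  y <- rolling_mean(c(0, 0, 8, 0, 0, 0, 0, 0), 8)
  expect_length(y, 8)
  expect_true(any(y == 1))   # windows covering the whole series average to 1
  expect_error(rolling_mean(numeric(0)), "empty")
})

test_that("hypergeometric p matches closed form and BH matches hand computation", {
  universe <- sprintf("g%02d", 1:20)
  res <- hypergeom_bh(universe[1:5], list(T1 = universe[1:10]), universe)
  expect_equal(res$p_value, 252 / 15504, tolerance = 1e-12)
  res0 <- hypergeom_bh(universe[1:5], list(T2 = universe[19:20]), universe)
  expect_gt(res0$p_value, 0.4)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  expect_error(hypergeom_bh("zz", list(a = universe[1]), universe), "outside")
})

test_that("hypergeometric tail agrees with exhaustive pmf enumeration", {
  # enumerate the tail directly from binomial coefficients for small cases
  set.seed(71)
  for (i in 1:20) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- as.character(seq_len(N))
    term <- sample(universe, K)
    query <- sample(universe, n)
    res <- hypergeom_bh(query, list(T = term), universe)
    support <- max(0, n - (N - K)):min(K, n)
    pmf <- vapply(support, function(x) {
      choose(K, x) * choose(N - K, n - x) / choose(N, n)
    }, numeric(1))
    expect_equal(res$p_value, sum(pmf[support >= res$k]), tolerance = 1e-12,
                 info = paste(N, K, n, res$k))
  }
})
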