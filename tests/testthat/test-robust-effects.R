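test_that("Harrell-Davis quantiles agree with the incomplete-beta oracle", {
  set.seed(11)
  x <- rnorm(10)
  for (q in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(hd_quantile(x, q), hd_oracle(x, q), tolerance = 1e-12)
  }
  expect_equal(hd_quantile(c(1, 2, 3), 0.5), 2, tolerance = 1e-12)
  expect_equal(hd_quantile(rep(4.2, 7), 0.33), 4.2)
  # weights sum to 1: a constant shift moves every quantile by that shift
  qs <- seq(0.1, 0.9, 0.1)
  expect_equal(hd_quantile(x + 5, qs), hd_quantile(x, qs) + 5, tolerance = 1e-12)
  expect_false(is.unsorted(hd_quantile(x, qs)))   # monotone in q
  expect_error(hd_quantile(numeric(0), 0.5), "empty")
  expect_error(hd_quantile(x, 1), "strictly")
})

test_that("Cliff delta and PS match exhaustive pair counting", {
  res <- cliff_delta_inference(c(1, 2, 3), c(0, 0, 4))
  expect_equal(res$delta$value, 1 / 3)           # (6 - 3) / 9
  set.seed(12)
  for (i in 1:5) {
    a <- sample(rnorm(40), 35, replace = TRUE)   # replacement forces ties
    b <- sample(a, 30, replace = TRUE) + sample(c(0, 0, 0.5), 30, TRUE)
    o <- cliff_oracle(a, b)
    r <- cliff_delta_inference(a, b)
    expect_equal(r$delta$value, o$delta, tolerance = 1e-12)
    expect_equal(r$ps_a, o$ps, tolerance = 1e-12)
    expect_equal(r$delta$value, 2 * r$ps_a - 1, tolerance = 1e-12)  # tie identity
    expect_equal(r$ps_a + r$ps_b, 1)
    # antisymmetry under group swap
    r2 <- cliff_delta_inference(b, a)
    expect_equal(r2$delta$value, -r$delta$value, tolerance = 1e-12)
  }
  same <- rnorm(30)
  expect_equal(cliff_delta_inference(same, same)$delta$value, 0)
  sep <- cliff_delta_inference(11:20, 1:10)
  expect_equal(sep$delta$value, 1)
  expect_equal(sep$ps_a, 1)
  expect_error(cliff_delta_inference(numeric(0), 1:3), "empty")
})

test_that("decile shifts equal direct HD differences and track location shifts", {
  set.seed(13)
  a <- rnorm(60); b <- rnorm(60)
  cfg <- fast_cfg(seed = 3)
  d <- decile_shift_test(a, b, cfg)
  qs <- seq(0.1, 0.9, 0.1)
  expect_equal(d$diff, hd_quantile(a, qs) - hd_quantile(b, qs), tolerance = 1e-12)
  # same sample: all point differences exactly zero
  d0 <- decile_shift_test(a, a, cfg)
  expect_equal(d0$diff, rep(0, 9))
  # pure location shift: every decile difference near -c
  set.seed(14)
  big <- rnorm(500)
  dsh <- decile_shift_test(big, big + 0.7, fast_cfg(seed = 4, n = 200))
  expect_equal(dsh$diff, rep(-0.7, 9), tolerance = 0.15)
  expect_true(all(dsh$significant))
  expect_error(decile_shift_test(rnorm(5), rnorm(30), cfg), "at least 10")
})

test_that("overlap index hits the trivial limits", {
  set.seed(15)
  x <- rnorm(200)
  cfg <- fast_cfg(seed = 5, n = 50)
  expect_gte(overlap_eta(x, x, cfg)$value, 0.99)
  expect_lte(overlap_eta(x, x + 100, cfg)$value, 0.01)
  expect_error(overlap_eta(rep(1, 30), x, cfg), "degenerate")
})

test_that("empirical U3 counts directly against the reference HD median", {
  cfg <- fast_cfg(seed = 6, n = 50)
  # median(B) = 2.5 by symmetry of HD weights; 2 of 4 values of A above it
  expect_equal(cohens_u3_empirical(c(1, 2, 3, 4), c(2, 3, 2, 3), cfg)$value, 50)
  expect_equal(cohens_u3_empirical(11:20, 1:10, cfg)$value, 100)
  set.seed(16)
  x <- rnorm(2000)
  expect_equal(cohens_u3_empirical(x, rnorm(2000), cfg)$value, 50, tolerance = 5)
})

test_that("IQR ratio detects scale differences and passes the identity check", {
  set.seed(17)
  a <- rnorm(500)
  cfg <- fast_cfg(seed = 7, n = 200)
  same <- iqr_ratio_test(a, a, cfg)
  expect_equal(same$value, 1)
  expect_gt(same$p, 0.5)
  doubled <- iqr_ratio_test(a, 2 * a, cfg)
  expect_equal(doubled$value, 0.5, tolerance = 0.05)
  expect_lt(doubled$p, 0.01)
})

test_that("moment differences use the plug-in estimators with the stated conventions", {
  set.seed(18)
  a <- rexp(300)
  cfg <- fast_cfg(seed = 8, n = 200)
  sk <- bootstrap_moment_difference(a, -a, "skewness", cfg)
  expect_equal(sk$value, 2 * sample_skewness(a), tolerance = 1e-12)  # antisymmetry
  expect_lt(sk$p, 0.05)
  # non-excess kurtosis: Gaussian samples sit near 3
  g <- rnorm(500)
  ku <- bootstrap_moment_difference(g, rnorm(500), "kurtosis", cfg)
  expect_equal(ku$est_a, 3, tolerance = 0.5)
  expect_gt(ku$p, 0.01)
  expect_error(bootstrap_moment_difference(rnorm(10), g, "skewness", cfg),
               "at least 20")
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.01, 0.2, 0.9)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("magnitude labels follow the published benchmarks", {
  expect_equal(classify_magnitude(0.62, "cliff_delta"), "large")
  expect_equal(classify_magnitude(0.22, "cliff_delta"), "small")
  expect_equal(classify_magnitude(-0.40, "cliff_delta"), "medium")
  expect_equal(classify_magnitude(0.80, "cohen_d"), "large")
  expect_equal(classify_magnitude(0, "cohen_d"), "negligible")
  expect_equal(classify_magnitude(0.6, "cohen_d", thresholds = c(0.1, 0.3, 0.9)),
               "medium")
  expect_error(classify_magnitude(Inf, "cohen_d"), "finite")
})

test_that("bootstrap operations are seed-reproducible and seed-stable", {
  set.seed(19)
  a <- rnorm(500); b <- rnorm(500) + 0.3
  cfg1 <- fast_cfg(seed = 1, n = 400)
  cfg2 <- fast_cfg(seed = 2, n = 400)
  o1 <- overlap_eta(a, b, cfg1)
  expect_identical(o1, overlap_eta(a, b, cfg1))
  o2 <- overlap_eta(a, b, cfg2)
  expect_lt(abs(o1$ci_low - o2$ci_low), 0.02)   # CI endpoints settle across seeds
  d1 <- decile_shift_test(a, b, cfg1)
  expect_identical(d1, decile_shift_test(a, b, cfg1))
})
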