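two_gaussians <- function(n = 100, gap = c(1, 0), p = 2, seed = 71) {
  set.seed(seed)
  a <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  b <- sweep(matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p))),
             2, gap, "+")
  list(a = a, b = b)
}

test_that("projection recovers the axis-aligned direction and its invariances", {
  g <- two_gaussians(n = 200, gap = c(1, 0))
  pr <- project_onto_center_line(g$a, g$b)
  expect_equal(sqrt(sum(pr$direction^2)), 1, tolerance = 1e-12)
  expect_gt(abs(pr$direction[1]), 0.97)        # essentially the first axis
  # translation invariance of the distances
  shift <- c(5, -3)
  pr2 <- project_onto_center_line(sweep(g$a, 2, shift, "+"),
                                  sweep(g$b, 2, shift, "+"))
  expect_equal(pr2$dist_a, pr$dist_a, tolerance = 1e-9)
  # rotation equivariance: exact with mean centers, approximate with the
  # (non-affine-equivariant) marginal HD-median centers
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ra <- g$a %*% R; rb <- g$b %*% R
  colnames(ra) <- colnames(rb) <- colnames(g$a)
  prm <- project_onto_center_line(g$a, g$b, center_method = "mean")
  prm_rot <- project_onto_center_line(ra, rb, center_method = "mean")
  expect_equal(prm_rot$dist_a, prm$dist_a, tolerance = 1e-9)
  expect_equal(projection_r2(prm_rot), projection_r2(prm), tolerance = 1e-9)
  pr3 <- project_onto_center_line(ra, rb)
  expect_equal(projection_r2(pr3), projection_r2(pr), tolerance = 0.05)
  # coincident centers are an error
  expect_error(project_onto_center_line(g$a, g$a), "coincident")
})

test_that("group-swap symmetry holds on a fixed projection and after refitting", {
  g <- two_gaussians(n = 60, gap = c(0.8, 0.3), seed = 72)
  pr <- project_onto_center_line(g$a, g$b)
  ps <- projection_ps_inference(pr, fast_cfg(seed = 1))
  # swapping labels on the SAME distances mirrors PS and negates delta
  fixed_swap <- cliff_delta_inference(pr$dist_b, pr$dist_a, fast_cfg(seed = 1))
  expect_equal(fixed_swap$ps_a, 1 - ps$ps_a, tolerance = 1e-12)
  expect_equal(fixed_swap$delta$value, -ps$delta$value, tolerance = 1e-12)
  # refitting the projection with swapped groups also flips its direction,
  # so the leading group's PS is reproduced exactly
  pr_swap <- project_onto_center_line(g$b, g$a)
  ps_swap <- projection_ps_inference(pr_swap, fast_cfg(seed = 1))
  expect_equal(ps_swap$ps_a, ps$ps_a, tolerance = 1e-12)
  expect_equal(ps$ps_ci_low, (ps$delta$ci_low + 1) / 2)
})

test_that("Q statistic hits its limits and the r2 degenerate cases hold", {
  set.seed(73)
  x <- rnorm(300)
  expect_equal(q_statistic(x, rnorm(300)), 0.5, tolerance = 0.12)
  expect_gte(q_statistic(x, x + 50), 0.99)
  expect_error(q_statistic(rnorm(10), x), "at least 20")
  pr_same <- structure(list(dist_a = x, dist_b = rnorm(300)),
                       class = "projection_result")
  expect_lt(projection_r2(pr_same), 0.02)
  pr_pm <- structure(list(dist_a = rep(0, 30), dist_b = rep(1, 30)),
                     class = "projection_result")
  expect_equal(projection_r2(pr_pm), 1)
})

test_that("HC4 bootstrap-t correlation recovers exact linear relations", {
  set.seed(74)
  x <- rnorm(50)
  up <- hc4_bootstrap_correlation(x, 2 * x, n_boot = 100, seed = 2)
  expect_equal(up$value, 1)
  expect_gt(up$ci_low, 0.9)
  down <- hc4_bootstrap_correlation(x, -x, n_boot = 100, seed = 2)
  expect_equal(down$value, -1)
  expect_error(hc4_bootstrap_correlation(x, rep(1, 50)), "variance")
  expect_error(hc4_bootstrap_correlation(rnorm(5), rnorm(5)), "at least 20")
})

test_that("HC4 standard error matches the sandwich reference implementation", {
  skip_if_not_installed("sandwich")
  set.seed(75)
  x <- rnorm(80)
  y <- 0.5 * x + rnorm(80, 0, sqrt(abs(x)) + 0.2)   # heteroscedastic
  zx <- scale(x)[, 1]; zy <- scale(y)[, 1]
  fit <- lm(zy ~ zx)
  se_ref <- sqrt(sandwich::vcovHC(fit, type = "HC4")["zx", "zx"])
  est <- sexvoldiff:::hc4_slope(x, y)
  expect_equal(est[["r"]], cor(x, y), tolerance = 1e-12)
  expect_equal(est[["se"]], se_ref, tolerance = 1e-10)
})

test_that("cross-method comparison is exact on identical inputs", {
  g <- two_gaussians(n = 80, gap = c(1.2, 0.4), seed = 76)
  pr <- project_onto_center_line(g$a, g$b)
  # feed the projection scores in as the "pclass" side (rescaled to [0,1])
  sc <- plogis(c(pr$dist_a, pr$dist_b))
  # distances grow toward M, so M is the reference of the identical scores
  ss <- score_set(sc, rep(c("F", "M"), each = 80), "pclass", "M")
  pr_logit <- structure(list(dist_a = plogis(pr$dist_a),
                             dist_b = plogis(pr$dist_b)),
                        class = "projection_result")
  res <- crossmethod_comparison(ss, pr_logit, fast_cfg(seed = 4, n = 60))
  expect_equal(res$table$projected, res$table$pclass, tolerance = 1e-9)
  expect_equal(res$correlations$r[1], 1, tolerance = 1e-9)
  # subject mismatch errors
  ss_bad <- score_set(sc[-1], rep(c("F", "M"), each = 80)[-1], "pclass", "M")
  expect_error(crossmethod_comparison(ss_bad, pr_logit, fast_cfg()), "different")
})
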