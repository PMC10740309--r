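sim_xy <- function(n = 200, p = 4, beta = c(1.5, 0, 0, 0), seed = 51) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  pr <- plogis(drop(X %*% beta))
  y <- ifelse(runif(n) < pr, "F", "M")
  # guard against degenerate draws
  if (length(unique(y)) < 2) y[1:2] <- c("F", "M")
  list(X = X, y = y)
}

test_that("reference category follows the median univariate direction", {
  fake_uni <- function(deltas) {
    structure(data.frame(roi = paste0("r", seq_along(deltas)), delta = deltas),
              class = c("univariate_table", "data.frame"))
  }
  expect_equal(select_reference_category(fake_uni(rep(-0.4, 5))), "M")
  expect_equal(select_reference_category(fake_uni(rep(0.2, 5))), "F")
  expect_warning(ref <- select_reference_category(fake_uni(c(-0.3, 0, 0.3))),
                 "balanced")
  expect_equal(ref, "F")
})

test_that("penalized fit respects the monotone link and the penalty limit", {
  d <- sim_xy()
  m1 <- fit_penalized_lr(d$X[, 1, drop = FALSE], d$y, reference_sex = "F")
  ord <- order(d$X[, 1])
  expect_false(is.unsorted(m1$pclass[ord]))       # monotone in the lone predictor
  m <- fit_penalized_lr(d$X, d$y, reference_sex = "F")
  expect_gt(m$coefficients[["x1"]], 0)
  # lambda -> infinity: slopes -> 0, Pclass -> prevalence of reference class
  m_inf <- fit_penalized_lr(d$X, d$y, "F", penalty_grid = 1e8)
  expect_lt(max(abs(m_inf$coefficients)), 1e-3)
  expect_equal(unname(m_inf$pclass), rep(mean(d$y == "F"), nrow(d$X)),
               tolerance = 1e-3)
})

test_that("ridge coefficients agree with glmnet at a fixed penalty", {
  skip_if_not_installed("glmnet")
  d <- sim_xy(n = 300, beta = c(1, -0.5, 0.3, 0))
  lam <- 4
  m <- fit_penalized_lr(d$X, d$y, "F", penalty_grid = lam)
  # glmnet minimizes -loglik/n + lambda_g/2 * sum(beta^2) (standardize off)
  g <- glmnet::glmnet(d$X, factor(d$y, levels = c("M", "F")), family = "binomial",
                      alpha = 0, lambda = lam / nrow(d$X), standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(m$coefficients), unname(as.vector(g$beta)), tolerance = 1e-4)
  expect_equal(m$intercept, unname(g$a0), tolerance = 1e-4)
})

test_that("apparent c-index equals the rank statistic of scores vs labels", {
  d <- sim_xy(n = 250, beta = c(0.8, 0.8, 0, 0), seed = 52)
  m <- fit_penalized_lr(d$X, d$y, "F")
  w <- wilcox.test(m$pclass[d$y == "F"], m$pclass[d$y == "M"], exact = FALSE)
  c_oracle <- unname(w$statistic) / (sum(d$y == "F") * sum(d$y == "M"))
  expect_equal(unname(m$apparent[["c_index"]]), c_oracle, tolerance = 1e-12)
  expect_equal(m$apparent[["somers_dxy"]],
               2 * (m$apparent[["c_index"]] - 0.5), tolerance = 1e-9)
})

test_that("degenerate designs raise informative errors", {
  d <- sim_xy(n = 30, p = 2, beta = c(0, 0))
  Xbad <- cbind(d$X, x3 = d$X[, 1] + d$X[, 2])
  expect_error(fit_penalized_lr(Xbad, d$y, "F"), "rank deficient")
  Xconst <- cbind(d$X, x3 = 1)
  expect_error(fit_penalized_lr(Xconst, d$y, "F"), "degenerate")
  expect_error(fit_penalized_lr(d$X[1:2, ], d$y[1:2], "F"), "more subjects")
})

test_that("optimism correction pulls an overfit null model toward 0.5", {
  # small n, many predictors, no signal: apparent c is inflated
  set.seed(53)
  reps <- 30
  app <- cor_c <- numeric(reps)
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(60 * 10), 60, 10, dimnames = list(NULL, paste0("x", 1:10)))
    y <- rep(c("F", "M"), 30)
    m <- fit_penalized_lr(X, y, "F", penalty_grid = 0.5)
    m <- bootstrap_validate(m, n_reps = 40, seed = 500 + r)
    app[r] <- m$apparent[["c_index"]]
    cor_c[r] <- m$corrected[["c_index"]]
  }
  expect_gt(mean(app), 0.6)                    # visibly overfit
  expect_equal(mean(cor_c), 0.5, tolerance = 0.2)
  expect_lt(mean(cor_c), mean(app) - 0.05)     # correction removes most optimism
  # deterministic under a fixed seed
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rep(c("F", "M"), 25)
  m <- fit_penalized_lr(X, y, "F")
  v1 <- bootstrap_validate(m, n_reps = 25, seed = 9)
  v2 <- bootstrap_validate(m, n_reps = 25, seed = 9)
  expect_identical(v1$corrected, v2$corrected)
})

test_that("calibration curve behaves at the degenerate bin counts", {
  d <- sim_xy(n = 400, beta = c(1, 0, 0, 0), seed = 54)
  m <- fit_penalized_lr(d$X, d$y, "F")
  cal1 <- calibration_curve(m, n_bins = 1)
  expect_equal(cal1$mean_predicted, mean(m$pclass))
  expect_equal(cal1$observed, mean(d$y == "F"))
  cal <- calibration_curve(m, n_bins = 10)
  expect_lte(max(abs(cal$mean_predicted - cal$observed)), 0.15)
  expect_error(calibration_curve(m, n_bins = 1000), "exceeds")
})

test_that("score battery composes the univariate toolbox and reports accuracy", {
  cfg <- fast_cfg(seed = 61, n = 80)
  # perfectly separated scores
  s_sep <- score_set(c(runif(40, 0.8, 1), runif(40, 0, 0.2)),
                     rep(c("F", "M"), each = 40), "pclass", "F")
  b <- score_battery(s_sep, cfg)
  expect_equal(unname(b$accuracy[["balanced"]]), 100)
  expect_equal(b$cliff$delta$value, 1)
  expect_lt(b$overlap$value, 0.05)
  # compositional identity: battery delta equals direct Cliff on the vectors
  set.seed(62)
  sc <- plogis(rnorm(120))
  sx <- rep(c("F", "M"), 60)
  s <- score_set(sc, sx, "pclass", "F")
  b2 <- score_battery(s, cfg)
  direct <- cliff_delta_inference(sc[sx == "F"], sc[sx == "M"], cfg)
  expect_equal(b2$cliff$delta$value, direct$delta$value)
  expect_equal(unname(b2$accuracy[["balanced"]]),
               50 * (mean(sc[sx == "F"] >= 0.5) + mean(sc[sx == "M"] < 0.5)))
})

test_that("pairwise differences match exhaustive enumeration", {
  cfg <- fast_cfg(seed = 63, n = 50)
  s <- score_set(c(1, 1, 0, 0), c("F", "F", "M", "M"), "distance", "F")
  pw <- pairwise_difference_summary(s, cfg, n_boot = 20)
  expect_equal(pw$n_pairs, 4L)
  expect_equal(pw$percent_favoring_reference$value, 100)
  # ties excluded from both numerator and denominator
  s2 <- score_set(c(1, 0, 0, 1), c("F", "F", "M", "M"), "distance", "F")
  pw2 <- pairwise_difference_summary(s2, cfg, n_boot = 20)
  expect_equal(pw2$n_ties, 2L)
  expect_equal(pw2$percent_favoring_reference$value, 50)
  # identical groups: median difference 0
  s3 <- score_set(rep(c(0.2, 0.8), 20), rep(c("F", "M"), each = 20),
                  "pclass", "F")
  pw3 <- pairwise_difference_summary(s3, cfg, n_boot = 20)
  expect_equal(pw3$pomp_deciles$pomp, 100 * pw3$deciles$diff)
})

test_that("nomogram point scales follow the stated arithmetic", {
  set.seed(64)
  X <- cbind(x1 = runif(100, 0, 2), x2 = runif(100, 0, 2))
  m <- structure(list(coefficients = c(x1 = 1, x2 = 0.5), intercept = -1.5,
                      significant = c(TRUE, FALSE), X = X,
                      reference_sex = "F"), class = "pclass_model")
  nom <- build_nomogram(m, X)
  # |b1| r1 = 2 |b2| r2 (ranges equal): max points 100 vs ~50
  expect_equal(nom$scales$max_points[1], 100)
  expect_equal(nom$scales$max_points[2] / nom$scales$max_points[1], 0.5,
               tolerance = 0.05)
  # total points reconstruct Pclass through the inverse logit
  eta <- m$intercept + drop(X %*% m$coefficients)
  total <- vapply(seq_len(nrow(X)), function(i) {
    nom$points_fun("x1", X[i, 1]) + nom$points_fun("x2", X[i, 2])
  }, numeric(1))
  expect_equal(nom$total_points_to_pclass(total), plogis(eta), tolerance = 1e-9)
  # single predictor spans 0-100; zero-coefficient scale is flat
  m1 <- m; m1$coefficients <- c(x1 = -2, x2 = 0)
  nom1 <- build_nomogram(m1, X)
  expect_equal(nom1$scales$max_points, c(100, 0))
  m0 <- m; m0$coefficients <- c(x1 = 0, x2 = 0)
  expect_error(build_nomogram(m0, X), "zero")
})

test_that("model-structure comparison uses absolute rank correlations", {
  mk <- function(b) structure(list(coefficients = b), class = "pclass_model")
  b <- setNames(rnorm(18), sent_core_labels())
  res <- compare_model_structure(list(m1 = mk(b), m2 = mk(b), m3 = mk(-b)))
  expect_equal(unname(res$coef_rho["m1", "m2"]), 1)
  expect_equal(unname(res$coef_rho["m1", "m3"]), 1)   # negation: |rho| = 1
  # independent random vectors: |rho| typically small at n = 18
  set.seed(65)
  rhos <- replicate(300, {
    r <- compare_model_structure(list(a = mk(setNames(rnorm(18), sent_core_labels())),
                                      b = mk(setNames(rnorm(18), sent_core_labels()))))
    r$coef_rho["a", "b"]
  })
  expect_lt(quantile(rhos, 0.95), 0.55)
  expect_error(compare_model_structure(list(m1 = mk(b),
                                            m2 = mk(setNames(rnorm(3), c("q1", "q2", "q3"))))),
               "mismatch|too few")
})

test_that("significant-predictor intersections follow set arithmetic", {
  mk <- function(preds, sig) {
    structure(list(coefficients = setNames(rep(1, length(preds)), preds),
                   significant = preds %in% sig), class = "pclass_model")
  }
  res <- significant_predictor_intersections(list(
    m1 = mk(c("A", "B", "C"), c("A", "B")),
    m2 = mk(c("A", "B", "C"), c("B", "C"))))
  expect_equal(res$intersections[["m1+m2"]], "B")
  expect_equal(res$intersections[["m1"]], "A")
  expect_equal(res$intersections[["m2"]], "C")
  expect_equal(unname(res$counts), c(1L, 2L, 1L))
  none <- significant_predictor_intersections(list(
    m1 = mk(c("A", "B"), character(0)), m2 = mk(c("A", "B"), character(0))))
  expect_equal(names(none$intersections), "(none)")
})

test_that("TIV augmentation appends a robust-z TIV predictor", {
  co <- tiny_cohort(n_per_sex = 100, seed = 66)
  ds <- build_datasets(co)
  m <- fit_tiv_augmented(ds$raw$zscores, ds$raw$tiv, ds$raw$sex, "M")
  expect_true(m$includes_tiv)
  expect_true("TIV" %in% names(m$coefficients))
  # with a strong TIV sex gap, TIV dominates the nomogram
  nom <- build_nomogram(m, sex = ds$raw$sex)
  expect_equal(nom$scales$predictor[which.max(nom$scales$max_points)], "TIV")
  expect_error(fit_tiv_augmented(ds$raw$zscores, rep(1500, nrow(co)),
                                 ds$raw$sex, "M"), "constant")
})
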