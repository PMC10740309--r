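# Multivariate sex-difference estimation via L2-penalized logistic
# regression. The model condenses the 18 regional robust z-scores into a
# per-subject classification probability (Pclass score), which is then
# analysed as a continuous univariate outcome with the robust battery.
#
# The ridge-penalized fit, penalty-trace selection, effective degrees of
# freedom, penalized Wald covariance and Harrell optimism bootstrap are
# implemented here directly: the penalized information matrix is needed for
# Wald tests and the corrected-AIC penalty trace, and the optimism loop
# must refit at a fixed penalty.

# ---- core penalized fit ---------------------------------------------------

# overflow-safe log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# ridge-penalized logistic IRLS; X without intercept column; penalty on
# slopes only. Returns NULL on non-convergence.
ridge_logit_irls <- function(X, y, lambda, max_iter = 100L, tol = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(lambda, p))
  beta <- numeric(p + 1L)
  beta[1L] <- stats::qlogis(max(1e-6, min(1 - 1e-6, mean(y))))
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(Xd, Xd * w)
    grad <- drop(crossprod(Xd, y - mu)) - pen * beta
    H <- info + diag(pen, p + 1L)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # step-halving on the penalized deviance
    obj <- function(b) {
      e <- drop(Xd %*% b)
      -2 * sum(y * e - log1pexp(e)) + sum(pen * b^2)
    }
    cur <- obj(beta)
    fac <- 1
    repeat {
      cand <- beta + fac * step
      if (obj(cand) <= cur + 1e-12 || fac < 1e-4) break
      fac <- fac / 2
    }
    beta_new <- beta + fac * step
    dev_new <- obj(beta_new)
    if (abs(dev_old - dev_new) < tol * (abs(dev_new) + 1)) {
      beta <- beta_new
      break
    }
    beta <- beta_new
    dev_old <- dev_new
  }
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(Xd, Xd * w)               # unpenalized information
  H <- info + diag(pen, p + 1L)
  Hinv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Hinv)) return(NULL)
  deviance <- -2 * sum(y * eta - log1pexp(eta))
  list(beta = stats::setNames(beta, colnames(Xd)), fitted = mu,
       deviance = deviance, info = info, Hinv = Hinv,
       df_eff = sum(diag(info %*% Hinv)),     # includes the intercept
       cov = Hinv %*% info %*% Hinv)
}

# rank-based concordance of scores against binary labels (ties = 0.5)
concordance_index <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

lr_indexes <- function(score, y, deviance, n) {
  dev_null <- -2 * (sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y)))
  lr_chi2 <- dev_null - deviance
  r2 <- (1 - exp(-lr_chi2 / n)) / (1 - exp(-dev_null / n))
  cidx <- concordance_index(score, y)
  c(nagelkerke_r2 = r2, c_index = cidx, somers_dxy = 2 * (cidx - 0.5),
    lr_chi2 = lr_chi2)
}

# ---- public operations ----------------------------------------------------

#' Choose the reference sex category from the univariate pattern
#'
#' The reference (positive) class of a classification model is the sex
#' favored by the direction of the observed univariate differences, so
#' that higher Pclass scores correspond to larger (raw or TIV-adjusted)
#' volumes. The rule: the sign of the median Cliff's delta over the
#' FDR-significant regions (delta > 0 means F > M under the package's
#' F-vs-M convention); when no region is significant, the median over all
#' regions. With many null regions the all-region median is dominated by
#' noise, so restricting to the significant ones is what keeps the
#' reference aligned with the differences actually observed. An exact zero
#' median breaks toward "F" with a warning.
#'
#' @param uni A `univariate_table`.
#' @return `"F"` or `"M"`.
#' @export
select_reference_category <- function(uni) {
  stopifnot(inherits(uni, "univariate_table"))
  alpha <- attr(uni, "alpha") %||% 0.05
  sig <- !is.null(uni$delta_fdr_p) && any(uni$delta_fdr_p <= alpha)
  med <- if (isTRUE(sig)) {
    stats::median(uni$delta[uni$delta_fdr_p <= alpha])
  } else stats::median(uni$delta)
  if (med == 0) {
    warning("univariate directions exactly balanced; reference set to 'F'")
    return("F")
  }
  if (med > 0) "F" else "M"
}

#' Fit an L2-penalized logistic regression sex classifier
#'
#' Maximum penalized likelihood with ridge penalty `lambda/2 * sum(beta^2)`
#' (intercept unpenalized), the penalty chosen over a grid by a corrected
#' AIC penalty trace: maximize `LR chi^2 - 2 * df_eff`, with effective
#' degrees of freedom `trace(I(b) (I(b) + lambda P)^(-1))`. Wald statistics
#' use the sandwich covariance of the penalized fit,
#' `(I + lambda P)^(-1) I (I + lambda P)^(-1)`, and are approximate;
#' coefficient p-values are FDR-adjusted across predictors.
#'
#' @param X Subject x predictor matrix of robust z-scores (no missing
#'   values; `n > ncol(X)`).
#' @param y Sex labels (factor or character with levels F/M).
#' @param reference_sex The class coded 1 (higher Pclass = this sex).
#' @param penalty_grid Candidate ridge penalties (default `c(0, 2^(-4:8))`).
#' @param alpha Level used for the coefficient significance flags.
#' @return An object of class `pclass_model`: coefficients, penalty,
#'   per-coefficient Wald z / p / fdr_p, apparent discrimination indexes
#'   (Nagelkerke R2, C-index, Somers Dxy), fitted Pclass scores.
#' @export
fit_penalized_lr <- function(X, y, reference_sex = "F",
                             penalty_grid = c(0, 2^seq(-4, 8)),
                             alpha = 0.05) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y_chr <- as.character(y)
  stopifnot(all(y_chr %in% c("F", "M")), reference_sex %in% c("F", "M"))
  yy <- as.integer(y_chr == reference_sex)
  if (nrow(X) <= ncol(X)) stop("need more subjects than predictors", call. = FALSE)
  if (length(unique(yy)) < 2L) stop("both classes must be present", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate predictor(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  qr_rank <- qr(cbind(1, X))$rank
  if (qr_rank < ncol(X) + 1L) stop("predictor matrix is rank deficient", call. = FALSE)

  fits <- lapply(penalty_grid, function(l) ridge_logit_irls(X, yy, l))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("all fits failed; if the classes are separable use a positive penalty",
         call. = FALSE)
  }
  crit <- vapply(seq_along(fits), function(i) {
    if (!ok[i]) return(-Inf)
    f <- fits[[i]]
    idx <- lr_indexes(f$fitted, yy, f$deviance, length(yy))
    idx[["lr_chi2"]] - 2 * (f$df_eff - 1)  # slope df only, intercept always in
  }, numeric(1))
  best <- which.max(crit)
  fit <- fits[[best]]
  lambda <- penalty_grid[best]
  se <- sqrt(diag(fit$cov))
  wald_z <- fit$beta / se
  wald_p <- 2 * stats::pnorm(-abs(wald_z))
  coef_idx <- -1L   # drop intercept for the FDR family
  fdr_p <- fdr_adjust(wald_p[coef_idx])
  idx <- lr_indexes(fit$fitted, yy, fit$deviance, length(yy))
  structure(list(
    reference_sex = reference_sex,
    coefficients = fit$beta[coef_idx], intercept = fit$beta[[1L]],
    penalty = lambda, penalty_grid = penalty_grid, penalty_trace = crit,
    df_eff = fit$df_eff,
    wald_z = wald_z[coef_idx], wald_p = wald_p[coef_idx], fdr_p = fdr_p,
    significant = fdr_p <= alpha, alpha = alpha,
    apparent = idx[c("nagelkerke_r2", "c_index", "somers_dxy")],
    lr_chi2 = idx[["lr_chi2"]], deviance = fit$deviance,
    pclass = fit$fitted, y = yy, X = X,
    includes_tiv = "TIV" %in% colnames(X)
  ), class = "pclass_model")
}

#' @export
print.pclass_model <- function(x, ...) {
  cat(sprintf("Penalized LR sex classifier (reference: %s, lambda = %g)\n",
              x$reference_sex, x$penalty))
  cat(sprintf("  apparent R2 = %.3f, C = %.3f, Dxy = %.3f\n",
              x$apparent[["nagelkerke_r2"]], x$apparent[["c_index"]],
              x$apparent[["somers_dxy"]]))
  if (!is.null(x$corrected))
    cat(sprintf("  corrected R2 = %.3f, C = %.3f, Dxy = %.3f (%d boot reps)\n",
                x$corrected[["nagelkerke_r2"]], x$corrected[["c_index"]],
                x$corrected[["somers_dxy"]], x$n_validation))
  invisible(x)
}

#' Predict Pclass scores from a fitted model
#' @param object A `pclass_model`.
#' @param newdata Predictor matrix with the model's columns (default the
#'   training matrix).
#' @param ... Unused.
#' @return Vector of classification probabilities in \[0, 1\].
#' @export
predict.pclass_model <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  stats::plogis(object$intercept + drop(X %*% object$coefficients))
}

#' Bootstrap optimism correction of discrimination indexes
#'
#' Harrell's optimism bootstrap: refit the model (at its selected penalty)
#' on each resample, measure each index on the resample and on the original
#' data, average the difference (the optimism), and subtract it from the
#' apparent index. Applied to Nagelkerke R2, the C-index and Somers Dxy.
#'
#' @param model A `pclass_model`.
#' @param n_reps Bootstrap repetitions (default 200).
#' @param seed Integer seed.
#' @return The model with `corrected`, `optimism` and `n_validation`
#'   fields added; failed refits are skipped (error if more than 20% fail).
#' @export
bootstrap_validate <- function(model, n_reps = 200, seed = 1L) {
  stopifnot(inherits(model, "pclass_model"))
  X <- model$X; y <- model$y; n <- length(y)
  keys <- c("nagelkerke_r2", "c_index", "somers_dxy")
  opt <- with_seed(seed, {
    res <- matrix(NA_real_, n_reps, 3L, dimnames = list(NULL, keys))
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) next
      f <- ridge_logit_irls(X[idx, , drop = FALSE], y[idx], model$penalty)
      if (is.null(f)) next
      app <- lr_indexes(f$fitted, y[idx], f$deviance, n)[keys]
      eta0 <- f$beta[[1L]] + drop(X %*% f$beta[-1L])
      mu0 <- stats::plogis(eta0)
      dev0 <- -2 * sum(y * eta0 - log1pexp(eta0))
      tst <- lr_indexes(mu0, y, dev0, n)[keys]
      res[r, ] <- app - tst
    }
    res
  })
  failed <- sum(!stats::complete.cases(opt))
  if (failed > 0.2 * n_reps)
    stop(sprintf("%d of %d bootstrap refits failed", failed, n_reps), call. = FALSE)
  if (failed > 0)
    message(sprintf("skipped %d failed bootstrap refits", failed))
  optimism <- colMeans(opt, na.rm = TRUE)
  model$optimism <- optimism
  model$corrected <- model$apparent - optimism
  model$n_validation <- n_reps - failed
  model
}

#' Calibration curve of Pclass scores
#'
#' Equal-frequency bins of predicted probability against the observed
#' class fraction in each bin.
#'
#' @param model A `pclass_model`.
#' @param n_bins Number of bins (default 10; must not exceed n).
#' @return `data.frame` with `bin`, `n`, `mean_predicted`, `observed`.
#' @export
calibration_curve <- function(model, n_bins = 10L) {
  stopifnot(inherits(model, "pclass_model"))
  p <- model$pclass; y <- model$y
  if (n_bins > length(y)) stop("n_bins exceeds the number of subjects", call. = FALSE)
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(br) <= 2L) rep(1L, length(p))
         else as.integer(cut(p, br, include.lowest = TRUE))
  agg <- lapply(sort(unique(bin)), function(b) {
    data.frame(bin = b, n = sum(bin == b),
               mean_predicted = mean(p[bin == b]),
               observed = mean(y[bin == b]))
  })
  do.call(rbind, agg)
}

# ---- score sets -----------------------------------------------------------

#' Bundle per-subject continuous scores with sex labels
#'
#' @param score Numeric per-subject scores (Pclass probabilities or signed
#'   projected distances).
#' @param sex Factor/character F/M labels, same length.
#' @param kind `"pclass"` or `"distance"`.
#' @param reference_sex The sex toward which high scores point.
#' @return An object of class `score_set`.
#' @export
score_set <- function(score, sex, kind = c("pclass", "distance"),
                      reference_sex = "F") {
  kind <- match.arg(kind)
  sex <- factor(as.character(sex), levels = c("F", "M"))
  stopifnot(length(score) == length(sex), all(table(sex) > 0))
  if (kind == "pclass" && (any(score < 0) || any(score > 1)))
    stop("pclass scores must lie in [0, 1]", call. = FALSE)
  structure(list(score = as.numeric(score), sex = sex, kind = kind,
                 reference_sex = reference_sex), class = "score_set")
}

#' Robust battery on a set of multivariate scores
#'
#' Applies the univariate toolbox to one continuous score vector (Pclass
#' or projected distance): overlap, Cliff's delta / PS, empirical U3,
#' decile shift function, IQR ratio and skewness/kurtosis comparisons,
#' plus per-sex Harrell-Davis CDF deciles. For Pclass scores, it also
#' reports classification accuracy at the 0.5 cutoff: the fraction of the
#' reference sex at or above 0.5, the fraction of the other sex below it,
#' and their balanced mean.
#'
#' Group A is the reference sex throughout, so positive deltas mean the
#' reference sex scores higher.
#'
#' @param scores A [score_set()].
#' @param cfg A [bootstrap_config()].
#' @return List of battery components (`overlap`, `cliff`, `u3`, `deciles`,
#'   `iqr`, `skewness`, `kurtosis`, `cdf_deciles`, `moments`, and for
#'   Pclass `accuracy`).
#' @export
score_battery <- function(scores, cfg = bootstrap_config()) {
  stopifnot(inherits(scores, "score_set"))
  ref <- scores$reference_sex
  a <- scores$score[scores$sex == ref]
  b <- scores$score[scores$sex != ref]
  out <- list(
    reference_sex = ref,
    overlap = overlap_eta(a, b, cfg),
    cliff = cliff_delta_inference(a, b, cfg),
    u3 = cohens_u3_empirical(a, b, cfg),
    deciles = decile_shift_test(a, b, cfg),
    iqr = iqr_ratio_test(a, b, cfg),
    skewness = bootstrap_moment_difference(a, b, "skewness", cfg),
    kurtosis = bootstrap_moment_difference(a, b, "kurtosis", cfg),
    moments = data.frame(
      group = c("reference", "other"),
      skewness = c(sample_skewness(a), sample_skewness(b)),
      kurtosis = c(sample_kurtosis(a), sample_kurtosis(b)),
      iqr = c(diff(hd_quantile(a, c(0.25, 0.75))),
              diff(hd_quantile(b, c(0.25, 0.75))))
    ),
    cdf_deciles = data.frame(
      q = seq(0.1, 0.9, 0.1),
      reference = hd_quantile(a, seq(0.1, 0.9, 0.1)),
      other = hd_quantile(b, seq(0.1, 0.9, 0.1))
    )
  )
  if (scores$kind == "pclass") {
    acc_ref <- mean(a >= 0.5)
    acc_other <- mean(b < 0.5)
    out$accuracy <- c(reference = 100 * acc_ref, other = 100 * acc_other,
                      balanced = 100 * (acc_ref + acc_other) / 2)
  }
  out
}

#' All-pairwise difference summary of two groups' scores
#'
#' Computes every reference-minus-other pairwise difference, its
#' Harrell-Davis deciles, and the percent of differences favoring the
#' reference sex (ties excluded from numerator and denominator), with a
#' subject-level percentile-bootstrap CI. For Pclass scores a difference of
#' `x` is also `100 * x` percent of the maximum possible (POMP).
#'
#' @param scores A [score_set()].
#' @param cfg A [bootstrap_config()].
#' @param n_boot Bootstrap reps for the percent CI (default 500).
#' @param max_pairs Cap on `n_ref * n_other`; beyond it each group is
#'   subsampled (seeded) if `subsample = TRUE`, else an error.
#' @param subsample Allow seeded subsampling past the cap.
#' @return List with `deciles` (`data.frame`), `percent_favoring_reference`
#'   (an `effect_estimate` on the percent scale), `n_pairs`, `n_ties`,
#'   `pomp_deciles` (Pclass only).
#' @export
pairwise_difference_summary <- function(scores, cfg = bootstrap_config(),
                                        n_boot = 500, max_pairs = 4e6,
                                        subsample = TRUE) {
  stopifnot(inherits(scores, "score_set"))
  ref <- scores$reference_sex
  a <- scores$score[scores$sex == ref]
  b <- scores$score[scores$sex != ref]
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  if (length(a) * length(b) > max_pairs) {
    if (!subsample) stop("pair count exceeds max_pairs and subsampling is off",
                         call. = FALSE)
    k <- floor(sqrt(max_pairs))
    with_seed(cfg$seed + 7L, {
      if (length(a) > k) a <- sample(a, k)
      if (length(b) > k) b <- sample(b, k)
    })
  }
  d <- as.vector(outer(a, b, "-"))
  n_ties <- sum(d == 0)
  pct <- function(dd) {
    nz <- dd[dd != 0]
    if (!length(nz)) return(NA_real_)
    100 * mean(nz > 0)
  }
  pct_hat <- pct(d)
  boots <- with_seed(cfg$seed + 8L, {
    vapply(seq_len(n_boot), function(i) {
      pct(as.vector(outer(sample(a, replace = TRUE),
                          sample(b, replace = TRUE), "-")))
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(cfg$alpha / 2, 1 - cfg$alpha / 2),
                        names = FALSE, na.rm = TRUE)
  qs <- seq(0.1, 0.9, 0.1)
  dec <- data.frame(q = qs, diff = hd_quantile(d, qs))
  out <- list(deciles = dec,
              percent_favoring_reference = effect_estimate(pct_hat, ci[1L], ci[2L]),
              n_pairs = length(d), n_ties = n_ties)
  if (scores$kind == "pclass") out$pomp_deciles <- transform(dec, pomp = 100 * diff)
  out
}

#' Nomogram table of a fitted classifier
#'
#' Linear point scales: predictor j contributes
#' `points_j(x) = 100 * |b_j| * (x - x_j0) / max_k(|b_k| * range_k)` with
#' `x_j0` the end of the observed span that pushes away from the reference
#' class, so points always increase toward the reference sex and the most
#' influential predictor spans 0--100. Total points map back to Pclass
#' through the inverse logit of the reconstructed linear predictor.
#'
#' @param model A `pclass_model`.
#' @param X Predictor matrix defining the observed spans (default the
#'   training matrix).
#' @param sex Optional sex labels for median markers.
#' @return List with `scales` (`data.frame`: predictor, beta, range,
#'   max_points, plus per-sex median points when `sex` given),
#'   `total_points_to_pclass` (function), and `points_fun` (function of
#'   predictor name and value).
#' @export
build_nomogram <- function(model, X = model$X, sex = NULL) {
  stopifnot(inherits(model, "pclass_model"))
  X <- as.matrix(X)[, names(model$coefficients), drop = FALSE]
  beta <- model$coefficients
  if (all(beta == 0)) stop("all coefficients are zero; nomogram undefined", call. = FALSE)
  rng <- apply(X, 2, function(v) diff(range(v)))
  scale_max <- max(abs(beta) * rng)
  x0 <- ifelse(beta > 0, apply(X, 2, min), apply(X, 2, max))
  points_fun <- function(predictor, value) {
    100 * beta[[predictor]] * (value - x0[[predictor]]) / scale_max
  }
  scales <- data.frame(predictor = names(beta), beta = unname(beta),
                       range = unname(rng),
                       max_points = unname(100 * abs(beta) * rng / scale_max),
                       significant = unname(model$significant),
                       stringsAsFactors = FALSE)
  if (!is.null(sex)) {
    sex <- factor(as.character(sex), levels = c("F", "M"))
    for (s in c("F", "M")) {
      med <- apply(X[sex == s, , drop = FALSE], 2, stats::median)
      scales[[paste0("median_points_", s)]] <-
        vapply(seq_along(beta), function(j) points_fun(names(beta)[j], med[j]),
               numeric(1))
    }
  }
  offset <- model$intercept + sum(beta * x0)
  total_to_pclass <- function(total_points) {
    stats::plogis(offset + scale_max * total_points / 100)
  }
  list(scales = scales, total_points_to_pclass = total_to_pclass,
       points_fun = points_fun)
}

#' Compare the coefficient structure of several classifiers
#'
#' Pairwise absolute Spearman correlations between the models' region
#' coefficients (TIV excluded where present), and, when univariate tables
#' are supplied, each model's Spearman correlation between its coefficients
#' and the univariate medians' difference, Cliff's delta and Cohen's U3.
#'
#' @param models Named list of `pclass_model`s sharing the region
#'   predictors.
#' @param uni_tables Optional named list of `univariate_table`s; names must
#'   match `models` names (a model may be matched by prefix, e.g. model
#'   `raw_tiv` to table `raw`).
#' @return List with `coef_rho` (absolute-rho matrix) and `uni_rho`
#'   (`data.frame`, NULL when no tables given).
#' @export
compare_model_structure <- function(models, uni_tables = NULL) {
  stopifnot(is.list(models), length(models) >= 2L)
  coefs <- lapply(models, function(m) {
    b <- m$coefficients
    b[setdiff(names(b), "TIV")]
  })
  shared <- Reduce(intersect, lapply(coefs, names))
  if (length(shared) < 3L) stop("models share too few predictors", call. = FALSE)
  if (!all(vapply(coefs, function(b) setequal(names(b), shared), logical(1))))
    stop("models have mismatched region predictor sets", call. = FALSE)
  cm <- sapply(coefs, function(b) b[shared])
  k <- ncol(cm)
  rho <- matrix(1, k, k, dimnames = list(colnames(cm), colnames(cm)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- abs(stats::cor(cm[, i], cm[, j], method = "spearman"))
    rho[i, j] <- rho[j, i] <- r
  }
  uni_rho <- NULL
  if (!is.null(uni_tables)) {
    rows <- list()
    for (nm in names(models)) {
      tab_nm <- if (nm %in% names(uni_tables)) nm else
        names(uni_tables)[startsWith(nm, names(uni_tables))][1L]
      if (is.na(tab_nm) || is.null(uni_tables[[tab_nm]])) next
      uni <- uni_tables[[tab_nm]]
      b <- cm[, nm]
      u <- uni[match(shared, uni$roi), ]
      rows[[nm]] <- data.frame(
        model = nm, dataset = tab_nm,
        rho_vs_median_diff = stats::cor(b, u$shift, method = "spearman"),
        rho_vs_delta = stats::cor(b, u$delta, method = "spearman"),
        rho_vs_u3 = stats::cor(b, u$u3, method = "spearman"),
        stringsAsFactors = FALSE
      )
    }
    uni_rho <- do.call(rbind, rows)
  }
  list(coef_rho = rho, uni_rho = uni_rho)
}

#' Intersection analysis of significant predictors across models
#'
#' For every non-empty subset of models, lists the predictors whose
#' FDR-adjusted Wald tests are significant in exactly those models (the
#' upset-plot decomposition), plus a per-predictor count of models flagging
#' it.
#'
#' @param models Named list of `pclass_model`s (>= 2).
#' @return List with `membership` (logical predictor x model matrix),
#'   `counts` (named integer vector), and `intersections` (named list of
#'   predictor sets keyed by `model1+model2` patterns).
#' @export
significant_predictor_intersections <- function(models) {
  stopifnot(is.list(models), length(models) >= 2L)
  preds <- Reduce(union, lapply(models, function(m) names(m$coefficients)))
  memb <- sapply(models, function(m) {
    flags <- stats::setNames(rep(FALSE, length(preds)), preds)
    flags[names(m$coefficients)[m$significant]] <- TRUE
    flags
  })
  counts <- rowSums(memb)
  pattern <- apply(memb, 1L, function(r) paste(colnames(memb)[r], collapse = "+"))
  pattern[pattern == ""] <- "(none)"
  inter <- split(rownames(memb), pattern)
  list(membership = memb, counts = counts, intersections = inter)
}

#' Fit the TIV-augmented classifier
#'
#' Refits [fit_penalized_lr()] with robust-z TIV appended as an additional
#' predictor named `TIV`.
#'
#' @inheritParams fit_penalized_lr
#' @param tiv Per-subject total intracranial volumes (not constant).
#' @return A `pclass_model` with `includes_tiv = TRUE`.
#' @export
fit_tiv_augmented <- function(X, tiv, y, reference_sex = "F",
                              penalty_grid = c(0, 2^seq(-4, 8)), alpha = 0.05) {
  check_numeric_vec(tiv, "tiv", positive = TRUE)
  if (stats::var(tiv) == 0) stop("TIV is constant; degenerate predictor", call. = FALSE)
  Xa <- cbind(as.matrix(X), TIV = robust_z_transform(tiv))
  fit_penalized_lr(Xa, y, reference_sex, penalty_grid, alpha)
}
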