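# Two-sample robust estimators and bootstrap machinery.
#
# Every estimator here works on a pair of numeric vectors (typically robust
# z-scores of one region, split by sex) and returns point estimate,
# percentile-bootstrap or normal-theory confidence interval, and (where
# defined) a p-value. All bootstrap draws run under an explicit seed taken
# from the shared bootstrap_config, so whole batteries are reproducible
# end to end.

#' Bootstrap configuration
#'
#' Shared resampling settings for the robust two-sample batteries. The
#' defaults are the rep counts used throughout: 4000 for decile shift
#' functions, 1000 for the overlap index, 2000 for Cohen's U3 and 2000 for
#' moment (skewness/kurtosis/IQR) comparisons.
#'
#' @param n_boot_deciles,n_boot_overlap,n_boot_u3,n_boot_moments Bootstrap
#'   repetition counts (>= 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param seed Integer seed; each operation derives its own stream from it.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot_deciles = 4000, n_boot_overlap = 1000,
                             n_boot_u3 = 2000, n_boot_moments = 2000,
                             alpha = 0.05, seed = 1L) {
  counts <- c(n_boot_deciles, n_boot_overlap, n_boot_u3, n_boot_moments)
  if (any(counts < 1)) stop("bootstrap counts must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(n_boot_deciles = as.integer(n_boot_deciles),
                 n_boot_overlap = as.integer(n_boot_overlap),
                 n_boot_u3 = as.integer(n_boot_u3),
                 n_boot_moments = as.integer(n_boot_moments),
                 alpha = alpha, seed = as.integer(seed)),
            class = "bootstrap_config")
}

effect_estimate <- function(value, ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_, label = NA_character_, ...) {
  structure(list(value = value, ci_low = ci_low, ci_high = ci_high,
                 p = p, label = label, ...), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%.4f [%.4f, %.4f]", x$value, x$ci_low, x$ci_high))
  if (is.finite(x$p)) cat(sprintf("  p = %.4g", x$p))
  if (!is.na(x$label)) cat(sprintf("  (%s)", x$label))
  cat("\n")
  invisible(x)
}

#' Harrell-Davis quantile estimator
#'
#' Beta-weighted L-estimator of the `q`-th quantile: the order statistics
#' are averaged with weights `W_i = I(i/n) - I((i-1)/n)` where `I` is the
#' CDF of a Beta((n+1)q, (n+1)(1-q)) distribution.
#'
#' @param x Numeric sample (n >= 1).
#' @param q Probability, or vector of probabilities, in (0, 1).
#' @return Estimated quantile(s), one per element of `q`.
#' @export
hd_quantile <- function(x, q) {
  check_numeric_vec(x, "x")
  n <- length(x)
  if (n == 0L) stop("empty input", call. = FALSE)
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)", call. = FALSE)
  xs <- sort(x)
  vapply(q, function(qq) {
    a <- (n + 1) * qq
    b <- (n + 1) * (1 - qq)
    w <- stats::pbeta(seq_len(n) / n, a, b) - stats::pbeta((seq_len(n) - 1) / n, a, b)
    sum(w * xs)
  }, numeric(1))
}

# two-sided percentile-bootstrap p: smallest alpha at which the percentile
# CI of the bootstrap distribution excludes `null`
percentile_boot_p <- function(boot_stats, null = 0) {
  boot_stats <- boot_stats[is.finite(boot_stats)]
  if (!length(boot_stats)) return(NA_real_)
  p_low <- mean(boot_stats < null) + 0.5 * mean(boot_stats == null)
  min(1, 2 * min(p_low, 1 - p_low))
}

#' Decile shift function between two groups
#'
#' Harrell-Davis deciles of each group, their differences
#' `d_q = HD_q(A) - HD_q(B)` for q = 0.1..0.9, percentile-bootstrap
#' confidence intervals from independent within-group resampling, and
#' significance flags controlled for the nine decile comparisons via
#' Hochberg's sequentially rejective procedure. When the inputs are robust
#' z-scores the differences read directly on the Cohen's d scale.
#'
#' @param x_a,x_b Numeric samples (n >= 10 each; a warning below 20).
#' @param cfg A [bootstrap_config()].
#' @return `data.frame` with one row per decile: `q`, `hd_a`, `hd_b`,
#'   `diff`, `ci_low`, `ci_high`, `p`, `p_crit` (Hochberg critical value)
#'   and `significant`.
#' @export
decile_shift_test <- function(x_a, x_b, cfg = bootstrap_config()) {
  check_numeric_vec(x_a, "x_a"); check_numeric_vec(x_b, "x_b")
  if (length(x_a) < 10L || length(x_b) < 10L)
    stop("each group needs at least 10 observations", call. = FALSE)
  if (length(x_a) < 20L || length(x_b) < 20L)
    warning("group sizes below 20: decile estimates will be unstable")
  # estimators are permutation-symmetric; canonical sorted order makes the
  # bootstrap draws (hence CIs and p-values) invariant to subject ordering
  x_a <- sort(x_a); x_b <- sort(x_b)
  qs <- seq(0.1, 0.9, by = 0.1)
  hd_a <- hd_quantile(x_a, qs); hd_b <- hd_quantile(x_b, qs)
  d <- hd_a - hd_b
  boots <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_boot_deciles), function(i) {
      hd_quantile(sample(x_a, replace = TRUE), qs) -
        hd_quantile(sample(x_b, replace = TRUE), qs)
    }, numeric(length(qs)))
  })
  ci <- apply(boots, 1L, stats::quantile,
              probs = c(cfg$alpha / 2, 1 - cfg$alpha / 2), names = FALSE)
  p <- vapply(seq_along(qs), function(k) percentile_boot_p(boots[k, ]), numeric(1))
  # Hochberg step-up over the 9 deciles within this comparison
  m <- length(qs)
  ord <- order(p, decreasing = TRUE)
  crit <- cfg$alpha / seq_len(m)           # alpha/1 for largest p, alpha/m for smallest
  sig <- logical(m); reject_rest <- FALSE
  for (k in seq_len(m)) {
    if (!reject_rest && p[ord[k]] <= crit[k]) reject_rest <- TRUE
    sig[ord[k]] <- reject_rest
  }
  p_crit <- numeric(m); p_crit[ord] <- crit
  data.frame(q = qs, hd_a = hd_a, hd_b = hd_b, diff = d,
             ci_low = ci[1L, ], ci_high = ci[2L, ], p = p,
             p_crit = p_crit, significant = sig)
}

# pairwise dominance counts; returns list(gt, lt, eq, dij matrix optional)
cliff_counts <- function(x_a, x_b) {
  d <- sign(outer(x_a, x_b, "-"))
  list(delta_mat = d, delta = mean(d))
}

#' Cliff's delta and probability of superiority
#'
#' Exhaustive pair counting of `P(A > B)` and `P(A < B)`:
#' `ps_a = (#(a > b) + 0.5 #(a = b)) / (n_a n_b)` (ties split evenly) and
#' `delta = P(A > B) - P(A < B)`. Inference follows Cliff's method: the
#' consistent variance estimate of delta and an asymmetric normal-theory
#' interval that respects the \[-1, 1\] bounds.
#'
#' @param x_a,x_b Non-empty numeric samples.
#' @param cfg A [bootstrap_config()] (used for `alpha` only).
#' @return List with `ps_a`, `ps_b` and `delta` (an `effect_estimate` with
#'   CI and p).
#' @export
cliff_delta_inference <- function(x_a, x_b, cfg = bootstrap_config()) {
  check_numeric_vec(x_a, "x_a"); check_numeric_vec(x_b, "x_b")
  if (!length(x_a) || !length(x_b)) stop("empty group", call. = FALSE)
  n_a <- length(x_a); n_b <- length(x_b)
  cc <- cliff_counts(x_a, x_b)
  d_mat <- cc$delta_mat
  delta <- cc$delta
  ps_a <- (sum(d_mat == 1) + 0.5 * sum(d_mat == 0)) / (n_a * n_b)
  # Cliff's consistent variance estimate
  di_ <- rowMeans(d_mat); d_j <- colMeans(d_mat)
  s2 <- (n_b^2 * sum((di_ - delta)^2) + n_a^2 * sum((d_j - delta)^2) -
           sum((d_mat - delta)^2)) / (n_a * n_b * (n_a - 1) * (n_b - 1))
  s2 <- max(s2, 0)
  z <- stats::qnorm(1 - cfg$alpha / 2)
  if (abs(delta) == 1 || s2 == 0) {
    # degenerate: fall back to the boundary-consistent interval of Cliff
    s2 <- (1 - delta^2) / (min(n_a, n_b) - 1)
  }
  denom <- 1 - delta^2 + z^2 * s2
  half <- z * sqrt(s2) * sqrt((1 - delta^2)^2 + z^2 * s2)
  ci_low <- max(-1, (delta - delta^3 - half) / denom)
  ci_high <- min(1, (delta - delta^3 + half) / denom)
  p <- if (s2 > 0) 2 * stats::pnorm(-abs(delta) / sqrt(s2)) else 0
  list(ps_a = ps_a, ps_b = 1 - ps_a,
       delta = effect_estimate(delta, ci_low, ci_high, p = min(1, p)))
}

#' Global heteroscedastic rank test for a two-group shift
#'
#' Global location comparison in the Wilcoxon-Mann-Whitney family that does
#' not assume equal variances: the p-value comes from Cliff's dominance
#' method (see [cliff_delta_inference()]), and the shift is reported as the
#' difference of Harrell-Davis medians, `HD_0.5(A) - HD_0.5(B)`.
#'
#' @inheritParams cliff_delta_inference
#' @return List with `shift` (an `effect_estimate`; CI by normal-theory
#'   scaling of the delta interval is not attempted -- the CI fields carry
#'   the delta interval), `delta`, `ps_a`, `ps_b` and `p`.
#' @export
global_wmw_test <- function(x_a, x_b, cfg = bootstrap_config()) {
  ci <- cliff_delta_inference(x_a, x_b, cfg)
  shift <- hd_quantile(x_a, 0.5) - hd_quantile(x_b, 0.5)
  list(shift = effect_estimate(shift, p = ci$delta$p),
       delta = ci$delta, ps_a = ci$ps_a, ps_b = ci$ps_b, p = ci$delta$p)
}

# kernel density estimates of both groups on one common grid
kde_pair <- function(x_a, x_b, n_grid = 512L) {
  bw_a <- stats::bw.nrd0(x_a); bw_b <- stats::bw.nrd0(x_b)
  pad <- 3 * max(bw_a, bw_b)
  lo <- min(x_a, x_b) - pad; hi <- max(x_a, x_b) + pad
  da <- stats::density(x_a, bw = bw_a, from = lo, to = hi, n = n_grid)
  db <- stats::density(x_b, bw = bw_b, from = lo, to = hi, n = n_grid)
  list(grid = da$x, f_a = da$y, f_b = db$y)
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Distribution overlap index
#'
#' The eta overlap index: the area under the pointwise minimum of the two
#' kernel density estimates, a similarity measure in \[0, 1\] requiring no
#' symmetry or unimodality assumption. Gaussian kernels with Silverman
#' bandwidths per group, evaluated on a shared grid spanning the pooled
#' range plus three bandwidths, integrated by the trapezoid rule.
#' Percentile-bootstrap CI from `n_boot_overlap` within-group resamples.
#'
#' @param x_a,x_b Numeric samples (n >= 10 each).
#' @param cfg A [bootstrap_config()].
#' @return An `effect_estimate` with the overlap proportion in \[0, 1\].
#' @export
overlap_eta <- function(x_a, x_b, cfg = bootstrap_config()) {
  check_numeric_vec(x_a, "x_a"); check_numeric_vec(x_b, "x_b")
  if (length(x_a) < 10L || length(x_b) < 10L)
    stop("each group needs at least 10 observations", call. = FALSE)
  if (stats::var(x_a) == 0 || stats::var(x_b) == 0)
    stop("degenerate (zero-variance) group", call. = FALSE)
  # estimators are permutation-symmetric; canonical sorted order makes the
  # bootstrap draws (hence CIs and p-values) invariant to subject ordering
  x_a <- sort(x_a); x_b <- sort(x_b)
  est <- function(a, b) {
    k <- kde_pair(a, b)
    min(1, trapezoid(k$grid, pmin(k$f_a, k$f_b)))
  }
  eta <- est(x_a, x_b)
  boots <- with_seed(cfg$seed + 1L, {
    vapply(seq_len(cfg$n_boot_overlap), function(i) {
      est(sample(x_a, replace = TRUE), sample(x_b, replace = TRUE))
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(cfg$alpha / 2, 1 - cfg$alpha / 2), names = FALSE)
  effect_estimate(eta, ci[1L], ci[2L])
}

#' Empirical Cohen's U3
#'
#' Percent of group A strictly above the Harrell-Davis median of group B,
#' counted directly (no normality assumption), with a percentile-bootstrap
#' CI (`n_boot_u3` resamples of both groups).
#'
#' @inheritParams cliff_delta_inference
#' @return An `effect_estimate` on the percent scale (0--100).
#' @export
cohens_u3_empirical <- function(x_a, x_b, cfg = bootstrap_config()) {
  check_numeric_vec(x_a, "x_a"); check_numeric_vec(x_b, "x_b")
  if (!length(x_a) || !length(x_b)) stop("empty group", call. = FALSE)
  # estimators are permutation-symmetric; canonical sorted order makes the
  # bootstrap draws (hence CIs and p-values) invariant to subject ordering
  x_a <- sort(x_a); x_b <- sort(x_b)
  est <- function(a, b) 100 * mean(a > hd_quantile(b, 0.5))
  u3 <- est(x_a, x_b)
  boots <- with_seed(cfg$seed + 2L, {
    vapply(seq_len(cfg$n_boot_u3), function(i) {
      est(sample(x_a, replace = TRUE), sample(x_b, replace = TRUE))
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(cfg$alpha / 2, 1 - cfg$alpha / 2), names = FALSE)
  effect_estimate(u3, ci[1L], ci[2L])
}

#' Interquartile-ratio comparison (scale test)
#'
#' Interquartile ranges estimated as `HD_0.75 - HD_0.25` per group; a
#' Wald-type test on the log ratio `log(IQR_A / IQR_B)` with a bootstrap
#' standard error (`n_boot_moments` within-group resamples).
#'
#' @param x_a,x_b Numeric samples (n >= 10 each).
#' @param cfg A [bootstrap_config()].
#' @return An `effect_estimate` with the ratio `IQR_A / IQR_B`, its CI and
#'   Wald p-value; extra fields `iqr_a`, `iqr_b`.
#' @export
iqr_ratio_test <- function(x_a, x_b, cfg = bootstrap_config()) {
  check_numeric_vec(x_a, "x_a"); check_numeric_vec(x_b, "x_b")
  if (length(x_a) < 10L || length(x_b) < 10L)
    stop("each group needs at least 10 observations", call. = FALSE)
  # estimators are permutation-symmetric; canonical sorted order makes the
  # bootstrap draws (hence CIs and p-values) invariant to subject ordering
  x_a <- sort(x_a); x_b <- sort(x_b)
  iqr_hd <- function(x) diff(hd_quantile(x, c(0.25, 0.75)))
  iqr_a <- iqr_hd(x_a); iqr_b <- iqr_hd(x_b)
  if (iqr_a <= 0 || iqr_b <= 0) stop("zero interquartile range", call. = FALSE)
  lr <- log(iqr_a / iqr_b)
  boots <- with_seed(cfg$seed + 3L, {
    vapply(seq_len(cfg$n_boot_moments), function(i) {
      ba <- iqr_hd(sample(x_a, replace = TRUE))
      bb <- iqr_hd(sample(x_b, replace = TRUE))
      if (ba <= 0 || bb <= 0) NA_real_ else log(ba / bb)
    }, numeric(1))
  })
  se <- stats::sd(boots, na.rm = TRUE)
  z <- stats::qnorm(1 - cfg$alpha / 2)
  p <- 2 * stats::pnorm(-abs(lr) / se)
  effect_estimate(exp(lr), exp(lr - z * se), exp(lr + z * se), p = p,
                  iqr_a = iqr_a, iqr_b = iqr_b)
}

#' Sample skewness (moment estimator)
#' @param x Numeric vector.
#' @return `m3 / m2^(3/2)` with central moments `m_k`.
#' @export
sample_skewness <- function(x) {
  m <- mean(x); s <- x - m
  mean(s^3) / mean(s^2)^1.5
}

#' Sample kurtosis (moment estimator, non-excess)
#' @param x Numeric vector.
#' @return `m4 / m2^2`; a Gaussian sample gives values near 3.
#' @export
sample_kurtosis <- function(x) {
  m <- mean(x); s <- x - m
  mean(s^4) / mean(s^2)^2
}

#' Percentile-bootstrap comparison of a distribution moment
#'
#' Difference of the plug-in skewness or kurtosis estimator between two
#' groups, with percentile-bootstrap CI and p-value
#' `2 min(P*(diff < 0), P*(diff > 0))` from `n_boot_moments` within-group
#' resamples. Kurtosis is non-excess (Gaussian reference value 3).
#'
#' @param x_a,x_b Numeric samples (n >= 20 each).
#' @param moment `"skewness"` or `"kurtosis"`.
#' @param cfg A [bootstrap_config()].
#' @return An `effect_estimate` of the A - B difference; extra fields
#'   `est_a`, `est_b`.
#' @export
bootstrap_moment_difference <- function(x_a, x_b,
                                        moment = c("skewness", "kurtosis"),
                                        cfg = bootstrap_config()) {
  moment <- match.arg(moment)
  check_numeric_vec(x_a, "x_a"); check_numeric_vec(x_b, "x_b")
  if (length(x_a) < 20L || length(x_b) < 20L)
    stop("each group needs at least 20 observations", call. = FALSE)
  if (stats::var(x_a) == 0 || stats::var(x_b) == 0)
    stop("degenerate (zero-variance) group", call. = FALSE)
  # estimators are permutation-symmetric; canonical sorted order makes the
  # bootstrap draws (hence CIs and p-values) invariant to subject ordering
  x_a <- sort(x_a); x_b <- sort(x_b)
  f <- if (moment == "skewness") sample_skewness else sample_kurtosis
  est_a <- f(x_a); est_b <- f(x_b)
  d <- est_a - est_b
  boots <- with_seed(cfg$seed + 4L + (moment == "kurtosis"), {
    vapply(seq_len(cfg$n_boot_moments), function(i) {
      f(sample(x_a, replace = TRUE)) - f(sample(x_b, replace = TRUE))
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(cfg$alpha / 2, 1 - cfg$alpha / 2), names = FALSE)
  effect_estimate(d, ci[1L], ci[2L], p = percentile_boot_p(boots),
                  est_a = est_a, est_b = est_b)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; monotone and never below the raw values.
#'
#' @param p Vector of p-values in \[0, 1\] (NAs preserved).
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Magnitude benchmarks for effect sizes
#'
#' Classifies an effect size as negligible / small / medium / large using
#' the conventional benchmarks: |d| thresholds 0.2 / 0.5 / 0.8 for Cohen's
#' d-scale values, |delta| thresholds 0.147 / 0.33 / 0.474 for Cliff's
#' delta. Thresholds are configurable.
#'
#' @param value Finite effect-size value (sign ignored).
#' @param index `"cohen_d"` or `"cliff_delta"`.
#' @param thresholds Optional increasing numeric vector of three cut
#'   points overriding the defaults.
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
classify_magnitude <- function(value, index = c("cohen_d", "cliff_delta"),
                               thresholds = NULL) {
  index <- match.arg(index)
  if (!is.finite(value)) stop("effect size must be finite", call. = FALSE)
  if (is.null(thresholds))
    thresholds <- switch(index,
                         cohen_d = c(0.2, 0.5, 0.8),
                         cliff_delta = c(0.147, 0.33, 0.474))
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds))
  v <- abs(value)
  c("negligible", "small", "medium", "large")[findInterval(v, thresholds) + 1L]
}
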