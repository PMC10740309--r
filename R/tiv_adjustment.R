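# TIV adjustment by power-corrected proportions (PCP) and robust z-scoring.
#
# PCP divides each regional volume by TIV^b, where b is the slope of the
# log(VOL) ~ log(TIV) ordinary least-squares line fitted on the entire
# pooled sample (both sexes). Under a power-law generative model this
# removes the TIV dependence exactly. Both the raw and the adjusted volumes
# are then put on a common robust z scale so effect sizes are numerically
# comparable to conventional Cohen's d values.

#' Fit the PCP allometric exponent
#'
#' Ordinary least-squares slope of `log(vol)` on `log(tiv)` over the full
#' pooled sample (both sexes together).
#'
#' @param vol Positive per-subject volumes.
#' @param tiv Positive per-subject total intracranial volumes.
#' @return The fitted exponent `b_hat` (dimensionless scalar).
#' @export
fit_pcp_exponent <- function(vol, tiv) {
  check_numeric_vec(vol, "vol", positive = TRUE)
  check_numeric_vec(tiv, "tiv", positive = TRUE)
  if (length(vol) != length(tiv)) stop("'vol' and 'tiv' lengths differ", call. = FALSE)
  if (length(vol) < 3L) stop("need at least 3 subjects to fit the exponent", call. = FALSE)
  lt <- log(tiv)
  if (stats::var(lt) == 0) stop("TIV is constant; log-log fit is singular", call. = FALSE)
  lv <- log(vol)
  stats::cov(lv, lt) / stats::var(lt)
}

#' Power-corrected-proportions adjustment
#'
#' Element-wise `vol / tiv^b_hat`.
#'
#' @inheritParams fit_pcp_exponent
#' @param b_hat Allometric exponent, typically from [fit_pcp_exponent()].
#' @return Adjusted volumes (positive, same length as `vol`).
#' @export
pcp_adjust <- function(vol, tiv, b_hat) {
  check_numeric_vec(vol, "vol", positive = TRUE)
  check_numeric_vec(tiv, "tiv", positive = TRUE)
  stopifnot(length(b_hat) == 1L, is.finite(b_hat))
  vol / tiv^b_hat
}

#' Robust z-score transform
#'
#' `0.6745 * (x - median(x)) / MAD(x)` with MAD the raw (unscaled) median
#' absolute deviation from the median. The 0.6745 factor puts the MAD on
#' the scale of a normal standard deviation, so the scores can be read as
#' conventional z-scores.
#'
#' @param x Numeric vector.
#' @return Robust z-scores, same length as `x`.
#' @export
robust_z_transform <- function(x) {
  check_numeric_vec(x, "x")
  med <- stats::median(x)
  mad_raw <- stats::median(abs(x - med))
  if (mad_raw == 0)
    stop("degenerate scale: median absolute deviation is zero", call. = FALSE)
  0.6745 * (x - med) / mad_raw
}

#' Proportion of volume variance explained by TIV
#'
#' Coefficient of determination of the simple linear regression
#' `vol ~ tiv`, on the volume scale by default (set `log_scale = TRUE` for
#' the log-log variant).
#'
#' @inheritParams fit_pcp_exponent
#' @param log_scale Regress log(vol) on log(tiv) instead.
#' @return R-squared in \[0, 1\].
#' @export
tiv_variance_explained <- function(vol, tiv, log_scale = FALSE) {
  check_numeric_vec(vol, "vol")
  check_numeric_vec(tiv, "tiv")
  if (length(vol) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (stats::var(tiv) == 0) stop("TIV is constant; R^2 undefined", call. = FALSE)
  if (log_scale) { vol <- log(vol); tiv <- log(tiv) }
  stats::cor(vol, tiv)^2
}

#' Build the raw and PCP analysis datasets
#'
#' From one cohort table, constructs the two parallel datasets on which the
#' whole analysis runs twice: robust z-scores of the raw volumes, and robust
#' z-scores of the PCP-adjusted volumes. Each dataset carries the per-region
#' TIV variance-explained (`tiv_r2`) computed on its own (raw or adjusted)
#' volumes; the PCP dataset also carries the fitted exponents.
#'
#' @param cohort Cohort `data.frame` as produced by [generate_cohort()] or
#'   [read_cohort_table()].
#' @param tiv_r2_log_scale Compute `tiv_r2` on the log scale (default
#'   volume scale).
#' @return Named list with elements `raw` and `pcp`, each an
#'   `analysis_dataset`: list with `kind`, `zscores` (subject x region
#'   matrix), `sex`, `subject_id`, `tiv`, `b_hat` (PCP only), `tiv_r2`.
#' @export
build_datasets <- function(cohort, tiv_r2_log_scale = FALSE) {
  cohort <- validate_cohort(cohort)
  rois <- setdiff(names(cohort), c("subject_id", "sex", "tiv_ml"))
  tiv <- cohort$tiv_ml
  raw_z <- pcp_z <- matrix(NA_real_, nrow(cohort), length(rois),
                           dimnames = list(cohort$subject_id, rois))
  b_hat <- r2_raw <- r2_pcp <- stats::setNames(numeric(length(rois)), rois)
  for (j in seq_along(rois)) {
    v <- cohort[[rois[j]]]
    if (stats::var(v) == 0)
      stop(sprintf("region '%s' has constant volumes", rois[j]), call. = FALSE)
    b_hat[j] <- fit_pcp_exponent(v, tiv)
    adj <- pcp_adjust(v, tiv, b_hat[j])
    raw_z[, j] <- tryCatch(robust_z_transform(v), error = function(e)
      stop(sprintf("region '%s': %s", rois[j], conditionMessage(e)), call. = FALSE))
    pcp_z[, j] <- tryCatch(robust_z_transform(adj), error = function(e)
      stop(sprintf("region '%s': %s", rois[j], conditionMessage(e)), call. = FALSE))
    r2_raw[j] <- tiv_variance_explained(v, tiv, log_scale = tiv_r2_log_scale)
    r2_pcp[j] <- tiv_variance_explained(adj, tiv, log_scale = tiv_r2_log_scale)
  }
  mk <- function(kind, z, r2, b = NULL) {
    structure(list(kind = kind, zscores = z, sex = cohort$sex,
                   subject_id = cohort$subject_id, tiv = tiv,
                   b_hat = b, tiv_r2 = r2),
              class = "analysis_dataset")
  }
  list(raw = mk("raw", raw_z, r2_raw),
       pcp = mk("pcp", pcp_z, r2_pcp, b_hat))
}

#' Per-region adjustment summary table
#'
#' @param datasets Output of [build_datasets()].
#' @return `data.frame` with columns `roi`, `b_hat`, `tiv_r2_raw`,
#'   `tiv_r2_pcp`.
#' @export
adjustment_table <- function(datasets) {
  data.frame(roi = colnames(datasets$raw$zscores),
             b_hat = unname(datasets$pcp$b_hat),
             tiv_r2_raw = unname(datasets$raw$tiv_r2),
             tiv_r2_pcp = unname(datasets$pcp$tiv_r2),
             stringsAsFactors = FALSE)
}

# schema validation shared by build_datasets and the CSV reader
validate_cohort <- function(cohort, roi_labels = NULL) {
  if (!is.data.frame(cohort)) stop("cohort must be a data.frame", call. = FALSE)
  required <- c("subject_id", "sex", "tiv_ml")
  missing <- setdiff(required, names(cohort))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(roi_labels)) {
    miss_roi <- setdiff(roi_labels, names(cohort))
    if (length(miss_roi))
      stop("missing region column(s): ", paste(miss_roi, collapse = ", "), call. = FALSE)
  }
  sex_chr <- as.character(cohort$sex)
  bad_sex <- setdiff(unique(sex_chr), c("F", "M"))
  if (length(bad_sex))
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "),
         "; accepted codes are F, M", call. = FALSE)
  if (length(unique(sex_chr)) < 2L)
    stop("both sex levels (F and M) must be present", call. = FALSE)
  cohort$sex <- factor(sex_chr, levels = c("F", "M"))
  rois <- setdiff(names(cohort), required)
  if (!length(rois)) stop("no region volume columns found", call. = FALSE)
  for (col in c("tiv_ml", rois)) {
    v <- cohort[[col]]
    if (!is.numeric(v)) stop(sprintf("column '%s' is not numeric", col), call. = FALSE)
    if (any(!is.finite(v)))
      stop(sprintf("column '%s' contains missing or non-finite values", col), call. = FALSE)
    if (any(v <= 0))
      stop(sprintf("column '%s' contains non-positive values (rows %s)", col,
                   paste(utils::head(which(v <= 0), 5L), collapse = ", ")), call. = FALSE)
  }
  cohort
}
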