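# Per-region univariate battery: five complementary robust comparisons of
# the female and male distributions of each region's robust z-scores, with
# Benjamini-Hochberg FDR control across regions within each test family.
#
# Convention used throughout: group A = females, group B = males, so a
# positive shift / delta / PS-F advantage means F > M.

#' Run the five-part univariate comparison battery
#'
#' For every region of an analysis dataset, compares the female and male
#' robust z-score distributions with: (1) a global heteroscedastic rank
#' test with Harrell-Davis median shift, (2) the eta overlap index, (3) the
#' decile shift function, (4) Cliff's delta / probability of superiority
#' plus empirical Cohen's U3, and (5) spread and shape comparisons
#' (interquartile ratio, skewness, kurtosis). FDR adjustment is applied
#' across the regions within each test family; magnitude labels use the
#' standard Cohen's d and Cliff's delta benchmarks.
#'
#' @param ds An `analysis_dataset` from [build_datasets()].
#' @param cfg A [bootstrap_config()]; per-region streams are derived from
#'   its seed.
#' @return An object of class `univariate_table`: a `data.frame` with one
#'   row per region (global test, overlap, delta/PS/U3, IQR, moments,
#'   direction) plus attributes `deciles` (long `data.frame` of the decile
#'   shift functions) and `kind`.
#' @export
run_univariate_battery <- function(ds, cfg = bootstrap_config()) {
  stopifnot(inherits(ds, "analysis_dataset"))
  rois <- colnames(ds$zscores)
  is_f <- ds$sex == "F"
  if (sum(is_f) < 10L || sum(!is_f) < 10L)
    stop("each sex needs at least 10 subjects", call. = FALSE)
  roi_seeds <- derive_seeds(cfg$seed, paste0("uni_", rois))
  rows <- vector("list", length(rois))
  dec_rows <- vector("list", length(rois))
  for (j in seq_along(rois)) {
    roi <- rois[j]
    f <- ds$zscores[is_f, j]; m <- ds$zscores[!is_f, j]
    cfg_j <- cfg; cfg_j$seed <- roi_seeds[[j]]
    res <- tryCatch({
      gw <- global_wmw_test(f, m, cfg_j)
      ov <- overlap_eta(f, m, cfg_j)
      dec <- decile_shift_test(f, m, cfg_j)
      cd <- cliff_delta_inference(f, m, cfg_j)
      u3 <- cohens_u3_empirical(f, m, cfg_j)
      iq <- iqr_ratio_test(f, m, cfg_j)
      sk <- bootstrap_moment_difference(f, m, "skewness", cfg_j)
      ku <- bootstrap_moment_difference(f, m, "kurtosis", cfg_j)
      list(gw = gw, ov = ov, dec = dec, cd = cd, u3 = u3,
           iq = iq, sk = sk, ku = ku)
    }, error = function(e) {
      stop(sprintf("region '%s': %s", roi, conditionMessage(e)), call. = FALSE)
    })
    rows[[j]] <- data.frame(
      roi = roi,
      shift = res$gw$shift$value, global_p = res$gw$p,
      overlap = res$ov$value, overlap_ci_low = res$ov$ci_low,
      overlap_ci_high = res$ov$ci_high,
      ps_f = res$cd$ps_a, ps_m = res$cd$ps_b,
      delta = res$cd$delta$value, delta_ci_low = res$cd$delta$ci_low,
      delta_ci_high = res$cd$delta$ci_high, delta_p = res$cd$delta$p,
      u3 = res$u3$value, u3_ci_low = res$u3$ci_low, u3_ci_high = res$u3$ci_high,
      iqr_ratio = res$iq$value, iqr_p = res$iq$p,
      skew_diff = res$sk$value, skew_p = res$sk$p,
      kurt_diff = res$ku$value, kurt_p = res$ku$p,
      stringsAsFactors = FALSE
    )
    dec_rows[[j]] <- cbind(roi = roi, res$dec, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  # FDR families: one BH correction per test family across regions
  tab$global_fdr_p <- fdr_adjust(tab$global_p)
  tab$delta_fdr_p <- fdr_adjust(tab$delta_p)
  tab$iqr_fdr_p <- fdr_adjust(tab$iqr_p)
  tab$skew_fdr_p <- fdr_adjust(tab$skew_p)
  tab$kurt_fdr_p <- fdr_adjust(tab$kurt_p)
  tab$shift_label <- vapply(tab$shift, classify_magnitude, character(1),
                            index = "cohen_d")
  tab$delta_label <- vapply(tab$delta, classify_magnitude, character(1),
                            index = "cliff_delta")
  sig <- tab$global_fdr_p <= cfg$alpha | tab$delta_fdr_p <= cfg$alpha
  tab$direction <- ifelse(!sig, "none", ifelse(tab$delta > 0, "F>M", "M>F"))
  structure(tab, deciles = do.call(rbind, dec_rows), kind = ds$kind,
            alpha = cfg$alpha, class = c("univariate_table", "data.frame"))
}

#' Decile shift functions of a univariate battery
#' @param uni A `univariate_table`.
#' @return Long `data.frame` with one row per region x decile.
#' @export
battery_deciles <- function(uni) attr(uni, "deciles")

#' Correlation of sex-difference estimates with TIV variance explained
#'
#' Spearman's rho between the per-region proportion of variance explained
#' by TIV and each sex-difference/similarity estimate: the nine decile
#' differences, Cliff's delta, Cohen's U3, and the overlap percent --
#' twelve rows per dataset. Large positive correlations for raw volumes and
#' near-zero ones after PCP adjustment indicate that raw-scale differences
#' track gross head-size scaling.
#'
#' Decile differences enter signed (not in absolute value), oriented
#' toward the dataset's dominant direction: when the median Cliff's delta
#' across regions is negative (M > F overall, as in raw volumes), the
#' signed statistics are flipped to read superior-sex-minus-other, the
#' convention of the source tables. Set `orient = "f_minus_m"` to keep the
#' package-wide F-minus-M signs instead.
#'
#' @param uni A `univariate_table` from [run_univariate_battery()].
#' @param ds The `analysis_dataset` the battery was computed on.
#' @param orient `"dominant"` (default) or `"f_minus_m"`.
#' @return `data.frame` with columns `statistic`, `rho`, `p`, `fdr_p`.
#' @export
tiv_dependence_correlation <- function(uni, ds,
                                       orient = c("dominant", "f_minus_m")) {
  orient <- match.arg(orient)
  stopifnot(inherits(uni, "univariate_table"), inherits(ds, "analysis_dataset"))
  r2 <- ds$tiv_r2[uni$roi]
  if (anyNA(r2)) stop("missing tiv_r2 for some regions", call. = FALSE)
  if (stats::var(r2) == 0)
    stop("tiv_r2 constant across regions; rank correlation undefined", call. = FALSE)
  dec <- battery_deciles(uni)
  flip <- if (orient == "dominant" && stats::median(uni$delta) < 0) -1 else 1
  stats_list <- c(
    stats::setNames(lapply(seq(0.1, 0.9, 0.1), function(qq) {
      d <- dec[abs(dec$q - qq) < 1e-9, ]
      stats::setNames(flip * d$diff, d$roi)[uni$roi]
    }), sprintf("decile_%.1f", seq(0.1, 0.9, 0.1))),
    list(cliff_delta = stats::setNames(flip * uni$delta, uni$roi),
         cohens_u3 = stats::setNames(
           if (flip < 0) 100 - uni$u3 else uni$u3, uni$roi),
         overlap = stats::setNames(uni$overlap, uni$roi))
  )
  rows <- lapply(names(stats_list), function(nm) {
    v <- stats_list[[nm]][uni$roi]
    ct <- suppressWarnings(stats::cor.test(r2, v, method = "spearman"))
    data.frame(statistic = nm, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- fdr_adjust(out$p)
  out
}
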