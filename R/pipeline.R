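# End-to-end orchestration: read a cohort, build the raw and PCP datasets,
# run the univariate batteries, fit and validate the classifiers (with and
# without TIV), run the projection analysis, and bundle every table for a
# tidy on-disk report. Deterministic under a single master seed: every
# stochastic stage draws its own stream via derive_seeds().

#' Read and validate a cohort CSV
#'
#' Expects columns `subject_id`, `sex` (F/M), `tiv_ml`, then one positive
#' volume column per region. Schema violations raise informative errors
#' naming the offending column or rows.
#'
#' @param path CSV file path.
#' @param roi_labels Optional required region columns (default: any
#'   non-metadata columns are accepted as regions).
#' @return A validated cohort `data.frame` with `sex` as a factor.
#' @export
read_cohort_table <- function(path, roi_labels = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(raw, roi_labels = roi_labels)
}

#' Configure a full pipeline run
#'
#' @param n_boot_deciles,n_boot_overlap,n_boot_u3,n_boot_moments Bootstrap
#'   reps per family (see [bootstrap_config()]); pipeline defaults are
#'   reduced (500/250/250/250) for desk-scale runtime.
#' @param alpha Significance level.
#' @param penalty_grid Ridge penalty grid for the classifiers.
#' @param n_validation Optimism-bootstrap repetitions (default 50).
#' @param seed Master seed.
#' @param datasets Which datasets to analyse: `"both"`, `"raw"` or `"pcp"`.
#' @param with_tiv_models Also fit the TIV-augmented classifiers.
#' @param pairwise_max_pairs Cap for the all-pairwise difference summary.
#' @return A `run_config` list.
#' @export
run_config <- function(n_boot_deciles = 500, n_boot_overlap = 250,
                       n_boot_u3 = 250, n_boot_moments = 250,
                       alpha = 0.05, penalty_grid = c(0, 2^seq(-4, 8)),
                       n_validation = 50, seed = 1L,
                       datasets = c("both", "raw", "pcp"),
                       with_tiv_models = TRUE, pairwise_max_pairs = 4e6) {
  datasets <- match.arg(datasets)
  if (n_validation < 1) stop("n_validation must be >= 1", call. = FALSE)
  structure(list(
    boot = bootstrap_config(n_boot_deciles, n_boot_overlap, n_boot_u3,
                            n_boot_moments, alpha, seed),
    alpha = alpha, penalty_grid = penalty_grid,
    n_validation = as.integer(n_validation), seed = as.integer(seed),
    datasets = datasets, with_tiv_models = isTRUE(with_tiv_models),
    pairwise_max_pairs = pairwise_max_pairs
  ), class = "run_config")
}

#' Run the full two-dataset analysis
#'
#' Executes, per selected dataset (raw and/or PCP): the univariate battery
#' and the TIV-dependence correlation table; reference-category selection;
#' the penalized logistic classifier with optimism-bootstrap validation and
#' calibration (optionally also TIV-augmented); the Pclass score battery,
#' all-pairwise difference summary and nomogram; the projection analysis
#' with Q, R2 and the cross-method comparison; and, when both datasets run,
#' the cross-model structure and significant-predictor intersection
#' reports.
#'
#' @param cohort A validated cohort `data.frame`.
#' @param cfg A [run_config()].
#' @return An object of class `report_bundle` (a nested list of tables and
#'   fitted objects plus a reproducibility manifest).
#' @export
run_full_analysis <- function(cohort, cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- validate_cohort(cohort)
  t0 <- Sys.time()
  ds_all <- build_datasets(cohort)
  wanted <- if (cfg$datasets == "both") c("raw", "pcp") else cfg$datasets
  seeds <- derive_seeds(cfg$seed, c(
    paste0("uni_", wanted), paste0("lr_val_", wanted),
    paste0("lr_val_tiv_", wanted), paste0("scores_", wanted),
    paste0("proj_", wanted)
  ))
  bundle <- list(adjustment = adjustment_table(ds_all), datasets = list(),
                 models = list())
  for (kind in wanted) {
    ds <- ds_all[[kind]]
    boot_u <- cfg$boot; boot_u$seed <- seeds[[paste0("uni_", kind)]]
    uni <- run_univariate_battery(ds, boot_u)
    tivdep <- tiv_dependence_correlation(uni, ds)
    ref <- select_reference_category(uni)
    model <- fit_penalized_lr(ds$zscores, ds$sex, reference_sex = ref,
                              penalty_grid = cfg$penalty_grid, alpha = cfg$alpha)
    model <- bootstrap_validate(model, cfg$n_validation,
                                seed = seeds[[paste0("lr_val_", kind)]])
    calib <- calibration_curve(model)
    boot_s <- cfg$boot; boot_s$seed <- seeds[[paste0("scores_", kind)]]
    pclass <- score_set(model$pclass, ds$sex, "pclass", reference_sex = ref)
    battery <- score_battery(pclass, boot_s)
    pairwise <- pairwise_difference_summary(pclass, boot_s,
                                            max_pairs = cfg$pairwise_max_pairs)
    nomogram <- build_nomogram(model, sex = ds$sex)
    # projection: F subjects are group A, M group B
    boot_p <- cfg$boot; boot_p$seed <- seeds[[paste0("proj_", kind)]]
    proj <- project_onto_center_line(ds$zscores[ds$sex == "F", , drop = FALSE],
                                     ds$zscores[ds$sex == "M", , drop = FALSE])
    proj_ps <- projection_ps_inference(proj, boot_p)
    proj_ps_holdout <- projection_ps_split(
      ds$zscores[ds$sex == "F", , drop = FALSE],
      ds$zscores[ds$sex == "M", , drop = FALSE], boot_p)
    tiv_ord <- c(ds$tiv[ds$sex == "F"], ds$tiv[ds$sex == "M"])
    pclass_ord <- score_set(
      c(pclass$score[ds$sex == "F"], pclass$score[ds$sex == "M"]),
      rep(c("F", "M"), c(sum(ds$sex == "F"), sum(ds$sex == "M"))),
      "pclass", reference_sex = ref)
    crossm <- crossmethod_comparison(pclass_ord, proj, boot_p, tiv = tiv_ord)
    model_tiv <- NULL
    if (cfg$with_tiv_models) {
      model_tiv <- fit_tiv_augmented(ds$zscores, ds$tiv, ds$sex,
                                     reference_sex = ref,
                                     penalty_grid = cfg$penalty_grid,
                                     alpha = cfg$alpha)
      model_tiv <- bootstrap_validate(model_tiv, cfg$n_validation,
                                      seed = seeds[[paste0("lr_val_tiv_", kind)]])
    }
    bundle$datasets[[kind]] <- list(
      univariate = uni, deciles = battery_deciles(uni),
      tiv_dependence = tivdep, reference_sex = ref,
      calibration = calib, score_battery = battery,
      pairwise = pairwise, nomogram = nomogram$scales,
      projection = proj, projection_ps = proj_ps,
      projection_ps_holdout = proj_ps_holdout,
      projection_q = q_statistic(proj$dist_a, proj$dist_b),
      projection_r2 = projection_r2(proj),
      crossmethod = crossm
    )
    bundle$models[[kind]] <- model
    if (!is.null(model_tiv)) bundle$models[[paste0(kind, "_tiv")]] <- model_tiv
  }
  if (length(bundle$models) >= 2L) {
    uni_tabs <- lapply(bundle$datasets, `[[`, "univariate")
    bundle$structure <- compare_model_structure(bundle$models, uni_tabs)
    bundle$intersections <- significant_predictor_intersections(bundle$models)
  }
  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("sexvoldiff")),
    r_version = R.version.string,
    seed = cfg$seed, derived_seeds = as.list(seeds),
    alpha = cfg$alpha, datasets = wanted,
    n_subjects = nrow(cohort), n_regions = ncol(ds_all$raw$zscores),
    bootstrap = unclass(cfg$boot)[1:4],
    n_validation = cfg$n_validation,
    penalty_grid = cfg$penalty_grid,
    with_tiv_models = cfg$with_tiv_models,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  class(bundle) <- "report_bundle"
  bundle
}

# flatten helpers for CSV emission -----------------------------------------

model_summary_table <- function(models) {
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    data.frame(model = nm, predictor = names(m$coefficients),
               coefficient = unname(m$coefficients),
               wald_z = unname(m$wald_z), wald_p = unname(m$wald_p),
               fdr_p = unname(m$fdr_p), significant = unname(m$significant),
               reference_sex = m$reference_sex, penalty = m$penalty,
               apparent_r2 = m$apparent[["nagelkerke_r2"]],
               apparent_c = m$apparent[["c_index"]],
               corrected_r2 = if (!is.null(m$corrected)) m$corrected[["nagelkerke_r2"]] else NA,
               corrected_c = if (!is.null(m$corrected)) m$corrected[["c_index"]] else NA,
               corrected_dxy = if (!is.null(m$corrected)) m$corrected[["somers_dxy"]] else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' Emits tidy CSV tables (adjustment, univariate families, deciles,
#' TIV-dependence, model summaries, nomograms, score batteries, pairwise
#' summaries, projection / cross-method tables, intersections) plus a JSON
#' manifest listing every file with its MD5 checksum and the full
#' reproducibility record (seed, derived seeds, settings).
#'
#' @param bundle A `report_bundle`.
#' @param outdir Output directory.
#' @param overwrite Allow writing into a non-empty existing directory.
#' @return Invisible character vector of written file paths.
#' @export
write_report_bundle <- function(bundle, outdir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!length(bundle$datasets)) stop("empty bundle", call. = FALSE)
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
    stop("output directory is not empty; pass overwrite = TRUE", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  put(bundle$adjustment, "adjustment")
  for (kind in names(bundle$datasets)) {
    d <- bundle$datasets[[kind]]
    put(as.data.frame(d$univariate), paste0("univariate_", kind))
    put(d$deciles, paste0("deciles_", kind))
    put(d$tiv_dependence, paste0("tiv_dependence_", kind))
    put(d$calibration, paste0("calibration_", kind))
    put(d$nomogram, paste0("nomogram_", kind))
    put(d$pairwise$deciles, paste0("pairwise_deciles_", kind))
    put(d$crossmethod$table, paste0("crossmethod_", kind))
    put(d$crossmethod$correlations, paste0("score_correlations_", kind))
    put(data.frame(subject = seq_along(c(d$projection$dist_a, d$projection$dist_b)),
                   group = rep(c("F", "M"), c(length(d$projection$dist_a),
                                              length(d$projection$dist_b))),
                   projected_distance = c(d$projection$dist_a, d$projection$dist_b)),
        paste0("projected_distances_", kind))
  }
  put(model_summary_table(bundle$models), "model_summaries")
  if (!is.null(bundle$structure)) {
    put(as.data.frame(bundle$structure$coef_rho), "coef_rho_matrix")
    if (!is.null(bundle$structure$uni_rho)) put(bundle$structure$uni_rho, "coef_uni_rho")
  }
  if (!is.null(bundle$intersections)) {
    memb <- bundle$intersections$membership
    put(data.frame(predictor = rownames(memb), memb,
                   n_models = bundle$intersections$counts,
                   row.names = NULL), "significant_predictor_intersections")
  }
  manifest <- bundle$manifest
  manifest$files <- lapply(files, function(f)
    list(name = basename(f), md5 = unname(tools::md5sum(f))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)
  invisible(files)
}
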