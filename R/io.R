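.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(ril_error("ril_schema_error",
                   sprintf("%s is missing required column(s): %s", what,
                           paste(miss, collapse = ", "))))
  }
}

#' Read a long-format blood-count table
#'
#' Expects columns `patient_id`, `alc` and either `day` (integer days from
#' RT start) or `date` plus a per-patient RT start date supplied via
#' `rt_start`. Values are sanity-checked for units (a median ALC above 20
#' suggests cells/uL rather than 10^3/uL) and patients with fewer than
#' three measurements are excluded with a reason, mirroring the cohort
#' inclusion rule of at least three blood morphology results.
#'
#' @param path CSV file path.
#' @param rt_start Optional data frame `patient_id`, `rt_start` (dates)
#'   used when the file carries a `date` column instead of `day`.
#' @return List with `blood` (included rows, sorted by patient and day)
#'   and `excluded` (`patient_id`, `reason`).
#' @export
read_blood_csv <- function(path, rt_start = NULL) {
  if (!file.exists(path)) {
    stop(ril_error("ril_io_error", sprintf("file not found: %s", path)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("patient_id", "alc"), "blood table")
  if (!"day" %in% names(df)) {
    .require_cols(df, "date", "blood table")
    if (is.null(rt_start)) {
      stop(ril_error("ril_schema_error",
                     "blood table has dates; supply rt_start (patient_id, rt_start)"))
    }
    start <- as.Date(rt_start$rt_start[match(df$patient_id,
                                             rt_start$patient_id)])
    df$day <- as.integer(as.Date(df$date) - start)
  }
  bad <- which(!is.finite(df$alc) | df$alc < 0 | !is.finite(df$day))
  if (length(bad)) {
    stop(ril_error("ril_schema_error",
                   sprintf("unparseable or negative ALC/day at row(s): %s",
                           paste(utils::head(bad, 5), collapse = ", "))))
  }
  if (stats::median(df$alc) > 20) {
    warning("median ALC exceeds 20; values may be in cells/uL, expected 10^3/uL")
  }
  counts <- table(df$patient_id)
  too_few <- names(counts)[counts < 3]
  excluded <- data.frame(patient_id = too_few,
                         reason = rep("fewer than 3 counts", length(too_few)),
                         stringsAsFactors = FALSE)
  blood <- df[!df$patient_id %in% too_few, c("patient_id", "day", "alc",
                                             intersect("anc", names(df)))]
  blood <- blood[order(blood$patient_id, blood$day), , drop = FALSE]
  rownames(blood) <- NULL
  list(blood = blood, excluded = excluded)
}

#' Read the per-patient clinical table
#' @param path CSV with columns `patient_id`, `technique`, `crt`,
#'   `total_dose_gy`, `n_fractions`, `ptv_cm3` (plus optional covariates).
#' @return Data frame.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("patient_id", "technique", "crt", "total_dose_gy",
                      "n_fractions", "ptv_cm3"), "clinical table")
  df
}

#' Read a long-format DVH table into the wide per-structure form
#'
#' @param path CSV with columns `patient_id`, `structure`, `metric`,
#'   `value` where `metric` is `Dmin`, `Dmax`, `Dmean` or `V<x>` on the
#'   standard grid.
#' @param validate Stop (with the offending patients and structures) when
#'   any record fails [validate_cdvh()] (default TRUE).
#' @return Wide DVH table (one row per patient x structure).
#' @export
read_dvh_csv <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_cols(df, c("patient_id", "structure", "metric", "value"),
                "DVH table")
  unknown <- setdiff(unique(df$metric), dvh_metric_names())
  if (length(unknown)) {
    stop(ril_error("ril_schema_error",
                   sprintf("unknown DVH metric(s): %s",
                           paste(unknown, collapse = ", "))))
  }
  wide <- stats::reshape(df, idvar = c("patient_id", "structure"),
                         timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  names(wide)[names(wide) == "Dmin"] <- "d_min"
  names(wide)[names(wide) == "Dmax"] <- "d_max"
  names(wide)[names(wide) == "Dmean"] <- "d_mean"
  wide <- wide[, c("patient_id", "structure", "d_min", "d_max", "d_mean",
                   vx_cols())]
  rownames(wide) <- NULL
  if (validate) {
    issues <- validate_cdvh_table(wide)
    if (nrow(issues)) {
      bad <- unique(paste(issues$patient_id, issues$structure))
      stop(ril_error("ril_validation_error",
                     sprintf("invalid DVH record(s) for: %s",
                             paste(utils::head(bad, 5), collapse = "; "))))
    }
  }
  wide
}

#' Write a wide DVH table in the long CSV schema
#' @param dvh Wide DVH table.
#' @param path Output CSV path.
#' @export
write_dvh_csv <- function(dvh, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(dvh)), function(i) {
    vals <- unlist(dvh[i, c("d_min", "d_max", "d_mean", vx_cols())])
    data.frame(patient_id = dvh$patient_id[i], structure = dvh$structure[i],
               metric = dvh_metric_names(), value = as.numeric(vals),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `blood.csv`, `clinical.csv`, `dvh.csv` (long schema) and
#' `truth.csv` into `dir`.
#'
#' @param cohort A `ril_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ril_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("blood.csv", "clinical.csv", "dvh.csv",
                            "truth.csv"))
  utils::write.csv(cohort$blood, paths[1], row.names = FALSE)
  utils::write.csv(cohort$clinical, paths[2], row.names = FALSE)
  write_dvh_csv(cohort$dvh, paths[3])
  utils::write.csv(cohort$truth, paths[4], row.names = FALSE)
  invisible(paths)
}

.write_stage <- function(writer, path) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run the full RIL analysis pipeline
#'
#' Chains cohort simulation (or CSV inputs), endpoint computation, DVH
#' validation with optional EQD2 conversion, EDRIC, and the association
#' stage (univariable screen, ANCOVA plan comparison, Spearman endpoint
#' comparison, PCA, and the two multivariable models with optimism
#' correction). All outputs and a manifest are written to `out_dir`; the
#' run is deterministic for a fixed configuration and seed. Stage outputs
#' are written under a `.partial` suffix first and renamed on stage
#' success, so an aborted run leaves its incomplete files marked.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()] for simulation, or `NULL` to read
#'   `blood.csv`, `clinical.csv` and `dvh.csv` from `input_dir`.
#' @param input_dir Directory with input CSVs when `config` is `NULL`.
#' @param window Fit window in days (default 45).
#' @param apply_eqd2 Convert DVH metrics to EQD2 before the association
#'   stage (default TRUE).
#' @param bootstrap_B Bootstrap resamples for the optimism correction.
#' @param seed Seed for the bootstrap stage (the simulation seed lives in
#'   `config`).
#' @return Invisibly, a list with the analysis table, model reports, PCA
#'   and the output paths.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         input_dir = NULL, window = 45, apply_eqd2 = TRUE,
                         bootstrap_B = 300, seed = 7L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))

  if (!is.null(config)) {
    cohort <- generate_cohort(config)
    write_cohort_csv(cohort, out_dir)
    blood <- cohort$blood
    clinical <- cohort$clinical
    dvh <- cohort$dvh
    log_msg("simulate: %d patients (seed %d)", nrow(cohort$truth),
            config$seed)
  } else {
    if (is.null(input_dir)) {
      stop(ril_error("ril_config_error",
                     "either config or input_dir must be given"))
    }
    rb <- read_blood_csv(file.path(input_dir, "blood.csv"))
    blood <- rb$blood
    if (nrow(rb$excluded)) {
      log_msg("read: excluded %d patient(s): %s", nrow(rb$excluded),
              paste(rb$excluded$patient_id, collapse = ", "))
    }
    clinical <- read_clinical_csv(file.path(input_dir, "clinical.csv"))
    dvh <- read_dvh_csv(file.path(input_dir, "dvh.csv"))
  }

  issues <- validate_cdvh_table(dvh)
  if (nrow(issues)) {
    stop(ril_error("ril_validation_error",
                   sprintf("DVH validation failed for: %s",
                           paste(unique(paste(issues$patient_id,
                                              issues$structure)),
                                 collapse = "; "))))
  }

  endpoints <- compute_endpoints(blood, window = window)
  .write_stage(function(p) utils::write.csv(endpoints, p, row.names = FALSE),
               file.path(out_dir, "endpoints.csv"))
  log_msg("endpoints: %d/%d successful fits", sum(endpoints$status == "success"),
          nrow(endpoints))

  edr <- edric_table(dvh, clinical)
  .write_stage(function(p) utils::write.csv(edr, p, row.names = FALSE),
               file.path(out_dir, "edric.csv"))

  dvh_used <- dvh
  if (apply_eqd2) {
    dvh_used <- eqd2_transform_dvh(dvh, clinical[, c("patient_id",
                                                     "n_fractions")])
    .write_stage(function(p) write_dvh_csv(dvh_used, p),
                 file.path(out_dir, "dvh_eqd2.csv"))
  }

  table <- build_analysis_table(endpoints, clinical, dvh_used, edr)
  log_msg("analysis table: %d evaluable patients (%d excluded)", nrow(table),
          attr(table, "n_excluded"))

  screen <- univariable_screen(table)
  .write_stage(function(p) utils::write.csv(screen, p, row.names = FALSE),
               file.path(out_dir, "screen_r2.csv"))
  ancova <- ancova_plan_comparison(table)
  .write_stage(function(p) utils::write.csv(ancova, p, row.names = FALSE),
               file.path(out_dir, "ancova.csv"))
  spearman <- spearman_endpoint_comparison(table)
  .write_stage(function(p) utils::write.csv(spearman, p, row.names = FALSE),
               file.path(out_dir, "spearman.csv"))

  pca <- pca_dose(table)
  .write_stage(function(p) jsonlite::write_json(
    list(metrics = pca$metrics,
         explained_fraction = pca$explained_fraction,
         pc1_loadings = as.numeric(pca$loadings[, 1])),
    p, auto_unbox = TRUE, digits = NA), file.path(out_dir, "pca.json"))
  table$pc1 <- pca$pc1_scores

  model_edric <- fit_multivariable(table, "edric", B = bootstrap_B,
                                   seed = seed)
  model_pc1 <- fit_multivariable(table, "pc1", B = bootstrap_B, seed = seed)
  report_of <- function(m) {
    list(dose_summary = m$dose_summary, n = m$n, terms = m$terms,
         r_squared = m$r_squared,
         r_squared_corrected = m$r_squared_corrected, mse = m$mse,
         aic = m$aic, bootstrap_B = m$bootstrap_B, seed = m$seed)
  }
  .write_stage(function(p) jsonlite::write_json(
    list(model_edric = report_of(model_edric),
         model_pc1 = report_of(model_pc1)),
    p, auto_unbox = TRUE, digits = NA, dataframe = "rows"),
    file.path(out_dir, "model_report.json"))

  .write_stage(function(p) writeLines(
    render_report_md(table, screen, ancova, spearman, pca,
                     model_edric, model_pc1), p),
    file.path(out_dir, "report.md"))

  inputs <- file.path(out_dir, c("blood.csv", "clinical.csv", "dvh.csv"))
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "rilkinetics",
    version = as.character(utils::packageVersion("rilkinetics")),
    seed = as.integer(seed),
    simulation_seed = if (!is.null(config)) config$seed else NULL,
    window = window, eqd2 = apply_eqd2, bootstrap_B = bootstrap_B,
    n_patients = length(unique(blood$patient_id)),
    n_successful_fits = sum(endpoints$status == "success"),
    n_analysis = nrow(table),
    input_md5 = as.list(tools::md5sum(inputs)))
  .write_stage(function(p) jsonlite::write_json(manifest, p,
                                                auto_unbox = TRUE,
                                                digits = NA),
               file.path(out_dir, "manifest.json"))

  invisible(list(table = table, endpoints = endpoints, pca = pca,
                 model_edric = model_edric, model_pc1 = model_pc1,
                 screen = screen, ancova = ancova, spearman = spearman,
                 out_dir = out_dir))
}

render_report_md <- function(table, screen, ancova, spearman, pca,
                             model_edric, model_pc1) {
  fmt_model <- function(m) {
    tt <- m$terms
    c(sprintf("### Model (%s), n = %d", m$dose_summary, m$n),
      "",
      "| term | coefficient (95% CI) | p |",
      "|---|---|---|",
      sprintf("| %s | %.2f (%.2f, %.2f) | %s |", tt$term, tt$estimate,
              tt$ci_lower, tt$ci_upper,
              format.pval(tt$p_value, digits = 3, eps = 1e-3)),
      "",
      sprintf("R2 %.3f; bias-corrected R2 %.3f (B = %d); MSE %.1f; AIC %.1f",
              m$r_squared, m$r_squared_corrected, m$bootstrap_B, m$mse,
              m$aic),
      "")
  }
  top_screen <- screen[!screen$degenerate, ]
  top_screen <- utils::head(top_screen[order(-top_screen$r_squared), ], 10)
  c("# RIL analysis report", "",
    sprintf("Evaluable patients: %d; median percent ALC loss %.1f%%; median nadir %.2f.",
            nrow(table), stats::median(table$percent_loss),
            stats::median(table$nadir)),
    "",
    sprintf("PC1 of the dose metrics explains %.1f%% of their variance.",
            100 * pca$explained_fraction[1]),
    "",
    "## Top univariable screen R2", "",
    "| metric | stratum | R2 |", "|---|---|---|",
    sprintf("| %s | %s | %.3f |", top_screen$metric, top_screen$stratum,
            top_screen$r_squared),
    "",
    "## Multivariable models", "",
    fmt_model(model_edric), fmt_model(model_pc1))
}
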