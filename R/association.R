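#' Pivot a wide DVH table to one row per patient
#'
#' Turns rows of structure-level records into per-patient columns named
#' `<structure>_<metric>` (e.g. `body_Dmean`, `lungs_sum_V5`).
#'
#' @param dvh Wide DVH table (one row per patient x structure).
#' @return Data frame with one row per patient.
#' @export
dvh_to_patient_matrix <- function(dvh) {
  pieces <- lapply(dvh_structures(), function(s) {
    d <- dvh[dvh$structure == s, c("patient_id", "d_min", "d_max", "d_mean",
                                   vx_cols())]
    names(d)[-1] <- paste(s, c("Dmin", "Dmax", "Dmean", vx_cols()), sep = "_")
    d
  })
  Reduce(function(x, y) merge(x, y, by = "patient_id"), pieces)
}

#' Names of the per-patient DVH metric columns
#' @param include_summaries Include `Dmin`/`Dmax`/`Dmean` columns (default
#'   TRUE) in addition to the Vx grid.
#' @return Character vector of column names produced by
#'   [dvh_to_patient_matrix()].
#' @export
dvh_metric_cols <- function(include_summaries = TRUE) {
  metrics <- if (include_summaries) dvh_metric_names() else vx_cols()
  unlist(lapply(dvh_structures(), function(s) paste(s, metrics, sep = "_")),
         use.names = FALSE)
}

#' Assemble the per-patient analysis table
#'
#' Joins endpoints, clinical covariates, per-patient DVH metrics and
#' (optionally) EDRIC, keeping only patients whose decay fit succeeded and
#' who are complete cases on the modelled columns.
#'
#' @param endpoints Output of [compute_endpoints()].
#' @param clinical Clinical table (`patient_id`, `technique`, `crt`,
#'   `ptv_cm3`, `n_fractions`, ...).
#' @param dvh Wide DVH table, or `NULL` to omit dose metrics.
#' @param edric Optional output of [edric_table()].
#' @return Data frame, one row per evaluable patient, with attribute
#'   `n_excluded` (patients dropped for fit failure or missingness).
#' @export
build_analysis_table <- function(endpoints, clinical, dvh = NULL,
                                 edric = NULL) {
  tab <- endpoints[endpoints$status == "success",
                   c("patient_id", "baseline_alc", "percent_loss", "nadir")]
  n_fail <- nrow(endpoints) - nrow(tab)
  cl <- clinical
  if ("ptv_cm3" %in% names(cl) && !"ptv_volume" %in% names(cl)) {
    cl$ptv_volume <- cl$ptv_cm3
  }
  keep <- intersect(c("patient_id", "age", "sex", "technique", "crt",
                      "total_dose_gy", "n_fractions", "ptv_volume", "centre"),
                    names(cl))
  tab <- merge(tab, cl[, keep], by = "patient_id")
  if (!is.null(dvh)) {
    tab <- merge(tab, dvh_to_patient_matrix(dvh), by = "patient_id")
  }
  if (!is.null(edric)) {
    tab <- merge(tab, edric[, c("patient_id", "edric")], by = "patient_id")
  }
  cc <- stats::complete.cases(tab[, setdiff(names(tab), c("age", "sex"))])
  out <- tab[cc, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_fail + sum(!cc)
  out
}

.default_metrics <- function(table) {
  cand <- c(dvh_metric_cols(), "edric", "ptv_volume")
  intersect(cand, names(table))
}

#' Univariable screen of dose metrics against percentage ALC loss
#'
#' For each dose metric and each technique stratum, fits
#' `percent_loss ~ CRT + metric` and records the model R^2, mirroring a
#' per-parameter predictive-power comparison. Metrics with (near) zero
#' variance in a stratum are flagged degenerate and skipped.
#'
#' @param table Analysis table from [build_analysis_table()].
#' @param metrics Metric column names; defaults to all DVH metric columns
#'   plus `edric` and `ptv_volume` when present.
#' @param stratify Stratify by `technique` (default) or fit on all rows
#'   (stratum `"all"`).
#' @param min_n Minimum rows required per stratum (default 10).
#' @return Data frame `metric`, `stratum`, `n`, `r_squared`, `degenerate`.
#' @export
univariable_screen <- function(table, metrics = NULL, stratify = TRUE,
                               min_n = 10) {
  metrics <- metrics %||% .default_metrics(table)
  strata <- if (stratify) split(table, table$technique) else list(all = table)
  out <- list()
  for (snm in names(strata)) {
    sub <- strata[[snm]]
    if (nrow(sub) < min_n) {
      stop(ril_error("ril_analysis_error",
                     sprintf("stratum '%s' has fewer than %d rows", snm, min_n)))
    }
    for (m in metrics) {
      x <- sub[[m]]
      degen <- stats::sd(x) < 1e-12
      r2 <- NA_real_
      if (!degen) {
        fit <- stats::lm(sub$percent_loss ~ sub$crt + x)
        r2 <- summary(fit)$r.squared
      }
      out[[length(out) + 1L]] <- data.frame(
        metric = m, stratum = snm, n = nrow(sub), r_squared = r2,
        degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  # stable order: structures in canonical order, then threshold, extras last
  ord <- match(res$metric, c(dvh_metric_cols(), "edric", "ptv_volume"))
  res <- res[order(res$stratum, ord), ]
  rownames(res) <- NULL
  res
}

#' ANCOVA comparison of VMAT vs IMRT plans adjusted for PTV volume
#'
#' For each dose metric fits `metric ~ technique + ptv_volume` and extracts
#' the VMAT-vs-IMRT contrast (coefficient, 95% CI, p-value), the
#' plan-comparison analysis for technique differences that are not
#' explained by target size.
#'
#' @inheritParams univariable_screen
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column
#'   (default FALSE).
#' @return Data frame `metric`, `estimate`, `ci_lower`, `ci_upper`,
#'   `p_value` (and `p_adjusted` when `adjust`).
#' @export
ancova_plan_comparison <- function(table, metrics = NULL, adjust = FALSE) {
  if (length(unique(table$technique)) < 2) {
    stop(ril_error("ril_analysis_error",
                   "both techniques must be present for the ANCOVA comparison"))
  }
  metrics <- metrics %||% setdiff(.default_metrics(table), "ptv_volume")
  tech <- factor(table$technique, levels = c("IMRT", "VMAT"))
  out <- lapply(metrics, function(m) {
    fit <- stats::lm(table[[m]] ~ tech + table$ptv_volume)
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    data.frame(metric = m, estimate = sm["techVMAT", "Estimate"],
               ci_lower = ci["techVMAT", 1], ci_upper = ci["techVMAT", 2],
               p_value = sm["techVMAT", "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}

#' Spearman correlation of dose metrics with the two RIL endpoints
#'
#' Rank correlation of each metric with percentage ALC loss and with the
#' observed nadir, for comparing how strongly dosimetry tracks the
#' curve-based endpoint versus the timing-sensitive nadir.
#'
#' @inheritParams univariable_screen
#' @return Data frame `metric`, `rho_percent_loss`, `rho_nadir`; constant
#'   metrics give `NA` correlations.
#' @export
spearman_endpoint_comparison <- function(table, metrics = NULL) {
  if (nrow(table) < 3) {
    stop(ril_error("ril_analysis_error", "at least 3 rows required"))
  }
  metrics <- metrics %||% .default_metrics(table)
  rho <- function(x, y) {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  res <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(metric = m,
               rho_percent_loss = rho(table[[m]], table$percent_loss),
               rho_nadir = rho(table[[m]], table$nadir),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Principal component summary of collinear dose metrics
#'
#' Z-standardises the DVH metric columns, eigendecomposes their
#' correlation matrix and returns loadings, explained variance fractions
#' and per-patient PC1 scores. The PC1 sign is oriented so that its
#' correlation with the mean body dose (or, failing that, with the average
#' standardised metric) is positive: higher PC1 means a more dose-intense
#' plan.
#'
#' @inheritParams univariable_screen
#' @param include_ptv Also include `ptv_volume` among the variables
#'   (default FALSE; the dose-metric-only convention).
#' @return List of class `ril_pca`: `loadings` (columns are components),
#'   `explained_fraction`, `pc1_scores`, `metrics`, `center`, `scale`.
#' @export
pca_dose <- function(table, metrics = NULL, include_ptv = FALSE) {
  metrics <- metrics %||% intersect(dvh_metric_cols(), names(table))
  if (include_ptv && "ptv_volume" %in% names(table)) {
    metrics <- c(metrics, "ptv_volume")
  }
  x <- as.matrix(table[, metrics, drop = FALSE])
  keep <- apply(x, 2, stats::sd) > 1e-12
  if (sum(keep) < 2) {
    stop(ril_error("ril_analysis_error",
                   "need at least 2 metrics with nonzero variance"))
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d zero-variance metric(s) from the PCA",
                    sum(!keep)))
    x <- x[, keep, drop = FALSE]
    metrics <- metrics[keep]
  }
  if (ncol(x) > nrow(x)) {
    warning("more metrics than patients; correlation PCA proceeds")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  load <- pc$rotation
  anchor <- if ("body_Dmean" %in% metrics) {
    x[, "body_Dmean"]
  } else {
    rowMeans(scale(x))
  }
  if (stats::cor(scores[, 1], anchor) < 0) {
    scores[, 1] <- -scores[, 1]
    load[, 1] <- -load[, 1]
  }
  structure(list(loadings = load, explained_fraction = expl,
                 pc1_scores = scores[, 1], scores = scores,
                 metrics = metrics, center = pc$center, scale = pc$scale),
            class = "ril_pca")
}

#' Multivariable linear model for percentage ALC loss
#'
#' Ordinary least squares of percentage ALC loss on concurrent CRT,
#' baseline ALC and one dose summary (EDRIC or PC1), with 95% CIs,
#' p-values, R^2, optimism-corrected R^2 (Harrell bootstrap), training MSE
#' (RSS/n) and AIC.
#'
#' @param table Analysis table containing `percent_loss`, `crt`,
#'   `baseline_alc` and the dose-summary column.
#' @param dose_summary Name of the dose-summary column (e.g. `"edric"` or
#'   `"pc1"`).
#' @param B Bootstrap resamples for the optimism correction (default 300).
#' @param seed Seed for the bootstrap (recorded in the report).
#' @return List of class `ril_model_report`: `terms` (data frame of
#'   coefficients with CIs and p-values), `r_squared`,
#'   `r_squared_corrected`, `optimism`, `mse`, `aic`, `n`, `bootstrap_B`,
#'   `seed`, `dose_summary`.
#' @export
fit_multivariable <- function(table, dose_summary = "edric", B = 300,
                              seed = 1L) {
  need <- c("percent_loss", "crt", "baseline_alc", dose_summary)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop(ril_error("ril_analysis_error",
                   paste("missing columns:", paste(miss, collapse = ", "))))
  }
  fml <- stats::as.formula(
    paste("percent_loss ~ crt + baseline_alc +", dose_summary))
  X <- stats::model.matrix(fml, data = table)
  if (qr(X)$rank < ncol(X)) {
    sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    culprit <- paste(names(sds)[sds < 1e-12], collapse = ", ")
    stop(ril_error("ril_analysis_error",
                   sprintf("rank-deficient design (collinear or constant terms: %s)",
                           if (nzchar(culprit)) culprit else "unidentified")))
  }
  fit <- stats::lm(fml, data = table)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, "Estimate"],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      p_value = sm$coefficients[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  n <- nrow(table)
  rss <- sum(stats::residuals(fit)^2)
  boot <- optimism_corrected_r2(fml, table, B = B, seed = seed)
  structure(list(terms = terms, r_squared = sm$r.squared,
                 r_squared_corrected = boot$corrected,
                 optimism = boot$optimism, mse = rss / n,
                 aic = stats::AIC(fit), n = n, bootstrap_B = B,
                 seed = as.integer(seed), dose_summary = dose_summary,
                 skipped_resamples = boot$skipped),
            class = "ril_model_report")
}

#' @export
print.ril_model_report <- function(x, ...) {
  cat(sprintf("Linear model for percent ALC loss (dose summary: %s, n = %d)\n",
              x$dose_summary, x$n))
  tt <- x$terms
  tt$estimate <- sprintf("%.2f (%.2f, %.2f)", tt$estimate, tt$ci_lower,
                         tt$ci_upper)
  tt$p_value <- format.pval(tt$p_value, digits = 3, eps = 1e-3)
  print(tt[, c("term", "estimate", "p_value")], row.names = FALSE)
  cat(sprintf("R2 %.3f | bias-corrected R2 %.3f (B = %d) | MSE %.1f | AIC %.1f\n",
              x$r_squared, x$r_squared_corrected, x$bootstrap_B, x$mse, x$aic))
  invisible(x)
}

#' Optimism-corrected R-squared by bootstrap
#'
#' Harrell's optimism bootstrap for the internal validation of a linear
#' model: for each of `B` resamples of rows with replacement, the model is
#' refit, its R^2 on the resample and the R^2 of its predictions on the
#' original data are compared, and the mean difference (the optimism) is
#' subtracted from the apparent R^2. Degenerate resamples (zero-variance
#' outcome or rank-deficient design) are skipped and counted; more than
#' 10% skipped raises a warning.
#'
#' @param formula Model formula.
#' @param data Data frame the model is fit on.
#' @param B Number of bootstrap resamples (default 300).
#' @param seed Seed making the resampling deterministic.
#' @param indices Optional list of row-index vectors overriding the random
#'   resamples (for checks).
#' @return List `apparent`, `optimism`, `corrected`, `skipped`.
#' @export
optimism_corrected_r2 <- function(formula, data, B = 300, seed = NULL,
                                  indices = NULL) {
  if (is.null(indices) && (!is.numeric(B) || B < 1)) {
    stop(ril_error("ril_domain_error", "B must be >= 1"))
  }
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data = data)
  n <- length(y)
  # predictive R^2: squared correlation between observed and predicted.
  # For an OLS fit evaluated on its own training data this equals the
  # classical 1 - SSE/SST, so the apparent R^2 is the usual one; out of
  # sample it remains a calibration-free measure of explained variation,
  # which keeps the correction near zero under a null model.
  r2 <- function(obs, pred) {
    if (stats::sd(obs) < 1e-12) return(NA_real_)
    if (stats::sd(pred) < 1e-12) return(0)
    stats::cor(obs, pred)^2
  }
  fit0 <- stats::lm.fit(X, y)
  apparent <- r2(y, fit0$fitted.values)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(indices)) {
    indices <- replicate(B, sample.int(n, n, replace = TRUE),
                         simplify = FALSE)
  }
  opt <- numeric(0)
  skipped <- 0L
  for (idx in indices) {
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    if (stats::sd(yb) < 1e-12 || qr(Xb)$rank < ncol(Xb)) {
      skipped <- skipped + 1L
      next
    }
    fb <- stats::lm.fit(Xb, yb)
    r2_boot <- r2(yb, fb$fitted.values)
    r2_orig <- r2(y, drop(X %*% fb$coefficients))
    opt <- c(opt, r2_boot - r2_orig)
  }
  if (skipped > 0.1 * length(indices)) {
    warning(sprintf("%d of %d bootstrap resamples were degenerate and skipped",
                    skipped, length(indices)))
  }
  optimism <- if (length(opt)) mean(opt) else 0
  list(apparent = apparent, optimism = optimism,
       corrected = apparent - optimism, skipped = skipped)
}
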