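#' Select the baseline ALC measurement
#'
#' The baseline is the measurement taken closest to the start of
#' radiotherapy, among measurements recorded no later than the second day of
#' treatment and no earlier than 91 days (three months) before RT start.
#' Ties in distance from day 0 are broken toward the later measurement.
#'
#' @param times Numeric vector of measurement days relative to RT start
#'   (day 0 = first fraction; pre-treatment measurements are negative).
#' @param values Numeric vector of ALC values (10^3/uL), same length as
#'   `times`.
#' @return A list with elements `baseline_alc` and `baseline_time`.
#' @examples
#' select_baseline(c(-30, 1, 8), c(2.4, 2.1, 1.5))
#' @export
select_baseline <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1)
  eligible <- which(times <= 2 & times >= -91 & !is.na(values))
  if (length(eligible) == 0L) {
    stop(ril_error("ril_baseline_missing",
                   "no ALC measurement between day -91 and day 2; baseline missing"))
  }
  # closest to day 0; ties broken toward the later measurement
  ord <- eligible[order(abs(times[eligible]), -times[eligible])]
  i <- ord[1L]
  list(baseline_alc = values[i], baseline_time = times[i])
}

#' Fit a per-patient exponential lymphocyte depletion curve
#'
#' Fits `ALC(t) = a * exp(-b * t) + c` by bounded nonlinear least squares
#' (Levenberg-Marquardt) to all measurements from RT start up to `window`
#' days. `a` and `c` are bounded below by zero (negative ALC is
#' non-physiological); `b` is left free and filtered afterwards: fits with
#' `b < 0` or `b > 1` are flagged as failures, as are fits with R^2 < 0.5,
#' rather than being constrained away.
#'
#' A baseline measured before RT start is mapped to `t = 0`: the model is
#' defined from RT onset and a pre-RT count estimates the day-0 state.
#' Duplicate same-day measurements are averaged before fitting.
#'
#' @param times,values The blood-count series (days; 10^3/uL).
#' @param baseline Optional list from [select_baseline()]; computed from the
#'   series when `NULL`.
#' @param window Fit window in days after RT start (default 45).
#' @param init_rate,init_plateau Initial values for the depletion rate `b`
#'   (per day) and plateau `c` (10^3/uL); defaults 0.10 and 0.34.
#' @param max_eval Maximum optimizer iterations; hitting it is a
#'   convergence failure.
#' @return An object of class `decay_fit`: a list with `a`, `b`, `c`,
#'   `r_squared`, `n_points`, `window_end_T` (time of the last fitted
#'   measurement, used as the endpoint integration time) and `status`, one
#'   of `"success"`, `"fail_insufficient_points"`, `"fail_no_converge"`,
#'   `"fail_b_range"`, `"fail_r2"`.
#' @examples
#' t <- c(0, 7, 14, 21, 28, 35, 42)
#' y <- 1.6 * exp(-0.1 * t) + 0.4
#' fit_decay(t, y)
#' @export
fit_decay <- function(times, values, baseline = NULL, window = 45,
                      init_rate = 0.10, init_plateau = 0.34,
                      max_eval = 1000) {
  stopifnot(length(times) == length(values))
  if (is.null(baseline)) baseline <- select_baseline(times, values)

  t <- times
  v <- values
  # pre-RT baseline mapped to t = 0; other pre-RT points are not fitted
  if (baseline$baseline_time < 0) {
    i <- which(t == baseline$baseline_time)
    t[i] <- 0
  }
  keep <- t >= 0 & t <= window & !is.na(v)
  t <- t[keep]
  v <- v[keep]
  if (length(t) > 0 && anyDuplicated(t)) {
    v <- as.numeric(tapply(v, t, mean))
    t <- sort(unique(t))
  } else {
    v <- v[order(t)]
    t <- sort(t)
  }

  out <- structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                        r_squared = NA_real_, n_points = length(t),
                        window_end_T = if (length(t)) max(t) else NA_real_,
                        status = "fail_insufficient_points"),
                   class = "decay_fit")
  if (length(t) < 3L) return(out)

  start <- c(a = max(baseline$baseline_alc - init_plateau, 0.01),
             b = init_rate, c = init_plateau)
  resid_fn <- function(p) p[1] * exp(-p[2] * t) + p[3] - v
  jac_fn <- function(p) {
    e <- exp(-p[2] * t)
    cbind(e, -p[1] * t * e, 1)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = c(0, -Inf, 0),
                       upper = c(Inf, Inf, Inf), fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = min(max_eval, 1024L),
                         ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  # info codes 1-4: converged (4 = gradient orthogonality, a valid
  # stationary point under bounds); 0, 5-: iteration/evaluation limits
  if (is.null(fit) || !fit$info %in% 1:4) {
    out$status <- "fail_no_converge"
    return(out)
  }

  p <- stats::coef(fit)
  pred <- p[["a"]] * exp(-p[["b"]] * t) + p[["c"]]
  ss_res <- sum((v - pred)^2)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot < 1e-12) {
    if (ss_res < 1e-12) 1 else 0   # constant series: perfect fit or not
  } else {
    1 - ss_res / ss_tot
  }

  out$a <- p[["a"]]; out$b <- p[["b"]]; out$c <- p[["c"]]
  out$r_squared <- r2
  out$status <- if (p[["b"]] < 0 || p[["b"]] > 1) {
    "fail_b_range"
  } else if (r2 < 0.5) {
    "fail_r2"
  } else {
    "success"
  }
  out
}

.fit_abc <- function(fit) {
  if (inherits(fit, "decay_fit") || is.list(fit)) {
    c(a = fit$a, b = fit$b, c = fit$c)
  } else {
    stopifnot(is.numeric(fit), length(fit) == 3)
    c(a = fit[[1]], b = fit[[2]], c = fit[[3]])
  }
}

#' Closed-form area under the fitted decay curve
#'
#' Integrates `a * exp(-b * t) + c` from 0 to `t_end`:
#' `a/b * (1 - exp(-b * t_end)) + c * t_end`, with the `b -> 0` limit
#' `(a + c) * t_end`.
#'
#' @param fit A `decay_fit` (or any list with `a`, `b`, `c`, or a numeric
#'   vector `c(a, b, c)`).
#' @param t_end Upper integration limit in days; must be positive.
#' @return Area in 10^3/uL * days.
#' @examples
#' auc_closed_form(c(1.6, 0.1, 0.4), 45)
#' @export
auc_closed_form <- function(fit, t_end) {
  p <- .fit_abc(fit)
  if (!is.finite(t_end) || t_end <= 0) {
    stop(ril_error("ril_domain_error", "t_end must be positive"))
  }
  if (p[["b"]] < 0) {
    stop(ril_error("ril_domain_error", "auc_closed_form requires b >= 0"))
  }
  if (p[["b"]] < 1e-12) {
    (p[["a"]] + p[["c"]]) * t_end
  } else {
    p[["a"]] / p[["b"]] * (1 - exp(-p[["b"]] * t_end)) + p[["c"]] * t_end
  }
}

#' Percentage ALC loss relative to baseline
#'
#' The endpoint summarising lymphocyte depletion over the fit window:
#' `100 * (1 - AUC(0, T) / (baseline_alc * T))`, i.e. the area lost under
#' the fitted decay curve relative to a flat curve at baseline. `T` is the
#' time of the last measurement inside the window (the curve-fitting time).
#' A negative value (fitted curve above baseline) is reported as-is and
#' should be flagged, not clamped.
#'
#' @inheritParams auc_closed_form
#' @param baseline_alc Baseline ALC (10^3/uL); must be positive.
#' @param t_end Integration time `T` in days.
#' @return Percentage loss (may exceed neither 100 nor be clamped below 0).
#' @examples
#' percent_alc_loss(c(1.6, 0.1, 0.4), baseline_alc = 2.0, t_end = 45)
#' @export
percent_alc_loss <- function(fit, baseline_alc, t_end) {
  if (!is.finite(baseline_alc) || baseline_alc <= 0) {
    stop(ril_error("ril_domain_error", "baseline_alc must be positive"))
  }
  100 * (1 - auc_closed_form(fit, t_end) / (baseline_alc * t_end))
}

#' Observed lymphocyte nadir within the window
#'
#' @param times,values The blood-count series.
#' @param window Window in days; measurements with `0 <= t <= window` are
#'   considered.
#' @return The minimum observed ALC in the window.
#' @export
alc_nadir <- function(times, values, window = 45) {
  keep <- times >= 0 & times <= window & !is.na(values)
  if (!any(keep)) {
    stop(ril_error("ril_domain_error", "no measurement inside the window"))
  }
  min(values[keep])
}

#' CTCAE lymphopenia grade from the nadir
#'
#' Grades: 4 if ALC < 0.2, 3 if < 0.5, 2 if < 0.8, 1 if below the lower
#' limit of normal (default 1.0), otherwise 0 (all in 10^3/uL). Severe RIL
#' is grade >= 3 (ALC < 500 cells/mm^3).
#'
#' @param nadir_value Nadir ALC (10^3/uL), non-negative; vectorised.
#' @param lln Lower limit of normal for grade 1 (default 1.0).
#' @return Integer grade(s) in 0..4.
#' @examples
#' ctcae_grade(c(0.49, 0.54, 0.15))
#' @export
ctcae_grade <- function(nadir_value, lln = 1.0) {
  if (any(!is.finite(nadir_value)) || any(nadir_value < 0)) {
    stop(ril_error("ril_domain_error", "nadir_value must be non-negative"))
  }
  ifelse(nadir_value < 0.2, 4L,
         ifelse(nadir_value < 0.5, 3L,
                ifelse(nadir_value < 0.8, 2L,
                       ifelse(nadir_value < lln, 1L, 0L))))
}

#' Per-patient lymphocyte endpoints for a cohort
#'
#' Runs baseline selection, decay fitting, endpoint and nadir computation
#' for every patient in a long-format blood-count table. Patients whose
#' fits fail quality control keep their status and nadir but have `NA`
#' endpoints; every patient receives exactly one status.
#'
#' @param blood Data frame with columns `patient_id`, `day`, `alc`.
#' @param window Fit window in days (default 45).
#' @param init_rate,init_plateau Initial values passed to [fit_decay()].
#' @param lln Lower limit of normal passed to [ctcae_grade()].
#' @return A data frame, one row per patient: baseline, fitted parameters,
#'   fit status, AUC, `percent_loss`, `fit_time_T`, `nadir`, `ctcae_grade`,
#'   `severe_ril` and a `negative_loss` flag.
#' @export
compute_endpoints <- function(blood, window = 45, init_rate = 0.10,
                              init_plateau = 0.34, lln = 1.0) {
  stopifnot(all(c("patient_id", "day", "alc") %in% names(blood)))
  res <- lapply(split(blood, blood$patient_id), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    row <- data.frame(patient_id = d$patient_id[1],
                      baseline_alc = NA_real_, baseline_time = NA_real_,
                      a = NA_real_, b = NA_real_, c = NA_real_,
                      r_squared = NA_real_, n_points = NA_integer_,
                      status = NA_character_, fit_time_T = NA_real_,
                      auc = NA_real_, percent_loss = NA_real_,
                      nadir = NA_real_, ctcae_grade = NA_integer_,
                      severe_ril = NA, negative_loss = FALSE,
                      stringsAsFactors = FALSE)
    bl <- tryCatch(select_baseline(d$day, d$alc), error = function(e) NULL)
    if (is.null(bl)) {
      row$status <- "fail_no_baseline"
      return(row)
    }
    row$baseline_alc <- bl$baseline_alc
    row$baseline_time <- bl$baseline_time
    fit <- fit_decay(d$day, d$alc, baseline = bl, window = window,
                     init_rate = init_rate, init_plateau = init_plateau)
    row$a <- fit$a; row$b <- fit$b; row$c <- fit$c
    row$r_squared <- fit$r_squared
    row$n_points <- fit$n_points
    row$status <- fit$status
    row$fit_time_T <- fit$window_end_T
    if (fit$status == "success" && fit$window_end_T > 0) {
      row$auc <- auc_closed_form(fit, fit$window_end_T)
      row$percent_loss <- percent_alc_loss(fit, bl$baseline_alc,
                                           fit$window_end_T)
      row$negative_loss <- row$percent_loss < 0
    }
    nad <- tryCatch(alc_nadir(d$day, d$alc, window), error = function(e) NA_real_)
    row$nadir <- nad
    if (!is.na(nad) && nad >= 0) {
      row$ctcae_grade <- ctcae_grade(nad, lln)
      row$severe_ril <- row$ctcae_grade >= 3L
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
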