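#' Default per-metric latent-factor loadings for the DVH generator
#'
#' One row per structure x metric with the population mean of the metric,
#' its loading on the shared latent plan-intensity factor, the residual
#' noise standard deviation, and an additive VMAT-vs-IMRT shift. The
#' default profiles emulate conformal lung-cancer plans: VMAT spreads a
#' larger low-dose bath over the body while IMRT exposes more lung and
#' heart volume at higher doses and gives slightly higher mean doses.
#' Loadings on the Vx grid scale with `mu * (100 - mu)` so metrics near
#' the middle of the volume scale co-vary most; the shared factor induces
#' the strong multicollinearity that the association stage summarises
#' with PCA.
#'
#' @return Data frame with columns `structure`, `metric`, `mean`,
#'   `loading`, `noise_sd`, `vmat_shift`.
#' @export
default_dvh_loadings <- function() {
  grid <- dvh_grid()
  profiles <- list(
    lungs_sum = c(90, 85, 75, 55, 42, 34, 28, 23, 19, 15, 12, 9, 6, 3),
    heart     = c(85, 78, 65, 45, 32, 25, 20, 16, 12, 9, 7, 5, 3, 1.5),
    body      = c(70, 60, 50, 35, 25, 20, 16, 13, 10, 8, 6, 4.5, 3, 1.5))
  dose_summary <- data.frame(
    structure = rep(names(profiles), each = 3),
    metric = rep(c("Dmin", "Dmax", "Dmean"), times = 3),
    mean = c(0.3, 63, 14,    # lungs_sum
             0.4, 55, 10,    # heart
             0.05, 64, 6),   # body
    loading = rep(c(0.05, 0.5, 1.5), times = 3),
    noise_sd = rep(c(0.1, 2, 1.5), times = 3),
    vmat_shift = rep(c(0, 0, -0.8), times = 3),
    stringsAsFactors = FALSE)
  vx <- do.call(rbind, lapply(names(profiles), function(s) {
    mu <- profiles[[s]]
    lam <- pmax(0.0016 * mu * (100 - mu), 0.3)
    shift <- rep(0, length(grid))
    if (s == "body") shift[grid <= 5] <- 8          # VMAT low-dose bath
    if (s == "heart") shift[] <- -4                  # IMRT: more heart volume
    if (s == "lungs_sum") shift[grid >= 15] <- -3    # IMRT: high-dose lung
    data.frame(structure = s, metric = vx_cols(), mean = mu, loading = lam,
               noise_sd = lam, vmat_shift = shift, stringsAsFactors = FALSE)
  }))
  out <- rbind(dose_summary, vx)
  rownames(out) <- NULL
  out
}

#' Configuration for the synthetic RIL cohort generator
#'
#' Defaults emulate a retrospective lung-cancer radiotherapy cohort:
#' baseline ALC log-normal with median 2.07 x 10^3/uL, depletion rate
#' around 0.10/day, plateau around 34% of baseline, 37% concurrent
#' chemoradiotherapy, 59% VMAT, weekly blood counts with +/- 2 days of
#' jitter, and a single latent plan-intensity factor driving all DVH
#' metrics and part of the lymphocyte loss.
#'
#' @param n_patients Number of patients (>= 1).
#' @param frac_crt Fraction receiving concurrent chemoradiotherapy.
#' @param frac_vmat Fraction treated with VMAT (the rest IMRT).
#' @param baseline_alc_median Median baseline ALC in 10^3/uL.
#' @param baseline_alc_log_sd Log-scale SD of baseline ALC.
#' @param decay_rate_base Central depletion rate b (per day).
#' @param decay_rate_log_sd Log-scale SD of the per-patient rate.
#' @param plateau_fraction_base Plateau c as a fraction of baseline before
#'   covariate effects.
#' @param effect_crt_on_loss Additional percentage points of ALC loss for
#'   CRT patients.
#' @param effect_dose_factor_on_loss Percentage points of ALC loss per unit
#'   latent dose factor (a z-score).
#' @param alc_noise_sd Additive Gaussian measurement noise on ALC
#'   (10^3/uL), truncated at zero.
#' @param visit_interval Days between scheduled on-treatment blood counts.
#' @param visit_jitter Visits are jittered by an integer uniform on
#'   `-visit_jitter .. visit_jitter` days.
#' @param fit_window Observation window in days (visits beyond it are not
#'   scheduled).
#' @param pathological_fraction Fraction of patients given series designed
#'   to fail fit quality control (rising ALC, flat noisy ALC, or fewer
#'   than three usable measurements), exercising the failure paths.
#' @param dvh_loadings Loadings table as in [default_dvh_loadings()].
#' @param n_centres Number of treating centres (centre label only unless
#'   `centre_sd > 0`).
#' @param centre_sd SD of an optional centre-level shift (percentage
#'   points) on the loss; default 0 (off).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration including the seed.
#' @return A validated list of class `ril_cohort_config`.
#' @export
cohort_config <- function(n_patients = 306,
                          frac_crt = 0.37,
                          frac_vmat = 0.59,
                          baseline_alc_median = 2.07,
                          baseline_alc_log_sd = 0.37,
                          decay_rate_base = 0.10,
                          decay_rate_log_sd = 0.25,
                          plateau_fraction_base = 0.34,
                          effect_crt_on_loss = 7,
                          effect_dose_factor_on_loss = 4,
                          alc_noise_sd = 0.15,
                          visit_interval = 7,
                          visit_jitter = 2,
                          fit_window = 45,
                          pathological_fraction = 0.08,
                          dvh_loadings = default_dvh_loadings(),
                          n_centres = 1,
                          centre_sd = 0,
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, frac_crt = frac_crt,
              frac_vmat = frac_vmat,
              baseline_alc_median = baseline_alc_median,
              baseline_alc_log_sd = baseline_alc_log_sd,
              decay_rate_base = decay_rate_base,
              decay_rate_log_sd = decay_rate_log_sd,
              plateau_fraction_base = plateau_fraction_base,
              effect_crt_on_loss = effect_crt_on_loss,
              effect_dose_factor_on_loss = effect_dose_factor_on_loss,
              alc_noise_sd = alc_noise_sd,
              visit_interval = visit_interval,
              visit_jitter = visit_jitter,
              fit_window = fit_window,
              pathological_fraction = pathological_fraction,
              dvh_loadings = dvh_loadings,
              n_centres = n_centres, centre_sd = centre_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "ril_cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, msg) {
    stop(ril_error("ril_config_error",
                   sprintf("invalid configuration field '%s': %s", field, msg)))
  }
  num1 <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      bad(field, "must be a finite number")
    }
    x
  }
  if (num1("n_patients") < 1) bad("n_patients", "must be >= 1")
  for (f in c("frac_crt", "frac_vmat", "pathological_fraction")) {
    if (num1(f) < 0 || cfg[[f]] > 1) bad(f, "must be in [0, 1]")
  }
  if (num1("baseline_alc_median") <= 0) bad("baseline_alc_median", "must be positive")
  if (num1("baseline_alc_log_sd") < 0) bad("baseline_alc_log_sd", "must be >= 0")
  if (num1("decay_rate_base") < 0 || cfg$decay_rate_base > 1) {
    bad("decay_rate_base", "must be in [0, 1]")
  }
  if (num1("decay_rate_log_sd") < 0) bad("decay_rate_log_sd", "must be >= 0")
  if (num1("plateau_fraction_base") < 0 || cfg$plateau_fraction_base > 1) {
    bad("plateau_fraction_base", "must be in [0, 1]")
  }
  if (num1("alc_noise_sd") < 0) bad("alc_noise_sd", "must be >= 0")
  if (num1("visit_interval") < 1) bad("visit_interval", "must be >= 1")
  if (num1("visit_jitter") < 0) bad("visit_jitter", "must be >= 0")
  if (num1("fit_window") < 2 * cfg$visit_interval) {
    bad("fit_window", "too short for at least three scheduled visits")
  }
  if (num1("n_centres") < 1) bad("n_centres", "must be >= 1")
  if (num1("centre_sd") < 0) bad("centre_sd", "must be >= 0")
  ld <- cfg$dvh_loadings
  need <- c("structure", "metric", "mean", "loading", "noise_sd", "vmat_shift")
  if (!is.data.frame(ld) || !all(need %in% names(ld))) {
    bad("dvh_loadings", paste("must be a data frame with columns",
                              paste(need, collapse = ", ")))
  }
  for (s in dvh_structures()) {
    have <- ld$metric[ld$structure == s]
    if (!all(dvh_metric_names() %in% have)) {
      bad("dvh_loadings", sprintf("missing metrics for structure '%s'", s))
    }
  }
  invisible(cfg)
}

.loss_multiplier <- function(b, t_end) {
  # percentage loss per unit (1 - plateau fraction): 100*(1-(1-e^-bT)/(bT))
  bt <- b * t_end
  ifelse(bt < 1e-12, 0, 100 * (1 - (1 - exp(-bt)) / bt))
}

.visit_days <- function(cfg) {
  k <- seq_len(floor(cfg$fit_window / cfg$visit_interval))
  jit <- if (cfg$visit_jitter > 0) {
    sample(seq(-cfg$visit_jitter, cfg$visit_jitter), length(k), replace = TRUE)
  } else {
    rep(0L, length(k))
  }
  days <- sort(unique(c(0, k * cfg$visit_interval + jit)))
  days[days >= 0 & days <= cfg$fit_window]
}

#' Generate DVH records driven by a latent plan-intensity factor
#'
#' Each metric is the structure-specific population mean plus
#' `loading * latent_dose_factor`, a technique shift for VMAT plans, and
#' Gaussian noise, then repaired to a physically valid cumulative DVH:
#' volumes clipped to \[0, 100\]%, the Vx profile projected onto the
#' non-increasing cone (pool-adjacent-violators), and
#' `Dmin <= Dmean <= Dmax` enforced. Every emitted record passes
#' [validate_cdvh()].
#'
#' @param truth Data frame with columns `patient_id`, `latent_dose_factor`
#'   and `technique` (`"IMRT"` or `"VMAT"`).
#' @param loadings Loadings table as in [default_dvh_loadings()]; set
#'   `noise_sd` to zero for deterministic profiles.
#' @return Wide DVH table: one row per patient x structure.
#' @export
generate_dvh <- function(truth, loadings = default_dvh_loadings()) {
  n <- nrow(truth)
  vxn <- vx_cols()
  out <- vector("list", 3L * n)
  k <- 0L
  for (s in dvh_structures()) {
    ld <- loadings[loadings$structure == s, ]
    ld <- ld[match(dvh_metric_names(), ld$metric), ]
    for (i in seq_len(n)) {
      z <- truth$latent_dose_factor[i]
      shift <- if (truth$technique[i] == "VMAT") ld$vmat_shift else 0
      val <- ld$mean + ld$loading * z + shift +
        stats::rnorm(nrow(ld), 0, ld$noise_sd)
      names(val) <- ld$metric
      v <- val[vxn]
      # repair: monotone non-increasing projection, then clip to [0, 100]
      v <- -stats::isoreg(seq_along(v), -v)$yf
      v <- pmin(pmax(v, 0), 100)
      d_min <- max(val[["Dmin"]], 0)
      d_max <- max(val[["Dmax"]], d_min)
      d_mean <- min(max(val[["Dmean"]], d_min), d_max)
      k <- k + 1L
      row <- c(list(patient_id = truth$patient_id[i], structure = s,
                    d_min = d_min, d_max = d_max, d_mean = d_mean),
               as.list(stats::setNames(v, vxn)))
      out[[k]] <- as.data.frame(row, stringsAsFactors = FALSE,
                                check.names = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic RIL cohort with stored ground truth
#'
#' Draws per-patient covariates, decay-curve parameters tied
#' mechanistically to the covariates, irregular weekly ALC series with
#' truncated Gaussian noise, latent-factor-driven multicollinear DVH
#' metrics, and a clinical table. A configurable fraction of patients
#' receives pathological series (rising ALC, flat ALC, or fewer than three
#' usable points) to exercise the fit-failure paths.
#'
#' The generative chain: baseline B is log-normal; the depletion rate b is
#' `decay_rate_base` with a log-normal perturbation, clipped to \[0, 1\];
#' the target extra loss `delta = effect_crt * CRT + effect_dose * z`
#' (percentage points) lowers the plateau fraction `f` from
#' `plateau_fraction_base` by `delta / m(b)` where
#' `m(b) = 100 (1 - (1 - e^(-bT)) / (bT))` is the loss obtained when the
#' plateau is zero; then `c = f B`, `a = B - c`. The stored
#' `true_percent_loss` is exactly the closed-form loss of `(a, b, c)` over
#' the fit window, so covariate effects propagate additively into the
#' endpoint.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ril_cohort` with data frames `truth`, `blood`,
#'   `clinical`, `dvh`, and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  id <- sprintf("P%04d", seq_len(n))

  crt <- as.integer(stats::runif(n) < config$frac_crt)
  technique <- ifelse(stats::runif(n) < config$frac_vmat, "VMAT", "IMRT")
  centre <- sample(seq_len(config$n_centres), n, replace = TRUE)
  z <- stats::rnorm(n)
  baseline <- stats::rlnorm(n, meanlog = log(config$baseline_alc_median),
                            sdlog = config$baseline_alc_log_sd)
  b <- config$decay_rate_base *
    exp(stats::rnorm(n, 0, config$decay_rate_log_sd))
  b <- pmin(pmax(b, 0), 1)

  delta <- config$effect_crt_on_loss * crt +
    config$effect_dose_factor_on_loss * z
  if (config$centre_sd > 0) {
    centre_shift <- stats::rnorm(config$n_centres, 0, config$centre_sd)
    delta <- delta + centre_shift[centre]
  }
  m <- .loss_multiplier(b, config$fit_window)
  f <- config$plateau_fraction_base - ifelse(m > 0, delta / m, 0)
  f <- pmin(pmax(f, 0), 1)
  cc <- f * baseline
  a <- baseline - cc
  true_loss <- vapply(seq_len(n), function(i) {
    percent_alc_loss(c(a[i], b[i], cc[i]), baseline[i], config$fit_window)
  }, numeric(1))

  # pathological series assignment
  pathological <- rep("none", n)
  n_path <- round(config$pathological_fraction * n)
  if (n_path > 0) {
    idx <- sample.int(n, n_path)
    pathological[idx] <- rep(c("rising", "flat", "too_few"),
                             length.out = n_path)
  }

  blood <- vector("list", n)
  for (i in seq_len(n)) {
    days <- .visit_days(config)
    curve <- a[i] * exp(-b[i] * days) + cc[i]
    if (pathological[i] == "rising") {
      curve <- baseline[i] * (1 + 0.012 * days)
    } else if (pathological[i] == "flat") {
      curve <- rep(baseline[i], length(days))
    }
    alc <- curve + stats::rnorm(length(days), 0, config$alc_noise_sd)
    alc <- pmax(alc, 0)
    if (pathological[i] == "too_few") {
      keep <- seq_len(min(2L, length(days)))
      days <- days[keep]
      alc <- alc[keep]
    }
    blood[[i]] <- data.frame(patient_id = id[i], day = days,
                             alc = alc, stringsAsFactors = FALSE)
  }
  blood <- do.call(rbind, blood)
  rownames(blood) <- NULL

  # fractionation schemes: radical-intent photon courses, median 60 Gy
  scheme <- sample(1:3, n, replace = TRUE, prob = c(0.55, 0.30, 0.15))
  total_dose <- c(60, 66, 55)[scheme]
  n_fractions <- c(30L, 33L, 20L)[scheme]
  ptv <- round(exp(log(330) + 0.15 * (technique == "IMRT") + 0.2 * z +
                     stats::rnorm(n, 0, 0.3)), 1)
  age <- pmin(pmax(round(stats::rnorm(n, 67, 8)), 35), 92)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.64, 0.36))

  truth <- data.frame(patient_id = id, true_a = a, true_b = b, true_c = cc,
                      latent_dose_factor = z, true_percent_loss = true_loss,
                      crt = crt, technique = technique,
                      baseline_alc = baseline, ptv_volume = ptv,
                      n_fractions = n_fractions, total_dose = total_dose,
                      centre = centre, pathological = pathological,
                      stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = id, age = age, sex = sex,
                         technique = technique, crt = crt,
                         total_dose_gy = total_dose,
                         n_fractions = n_fractions, ptv_cm3 = ptv,
                         centre = centre, stringsAsFactors = FALSE)
  dvh <- generate_dvh(truth, config$dvh_loadings)

  structure(list(truth = truth, blood = blood, clinical = clinical,
                 dvh = dvh, config = config),
            class = "ril_cohort")
}

#' @export
print.ril_cohort <- function(x, ...) {
  cat(sprintf("Synthetic RIL cohort: %d patients, %d ALC measurements, seed %d\n",
              nrow(x$truth), nrow(x$blood), x$config$seed))
  cat(sprintf("  CRT %.0f%%, VMAT %.0f%%, pathological series %d\n",
              100 * mean(x$truth$crt),
              100 * mean(x$truth$technique == "VMAT"),
              sum(x$truth$pathological != "none")))
  invisible(x)
}
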