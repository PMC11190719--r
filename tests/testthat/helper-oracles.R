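# Independent oracles and small fixture builders used across tests.

# Trapezoidal AUC of the decay curve on a fine grid (independent of the
# package's closed form).
trapz_auc <- function(a, b, c, t_end, step = 0.001) {
  t <- seq(0, t_end, by = step)
  y <- a * exp(-b * t) + c
  pracma::trapz(t, y)
}

# Population PC1 variance fraction implied by the configured one-factor
# DVH model plus the Bernoulli technique shift: covariance
# lambda lambda' + p(1-p) s s' + diag(sigma^2), standardised.
oracle_pc1_fraction <- function(loadings, frac_vmat) {
  lam <- loadings$loading
  s <- loadings$vmat_shift
  sig <- loadings$noise_sd
  S <- outer(lam, lam) + frac_vmat * (1 - frac_vmat) * outer(s, s) +
    diag(sig^2)
  R <- stats::cov2cor(S)
  eigen(R, symmetric = TRUE, only.values = TRUE)$values[1] / nrow(loadings)
}

# Noiseless weekly series from decay parameters.
decay_series <- function(a, b, c, days = c(0, 7, 14, 21, 28, 35, 42)) {
  list(times = days, values = a * exp(-b * days) + c)
}

# A valid random cDVH record: monotone Vx plus consistent dose summaries.
random_valid_record <- function() {
  v <- sort(runif(length(vx_cols()), 0, 100), decreasing = TRUE)
  doses <- sort(runif(3, 0, 70))
  rec <- as.list(setNames(v, vx_cols()))
  rec$d_min <- doses[1]
  rec$d_mean <- doses[2]
  rec$d_max <- doses[3]
  rec
}

# Small deterministic clinical/analysis-style table for model tests.
toy_analysis_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    crt = rep(0:1, length.out = n),
    baseline_alc = runif(n, 1, 3),
    edric = runif(n, 2, 10),
    technique = rep(c("IMRT", "VMAT"), each = n / 2),
    ptv_volume = runif(n, 100, 600),
    nadir = runif(n, 0.2, 1.2),
    stringsAsFactors = FALSE)
}
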