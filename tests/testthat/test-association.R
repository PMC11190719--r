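test_that("univariable screen recovers exact linear structure and flags degenerate metrics", {
  tab <- toy_analysis_table(n = 40)
  tab$metric_exact <- (tab$edric - 2) / 2
  tab$percent_loss <- 10 + 5 * tab$crt + 2 * tab$metric_exact
  tab$metric_flat <- 1.0
  out <- univariable_screen(tab, metrics = c("metric_exact", "metric_flat"),
                            stratify = FALSE)
  expect_equal(out$r_squared[out$metric == "metric_exact"], 1.0,
               tolerance = 1e-9)
  expect_true(out$degenerate[out$metric == "metric_flat"])
  expect_true(is.na(out$r_squared[out$metric == "metric_flat"]))
})

test_that("screen R2 ranks metrics by their configured latent loadings", {
  set.seed(44)
  n <- 400
  z <- rnorm(n)
  loadings <- c(m1 = 0.2, m2 = 0.5, m3 = 1, m4 = 2, m5 = 4)
  tab <- data.frame(crt = rbinom(n, 1, 0.4), technique = "IMRT")
  for (m in names(loadings)) {
    tab[[m]] <- loadings[[m]] * z + rnorm(n)
  }
  tab$percent_loss <- 50 + 7 * tab$crt + 4 * z + rnorm(n, 0, 2)
  out <- univariable_screen(tab, metrics = names(loadings), stratify = FALSE)
  expect_gt(cor(out$r_squared, loadings[out$metric], method = "spearman"),
            0.8)
})

test_that("ANCOVA contrast is null when the metric is PTV-determined", {
  tab <- toy_analysis_table(n = 60)
  tab$metric <- 0.05 * tab$ptv_volume
  out <- ancova_plan_comparison(tab, metrics = "metric")
  expect_equal(out$estimate, 0, tolerance = 1e-8)

  one_tech <- tab[tab$technique == "IMRT", ]
  expect_error(ancova_plan_comparison(one_tech, metrics = "metric"),
               class = "ril_analysis_error")
})

test_that("ANCOVA covers a configured VMAT shift on body V5", {
  ld <- default_dvh_loadings()
  ld$vmat_shift[ld$structure == "body" & ld$metric == "V5"] <- 10
  covered <- 0L
  reps <- 40
  set.seed(202)
  for (r in seq_len(reps)) {
    n <- 150
    truth <- data.frame(patient_id = sprintf("p%d", 1:n),
                        latent_dose_factor = rnorm(n),
                        technique = sample(c("IMRT", "VMAT"), n, TRUE),
                        stringsAsFactors = FALSE)
    dvh <- generate_dvh(truth, ld)
    tab <- merge(dvh_to_patient_matrix(dvh), truth, by = "patient_id")
    tab$ptv_volume <- exp(rnorm(n, log(330), 0.3))  # independent of dose
    out <- ancova_plan_comparison(tab, metrics = "body_V5")
    # PTV is independent of the latent factor here, so the conditional
    # VMAT effect equals the configured shift
    target <- 10
    if (out$ci_lower <= target && target <= out$ci_upper) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / reps, 0.85)
})

test_that("Spearman endpoint comparison matches construction", {
  tab <- toy_analysis_table(n = 30)
  tab$percent_loss <- seq_len(30)
  tab$metric_up <- tab$percent_loss^3  # monotone transform
  tab$metric_const <- 5
  out <- spearman_endpoint_comparison(
    tab, metrics = c("metric_up", "metric_const"))
  expect_equal(out$rho_percent_loss[out$metric == "metric_up"], 1.0)
  expect_true(is.na(out$rho_percent_loss[out$metric == "metric_const"]))

  set.seed(77)
  big <- data.frame(percent_loss = rnorm(2000), nadir = rnorm(2000),
                    metric_ind = rnorm(2000))
  out2 <- spearman_endpoint_comparison(big, metrics = "metric_ind")
  expect_lt(abs(out2$rho_percent_loss), 0.05)
  expect_lt(abs(out2$rho_nadir), 0.05)
})

test_that("the curve-based endpoint tracks dose better than a timing-noisy nadir", {
  set.seed(91)
  n <- 600
  z <- rnorm(n)
  tab <- data.frame(
    metric = 2 * z + rnorm(n, 0, 0.5),
    percent_loss = 50 + 4 * z + rnorm(n, 0, 2),
    # nadir driven by the same dose signal but with extra timing noise
    nadir = 0.6 - 0.05 * z + rnorm(n, 0, 0.25))
  out <- spearman_endpoint_comparison(tab, metrics = "metric")
  expect_gt(abs(out$rho_percent_loss), abs(out$rho_nadir))
})

test_that("PCA of collinear metrics has orthonormal loadings and oriented PC1", {
  tab <- toy_analysis_table(n = 50)
  set.seed(10)
  z <- rnorm(50)
  tab$body_Dmean <- 6 + 1.5 * z + rnorm(50, 0, 0.5)
  tab$lungs_sum_V5 <- 55 + 4 * z + rnorm(50, 0, 2)
  tab$heart_V5 <- 45 + 4 * z + rnorm(50, 0, 2)
  pca <- pca_dose(tab, metrics = c("body_Dmean", "lungs_sum_V5", "heart_V5"))
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$explained_fraction) <= 1e-9))
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # scores reconstruct from standardized data
  xs <- scale(as.matrix(tab[, pca$metrics]))
  expect_equal(unname(xs %*% pca$loadings[, 1]),
               cbind(unname(pca$pc1_scores)), tolerance = 1e-9)
  expect_gt(cor(pca$pc1_scores, tab$body_Dmean), 0)

  # two perfectly correlated metrics: PC1 explains everything
  tab$m1 <- z
  tab$m2 <- 3 * z + 1
  pca2 <- pca_dose(tab, metrics = c("m1", "m2"))
  expect_equal(pca2$explained_fraction[1], 1.0, tolerance = 1e-9)
})

test_that("multivariable fit recovers an exact linear identity", {
  tab <- toy_analysis_table(n = 40)
  tab$percent_loss <- 16 + 7 * tab$crt + 8 * tab$baseline_alc +
    2.4 * tab$edric
  rep <- fit_multivariable(tab, "edric", B = 10, seed = 1)
  est <- setNames(rep$terms$estimate, rep$terms$term)
  expect_equal(est[["(Intercept)"]], 16, tolerance = 1e-8)
  expect_equal(est[["crt"]], 7, tolerance = 1e-8)
  expect_equal(est[["baseline_alc"]], 8, tolerance = 1e-8)
  expect_equal(est[["edric"]], 2.4, tolerance = 1e-8)
  expect_equal(rep$r_squared, 1, tolerance = 1e-9)
  expect_true(all(rep$terms$ci_lower <= rep$terms$estimate &
                    rep$terms$estimate <= rep$terms$ci_upper))

  tab$edric_const <- 3
  expect_error(fit_multivariable(tab, "edric_const", B = 5),
               class = "ril_analysis_error")
})

test_that("screen R2 for the dose summary equals the restricted model R2", {
  set.seed(5)
  tab <- toy_analysis_table(n = 60)
  tab$percent_loss <- 30 + 6 * tab$crt + 2 * tab$edric + rnorm(60, 0, 4)
  screen <- univariable_screen(tab, metrics = "edric", stratify = FALSE)
  direct <- summary(lm(percent_loss ~ crt + edric, data = tab))$r.squared
  expect_equal(screen$r_squared, direct, tolerance = 1e-12)
})

test_that("model quality metrics are invariant to predictor rescaling", {
  set.seed(6)
  tab <- toy_analysis_table(n = 80)
  tab$percent_loss <- 30 + 6 * tab$crt + 2 * tab$edric +
    5 * tab$baseline_alc + rnorm(80, 0, 4)
  m1 <- fit_multivariable(tab, "edric", B = 20, seed = 9)
  tab2 <- tab
  tab2$edric <- tab2$edric * 100 - 7
  m2 <- fit_multivariable(tab2, "edric", B = 20, seed = 9)
  expect_equal(m1$r_squared, m2$r_squared, tolerance = 1e-12)
  expect_equal(m1$aic, m2$aic, tolerance = 1e-9)
  expect_equal(m1$mse, m2$mse, tolerance = 1e-9)
})

test_that("optimism correction is exact for the identity resample and bounded above", {
  set.seed(12)
  tab <- toy_analysis_table(n = 50)
  tab$percent_loss <- 30 + 6 * tab$crt + 2 * tab$edric + rnorm(50, 0, 6)
  fml <- percent_loss ~ crt + baseline_alc + edric
  res <- optimism_corrected_r2(fml, tab, indices = list(seq_len(50)))
  expect_equal(res$optimism, 0, tolerance = 1e-12)
  expect_equal(res$corrected, res$apparent, tolerance = 1e-12)

  res2 <- optimism_corrected_r2(fml, tab, B = 100, seed = 2)
  expect_lte(res2$corrected, res2$apparent + 0.02)
})
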