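test_that("baseline selection picks the eligible measurement closest to RT start", {
  bl <- select_baseline(c(-30, 1, 8), c(2.4, 2.1, 1.5))
  expect_equal(bl$baseline_alc, 2.1)
  expect_equal(bl$baseline_time, 1)

  bl2 <- select_baseline(c(-10, -3), c(2.0, 2.2))
  expect_equal(bl2$baseline_alc, 2.2)
  expect_equal(bl2$baseline_time, -3)

  # ties in |t| break toward the later measurement
  bl3 <- select_baseline(c(-1, 1), c(1.8, 2.0))
  expect_equal(bl3$baseline_time, 1)

  # measurements older than 91 days pre-RT are ineligible
  expect_error(select_baseline(c(-120, 5), c(2.0, 1.5)),
               class = "ril_baseline_missing")
  expect_error(select_baseline(c(3, 10), c(2.0, 1.5)),
               class = "ril_baseline_missing")
})

test_that("noiseless decay series recover their generating parameters", {
  s <- decay_series(1.6, 0.1, 0.4)
  fit <- fit_decay(s$times, s$values)
  expect_equal(fit$status, "success")
  expect_equal(fit$a, 1.6, tolerance = 1e-6)
  expect_equal(fit$b, 0.1, tolerance = 1e-6)
  expect_equal(fit$c, 0.4, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$window_end_T, 42)
})

test_that("fit QC flags super-fast decay, poor fits and short series", {
  s <- decay_series(1.6, 1.4, 0.4)
  fit <- fit_decay(s$times, s$values)
  expect_equal(fit$status, "fail_b_range")
  expect_gt(fit$b, 1)

  short <- fit_decay(c(0, 7), c(2.0, 1.5))
  expect_equal(short$status, "fail_insufficient_points")

  # rising series cannot be fit by a bounded decay: b-range or R2 failure
  t <- c(0, 7, 14, 21, 28, 35, 42)
  set.seed(8)
  rising <- fit_decay(t, 2 * (1 + 0.012 * t) + rnorm(7, 0, 0.1))
  expect_true(rising$status %in% c("fail_b_range", "fail_r2"))
})

test_that("constant series yield a perfect flat fit", {
  t <- c(0, 7, 14, 21, 28, 35, 42)
  fit <- fit_decay(t, rep(2, 7))
  pred <- fit$a * exp(-fit$b * t) + fit$c
  expect_equal(pred, rep(2, 7), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
})

test_that("pre-RT baseline is mapped to day 0 and duplicates averaged", {
  # baseline at day -5 acts as the day-0 value
  s <- decay_series(1.6, 0.1, 0.4, days = c(7, 14, 21, 28, 35, 42))
  fit <- fit_decay(c(-5, s$times), c(2.0, s$values))
  expect_equal(fit$status, "success")
  expect_equal(fit$a, 1.6, tolerance = 1e-6)

  # duplicate same-day values are averaged, not double-weighted
  s2 <- decay_series(1.6, 0.1, 0.4)
  times <- c(s2$times, 14)
  vals <- c(s2$values, s2$values[3])
  fit2 <- fit_decay(times, vals)
  expect_equal(fit2$n_points, 7)
  expect_equal(fit2$b, 0.1, tolerance = 1e-6)
})

test_that("closed-form AUC matches examples and the b -> 0 limit", {
  expect_equal(auc_closed_form(c(1.6, 0.1, 0.4), 45), 33.8223,
               tolerance = 1e-4)
  expect_equal(auc_closed_form(c(0, 0.3, 0.4), 45), 18.0)
  expect_equal(auc_closed_form(c(1, 0, 1), 10), 20.0)
  expect_error(auc_closed_form(c(1, 0.1, 0.4), 0), class = "ril_domain_error")
  expect_error(auc_closed_form(c(1, -0.2, 0.4), 10),
               class = "ril_domain_error")
})

test_that("percentage loss matches the closed-form oracle and identities", {
  expect_equal(percent_alc_loss(c(1.6, 0.1, 0.4), 2.0, 45),
               100 * (1 - trapz_auc(1.6, 0.1, 0.4, 45) / 90),
               tolerance = 1e-4)
  expect_equal(percent_alc_loss(c(1.6, 0.1, 0.4), 2.0, 45), 62.42,
               tolerance = 1e-4)
  # plateau at baseline: no loss
  expect_equal(percent_alc_loss(c(0, 0.5, 2.0), 2.0, 45), 0)
  expect_error(percent_alc_loss(c(1, 0.1, 0.4), 0, 45),
               class = "ril_domain_error")
})

test_that("percentage loss is scale-invariant and monotone in the plateau", {
  set.seed(31)
  for (i in 1:25) {
    a <- runif(1, 0.2, 3); b <- runif(1, 0.01, 0.9); c0 <- runif(1, 0, 1)
    bl <- a + c0
    t_end <- runif(1, 20, 60)
    k <- runif(1, 0.5, 10)
    expect_equal(percent_alc_loss(c(a, b, c0), bl, t_end),
                 percent_alc_loss(c(k * a, b, k * c0), k * bl, t_end),
                 tolerance = 1e-9)
    # larger plateau, same a and b: strictly less loss
    expect_lt(percent_alc_loss(c(a, b, c0 + 0.2), bl, t_end),
              percent_alc_loss(c(a, b, c0), bl, t_end))
  }
})

test_that("nadir and CTCAE grading follow the thresholds", {
  expect_equal(alc_nadir(c(0, 10, 20, 30), c(2.0, 1.2, 0.6, 0.9)), 0.6)
  expect_equal(alc_nadir(c(5), c(1.1)), 1.1)
  expect_error(alc_nadir(c(50, 60), c(1, 1), window = 45),
               class = "ril_domain_error")

  expect_equal(ctcae_grade(c(0.49, 0.54, 0.15, 0.85, 1.2)),
               c(3L, 2L, 4L, 1L, 0L))
  expect_error(ctcae_grade(-0.1), class = "ril_domain_error")
})

test_that("compute_endpoints assigns one status per patient with coherent fields", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 21))
  ep <- compute_endpoints(co$blood)
  expect_equal(nrow(ep), 60)
  expect_true(all(ep$status %in% c("success", "fail_insufficient_points",
                                   "fail_no_converge", "fail_b_range",
                                   "fail_r2", "fail_no_baseline")))
  ok <- ep$status == "success"
  expect_true(all(!is.na(ep$percent_loss[ok])))
  expect_true(all(is.na(ep$percent_loss[!ok])))
  expect_true(all(ep$a[ok] >= 0 & ep$c[ok] >= 0))
  expect_true(all(ep$b[ok] >= 0 & ep$b[ok] <= 1))
  expect_true(all(ep$r_squared[ok] >= 0.5))
  expect_equal(ep$severe_ril, ep$nadir < 0.5)
})
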