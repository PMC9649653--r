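test_that("fluorescence calibration recovers exact and noisy standard lines", {
  cal <- calibrate_fluorescence(c(0, 10, 20), c(0, 1000, 2000))
  expect_equal(cal$slope, 100)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(counts_to_uM(cal, 1500), 15)
  expect_error(calibrate_fluorescence(5, 500), "two distinct")
  expect_error(calibrate_fluorescence(c(5, 5), c(400, 600)), "two distinct")
  # noisy recovery: known slope 87.5, 1% multiplicative noise, n = 8
  set.seed(42)
  conc <- seq(5, 200, length.out = 8)
  counts <- 87.5 * conc * (1 + rnorm(8, 0, 0.01))
  cal2 <- calibrate_fluorescence(conc, counts)
  expect_lt(abs(cal2$slope - 87.5) / 87.5, 0.02)
})

test_that("initial-velocity windows follow the linearity/conversion policy", {
  t <- seq(0, 600, by = 10)
  # exactly linear: slope recovered regardless of window
  est <- estimate_initial_velocity(t, 0.002 * t, peptide_conc_uM = 10)
  expect_equal(est$v0, 0.002, tolerance = 1e-10)
  # flat blank curve with noise: accepted with v0 ~ 0
  set.seed(7)
  est0 <- estimate_initial_velocity(t, rnorm(length(t), 0, 1e-4),
                                    peptide_conc_uM = 10)
  expect_lt(est0$v0, 1e-4)
  # depleting curve: window capped at 10% conversion keeps bias under 5%
  sc <- kinetics_scenario(noise_cv = 0, seed = 1)
  curves <- gen_progress_curves(sc, data.frame(atp_uM = 1000, pept_uM = 10),
                                t_end = 600, dt = 5)
  cv <- curves[[1]]
  est2 <- estimate_initial_velocity(cv$time_s, cv$product_uM,
                                    peptide_conc_uM = 10)
  expect_lt(abs(est2$v0 - cv$v0_true) / cv$v0_true, 0.05)
  expect_error(estimate_initial_velocity(t[1:3], (0.002 * t)[1:3]),
               "strictly increasing|usable points|failed")
})

test_that("Michaelis-Menten fit recovers generating parameters", {
  s <- c(0.98, 3.9, 15.6, 62.5, 250, 1000, 3000)
  v <- 0.06 * s / (158 + s)
  fit <- fit_michaelis_menten(s, v, tkd_conc_nM = 100)
  expect_equal(fit$km, 158, tolerance = 1e-6)
  expect_equal(fit$vmax, 0.06, tolerance = 1e-6)
  expect_equal(fit$apparent_kcat, 0.06 / 0.1, tolerance = 1e-6)
  # model identity: v at Km is Vmax/2
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)
  # noisy simulation: median Km error within 10% over 100 replicates
  set.seed(11)
  s2 <- 0.98 * 2^(0:11); s2 <- s2[s2 <= 3000]
  errs <- replicate(100, {
    vn <- (0.06 * s2 / (23 + s2)) * (1 + rnorm(length(s2), 0, 0.05))
    abs(fit_michaelis_menten(s2, vn, 100)$km - 23) / 23
  })
  expect_lt(median(errs), 0.10)
})

test_that("IC50 fit inverts the one-parameter competition model", {
  d <- c(0, 10^seq(0, 4.6, length.out = 10))
  r <- 100 / (1 + d / 232)
  fit <- fit_ic50(d, r)
  expect_equal(fit$ic50, 232, tolerance = 1e-6)
  expect_false(fit$censored)
  # model identity: rate at the fitted IC50 is 50%
  expect_equal(100 / (1 + fit$ic50 / fit$ic50), 50)
  # censoring: no dose reaches 20% inhibition
  weak <- fit_ic50(d, 100 / (1 + d / 1e7))
  expect_true(weak$censored)
  expect_true(is.na(weak$ic50))
  expect_match(weak$bound, "^>")
  # noisy recovery: median error within 15% over 100 replicates
  set.seed(12)
  errs <- replicate(100, {
    tb <- gen_dose_response(36, d, noise_cv = 0.04,
                            seed = sample.int(1e6, 1))
    abs(fit_ic50(tb$inhibitor_nM, tb$rate_pct)$ic50 - 36) / 36
  })
  expect_lt(median(errs), 0.15)
})

test_that("Cheng-Prusoff fitting and prediction are mutually consistent", {
  atp <- c(0.98, 7.8, 62.5, 500, 2000)
  ic50 <- predict_ic50(5.3, 23, atp)
  # joint two-parameter fit
  fit <- fit_ki_cheng_prusoff(atp, ic50)
  expect_equal(fit$ki, 5.3, tolerance = 1e-8)
  expect_equal(fit$km_atp, 23, tolerance = 1e-6)
  expect_false(fit$noncompetitive)
  # one-parameter fit with known Km
  fit1 <- fit_ki_cheng_prusoff(atp, ic50, km_atp = 23)
  expect_equal(fit1$ki, 5.3, tolerance = 1e-8)
  # round-trip identity: refitted parameters reproduce the series
  expect_equal(predict_ic50(fit$ki, fit$km_atp, atp), ic50, tolerance = 1e-6)
  # IC50 extrapolated to zero ATP equals K_I
  expect_equal(predict_ic50(5.3, 23, 0), 5.3)
  # flat series flags non-competitive behaviour
  set.seed(3)
  flat <- fit_ki_cheng_prusoff(atp, 30 + rnorm(5, 0, 0.5))
  expect_true(flat$noncompetitive)
  expect_true(is.na(flat$km_atp))
  expect_error(fit_ki_cheng_prusoff(atp[1:2], ic50[1:2]), "3 distinct")
})

test_that("forward Cheng-Prusoff predictions match hand arithmetic", {
  expect_equal(predict_ic50(5.3, 23, 1000), 5.3 * (1 + 1000 / 23))
  expect_equal(round(predict_ic50(5.3, 23, 1000), 1), 235.7)
  expect_equal(round(predict_ic50(4.2, 101, 1000), 1), 45.8)
})

test_that("active-site correction reproduces the endpoint-titration estimator", {
  cor <- correct_kcat(0.91, 100, 36)
  expect_equal(cor$active_fraction, 0.72)
  expect_equal(round(cor$corrected_kcat, 2), 1.26)
  # fully active preparation: IC50 = [TKD]/2 leaves kcat unchanged
  expect_equal(correct_kcat(0.5, 80, 40)$corrected_kcat, 0.5)
  # 10x TKD assay, assay-scale IC50
  expect_equal(round(correct_kcat(0.044, 1000, 420)$corrected_kcat, 3), 0.052)
  expect_warning(correct_kcat(1, 100, 80), "active fraction")
  expect_error(correct_kcat(-1, 100, 30), "positive")
})

test_that("fold-change tables propagate error and test group differences", {
  tab <- data.frame(variant = c("A", "B"),
                    mean = c(31, 232), sd = c(8, 48), n = c(6, 6))
  fc <- fold_change_table(tab, "A")
  expect_equal(fc$fold[fc$variant == "B"], 232 / 31)
  expect_equal(fc$fold[fc$variant == "A"], 1)
  # delta-method SD of the ratio
  expect_equal(fc$fold_sd[2], (232 / 31) * sqrt((48 / 232)^2 + (8 / 31)^2))
  expect_lt(fc$p[2], 0.001)
  # identical groups: fold 1, p = 1
  same <- fold_change_table(data.frame(variant = c("A", "B"),
                                       mean = c(10, 10), sd = c(2, 2),
                                       n = c(3, 3)), "A")
  expect_equal(same$fold[2], 1)
  expect_equal(round(same$p[2], 10), 1)
  expect_error(fold_change_table(data.frame(variant = "A", mean = 0,
                                            sd = 1, n = 3), "A"),
               "zero")
})
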