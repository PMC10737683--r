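test_that("rmse matches hand computation", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0.1, -0.1), c(0, 0)), 0.1)
  expect_equal(rmse(c(1.0, 0.8, 0.7), c(0.9, 0.9, 0.6)), sqrt(0.03 / 3))
  expect_error(rmse(1:3, 1:2), "length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("noise-free synthetic series recover the true coefficients within 1%", {
  cfg <- patient_config(frac_post = 1)
  pats <- generate_patients(2, cfg, seed = 31)
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    tr <- noise_free_series(p)
    vols <- split_volumes(watson_tbw(p$sex, p$age, p$height_cm, p$weight_kg))
    fit <- fit_transfer_coefficients(tr$plasma, vols, p$kd,
                                     p$duration_min, p$post_min)
    expect_lt(abs(fit$k1 - p$k1) / p$k1, 0.01)
    expect_lt(abs(fit$k2 - p$k2) / p$k2, 0.01)
    expect_lt(fit$rmse, 1e-5)
    expect_true(fit$converged)
  }
})

test_that("a pure-exponential series is fitted to within the noise-free floor", {
  vols <- ref_vols()
  at <- c(seq(0, 240, 30))
  measured <- tibble::tibble(
    time_min = at,
    conc = closed_form_c1(1.4, 9, vols$v1, at)
  )
  fit <- fit_transfer_coefficients(measured, vols, kd = 9, duration_min = 240)
  expect_lt(fit$rmse, 1e-3)
  expect_equal(predict(fit), measured$conc, tolerance = 1e-2)
})

test_that("fitted RMSE beats every probe on a log-spaced parameter lattice", {
  p <- generate_patients(1, patient_config(frac_post = 1), seed = 57)
  tr <- generate_treatment(p, week = 1, cv = 0.056, seed = 57)
  vols <- split_volumes(watson_tbw(p$sex, p$age, p$height_cm, p$weight_kg))
  fit <- fit_transfer_coefficients(tr$plasma, vols, p$kd,
                                   p$duration_min, p$post_min)
  lattice <- exp(seq(log(0.1), log(1000), length.out = 20))
  for (k1 in lattice) {
    for (k2 in lattice) {
      h <- stable_step(vols, k1, k2, p$kd)
      traj <- phos_simulate(vols, k1, k2, p$kd, tr$plasma$conc[1],
                            p$duration_min, p$post_min, step_min = h)
      probe <- rmse(tr$plasma$conc, sample_traj(traj, tr$plasma$time_min))
      expect_lte(fit$rmse, probe + 1e-12)
    }
  }
})

test_that("fitting is deterministic: identical inputs give identical results", {
  p <- generate_patients(1, seed = 8)
  tr <- generate_treatment(p, week = 1, cv = 0.056, seed = 8)
  vols <- split_volumes(watson_tbw(p$sex, p$age, p$height_cm, p$weight_kg))
  f1 <- fit_transfer_coefficients(tr$plasma, vols, p$kd, p$duration_min, 0)
  f2 <- fit_transfer_coefficients(tr$plasma, vols, p$kd, p$duration_min, 0)
  expect_identical(f1$k1, f2$k1)
  expect_identical(f1$k2, f2$k2)
  expect_identical(f1$rmse, f2$rmse)
  expect_identical(f1$starts, f2$starts)
})

test_that("a flat RMSE profile in k2 is flagged unidentifiable, not reported as truth", {
  # data generated with k1 = 0: k2 cannot influence plasma, so its profile is flat
  vols <- ref_vols()
  at <- seq(0, 240, 30)
  measured <- tibble::tibble(time_min = at,
                             conc = closed_form_c1(1.5, 9, vols$v1, at))
  fit <- fit_transfer_coefficients(measured, vols, kd = 9, duration_min = 240)
  expect_false(fit$k2_identifiable)
})

test_that("degenerate measured series are rejected or warned about", {
  vols <- ref_vols()
  expect_error(
    fit_transfer_coefficients(
      tibble::tibble(time_min = c(0, 30), conc = c(1.4, 1.3)),
      vols, 9, 240),
    "3 measured")
  expect_error(
    fit_transfer_coefficients(
      tibble::tibble(time_min = c(30, 60, 90), conc = c(1.4, 1.3, 1.2)),
      vols, 9, 240),
    "time 0")
  expect_warning(
    fit_transfer_coefficients(
      tibble::tibble(time_min = c(0, 30, 60), conc = rep(1.4, 3)),
      vols, 9, 240),
    "flat")
})

test_that("tidy and glance expose the fit in broom shape", {
  p <- generate_patients(1, seed = 12)
  tr <- noise_free_series(p)
  vols <- split_volumes(watson_tbw(p$sex, p$age, p$height_cm, p$weight_kg))
  fit <- fit_transfer_coefficients(tr$plasma, vols, p$kd, p$duration_min,
                                   p$post_min)
  td <- tidy(fit)
  expect_equal(td$term, c("k1", "k2", "kd", "v1", "v2", "v3"))
  expect_true(all(td$fitted[1:2]))
  expect_false(any(td$fitted[3:6]))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$refitted)
  expect_gte(gl$r_squared, 0)
  expect_lte(gl$r_squared, 1)
})

test_that("frozen evaluation re-estimates nothing", {
  p <- generate_patients(1, seed = 44)
  tr1 <- generate_treatment(p, week = 1, cv = 0.03, seed = 44)
  tr2 <- generate_treatment(p, week = 2, cv = 0.03, seed = 45)
  vols <- split_volumes(watson_tbw(p$sex, p$age, p$height_cm, p$weight_kg))
  fit <- fit_transfer_coefficients(tr1$plasma, vols, p$kd, p$duration_min,
                                   p$post_min)
  ev <- evaluate_treatment(fit, tr2$plasma, p$duration_min, p$post_min)
  expect_identical(ev$k1, fit$k1)
  expect_identical(ev$k2, fit$k2)
  expect_identical(ev$kd, fit$kd)
  expect_false(ev$refitted)
  # but the initial condition comes from the new treatment
  expect_equal(ev$c0, tr2$plasma$conc[1])
})
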