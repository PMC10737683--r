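test_that("patient generation is deterministic given the seed", {
  a <- generate_patients(5, seed = 99)
  b <- generate_patients(5, seed = 99)
  expect_identical(a, b)
  c <- generate_patients(5, seed = 100)
  expect_false(identical(a, c))
})

test_that("drawn parameters respect the configured ranges and design", {
  cfg <- patient_config()
  pats <- generate_patients(200, cfg, seed = 13)
  expect_true(all(pats$k1 >= cfg$k1_range[1] & pats$k1 <= cfg$k1_range[2]))
  expect_true(all(pats$k2 >= cfg$k2_range[1] & pats$k2 <= cfg$k2_range[2]))
  expect_true(all(pats$kd >= cfg$kd_range[1] & pats$kd <= cfg$kd_range[2]))
  expect_true(all(pats$duration_min %in% cfg$durations_min))
  expect_true(all(pats$c0_hd1 > 0))
  expect_equal(sum(pats$includes_post), round(200 / 3))
  expect_true(all(pats$post_min[pats$includes_post] == 120))
  expect_true(all(pats$post_min[!pats$includes_post] == 0))
})

test_that("large cohorts reproduce the configured anthropometric means", {
  cfg <- patient_config()
  pats <- generate_patients(1000, cfg, seed = 29)
  se <- cfg$weight_sd / sqrt(1000)
  expect_lt(abs(mean(pats$weight_kg) - cfg$weight_mean), 3 * se)
  se_h <- cfg$height_sd / sqrt(1000)
  expect_lt(abs(mean(pats$height_cm) - cfg$height_mean), 3 * se_h)
})

test_that("degenerate (zero-variance) configurations return the exact values", {
  cfg <- patient_config(age_sd = 0, weight_sd = 0, height_sd = 0,
                        c0_sd = 0, flow_sd = 0,
                        k1_range = c(20, 20), k2_range = c(10, 10),
                        kd_range = c(9, 9), durations_min = 240)
  p <- generate_patients(3, cfg, seed = 1)
  expect_equal(p$age, rep(cfg$age_mean, 3))
  expect_equal(p$weight_kg, rep(cfg$weight_mean, 3))
  expect_equal(p$k1, rep(20, 3))
  expect_equal(p$kd, rep(9, 3))
})

test_that("impossible truncation errors out", {
  expect_error(
    generate_patients(3, patient_config(weight_mean = 5, weight_sd = 0.1,
                                        weight_min = 35), seed = 1),
    "Truncation")
})

test_that("emitted sample counts match the study design", {
  cfg <- patient_config(durations_min = 240, frac_post = 0)
  p <- generate_patients(1, cfg, seed = 2)
  tr <- generate_treatment(p, week = 1, cv = 0.056, seed = 2)
  expect_equal(nrow(tr$plasma), 9)  # t = 0, every 30 min, end
  expect_equal(tr$dialysate$time_min, c(60, 120, 180, 240))
  cfg_post <- patient_config(durations_min = 240, frac_post = 1)
  p2 <- generate_patients(1, cfg_post, seed = 2)
  tr2 <- generate_treatment(p2, week = 1, cv = 0.056, seed = 2)
  expect_equal(nrow(tr2$plasma), 13) # + 30/60/90/120 min postdialytic
  expect_equal(max(tr2$plasma$time_min), 360)
})

test_that("noise-free treatments reproduce the model exactly and round-trip the clearance", {
  p <- generate_patients(1, patient_config(frac_post = 1), seed = 21)
  tr <- generate_treatment(p, week = 1, cv = 0, seed = 21)
  vols <- split_volumes(watson_tbw(p$sex, p$age, p$height_cm, p$weight_kg))
  traj <- phos_simulate(vols, p$k1, p$k2, p$kd, p$c0_hd1,
                        p$duration_min, p$post_min)
  expect_equal(tr$plasma$conc, sample_traj(traj, tr$plasma$time_min))
  kd_est <- suppressWarnings(
    dialyzer_clearance(tr$plasma, tr$dialysate, tr$flow_ml_min))
  expect_equal(as.numeric(kd_est), p$kd, tolerance = 1e-9)
})

test_that("treatment generation is deterministic and weeks share the truth", {
  p <- generate_patients(1, seed = 77)
  a <- generate_treatment(p, week = 1, cv = 0.056, seed = 5)
  b <- generate_treatment(p, week = 1, cv = 0.056, seed = 5)
  expect_identical(a, b)
  # week 2 scales the predialytic concentration by the configured factor
  w1 <- generate_treatment(p, week = 1, cv = 0, seed = 5)
  w2 <- generate_treatment(p, week = 2, cv = 0, seed = 5)
  expect_equal(w2$plasma$conc[1] / w1$plasma$conc[1], p$hd2_factor,
               tolerance = 1e-9)
})

test_that("duplicate synthetic dialysate samples reproduce the assay CV", {
  p <- generate_patients(1, patient_config(durations_min = 240), seed = 3)
  cv <- 0.056
  pair_cv2 <- c()
  for (s in 1:125) {
    a <- generate_treatment(p, week = 1, cv = cv, seed = 1000 + s)
    b <- generate_treatment(p, week = 1, cv = cv, seed = 5000 + s)
    m <- (a$dialysate$conc + b$dialysate$conc) / 2
    sd2 <- (a$dialysate$conc - b$dialysate$conc)^2 / 2
    pair_cv2 <- c(pair_cv2, sd2 / m^2)
  }
  # pooled duplicate CV over 500 pairs: within one percentage point
  expect_lt(abs(sqrt(mean(pair_cv2)) - cv), 0.01)
})

test_that("generate_study emits the canonical long layout for every treatment", {
  pats <- generate_patients(3, seed = 61)
  st <- generate_study(pats, cv = 0.056, seed = 61)
  expect_setequal(names(st$samples),
                  c("patient_id", "treatment", "kind", "time_min", "conc"))
  expect_setequal(unique(st$samples$treatment), c("HD1", "HD2"))
  expect_equal(nrow(st$treatments), 6)
  expect_true(all(st$samples$conc > 0))
  # deterministic
  expect_identical(st, generate_study(pats, cv = 0.056, seed = 61))
})
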