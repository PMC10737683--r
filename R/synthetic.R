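#' Configuration for the synthetic patient generator
#'
#' Defaults emulate the study population the package is designed around:
#' a small maintenance-hemodialysis cohort (two thirds male, age 71.6 +/- 10.6
#' years, dry weight 72.2 +/- 14.2 kg, height 160.3 +/- 8.2 cm), predialytic
#' plasma phosphate 1.4 +/- 0.4 mmol/L at the first treatment rising by a
#' factor of about 1.7/1.4 a week later, dialyzer phosphate clearance in the
#' observed 6.5-11.5 L/h band, mass transfer coefficients log-uniform over
#' the bulk of the fitted range (k1 in 5-100, k2 in 1-30 L/h), treatment
#' durations in {180, 210, 240, 270} min and dialysate flow 445.7 +/- 55.4
#' mL/min (truncated to the machine range 318-547). One third of patients
#' also undergo a 120-min postdialytic sampling window.
#'
#' @param p_male Probability of male sex.
#' @param age_mean,age_sd,age_min,age_max Age distribution (years), truncated.
#' @param weight_mean,weight_sd,weight_min Weight distribution (kg), truncated.
#' @param height_mean,height_sd,height_min Height distribution (cm), truncated.
#' @param k1_range,k2_range Log-uniform ranges for the true transfer
#'   coefficients (L/h).
#' @param kd_range Uniform range for the true dialyzer clearance (L/h).
#' @param c0_mean,c0_sd,c0_min First-treatment predialytic concentration
#'   distribution (mmol/L), truncated.
#' @param hd2_factor_mean,hd2_factor_sd Week-2 predialytic concentration
#'   multiplier distribution (truncated positive).
#' @param durations_min Candidate dialysis durations (minutes).
#' @param flow_mean,flow_sd,flow_range Mean dialysate flow distribution
#'   (mL/min), truncated to `flow_range`.
#' @param frac_post Fraction of patients with a postdialytic sampling window.
#' @param post_min Length of that window (minutes).
#'
#' @return A list of class `phoskin_patient_config`.
#' @export
patient_config <- function(p_male = 2 / 3,
                           age_mean = 71.6, age_sd = 10.6,
                           age_min = 18, age_max = 95,
                           weight_mean = 72.2, weight_sd = 14.2, weight_min = 35,
                           height_mean = 160.3, height_sd = 8.2, height_min = 120,
                           k1_range = c(5, 100), k2_range = c(1, 30),
                           kd_range = c(6.5, 11.5),
                           c0_mean = 1.4, c0_sd = 0.4, c0_min = 0.6,
                           hd2_factor_mean = 1.7 / 1.4, hd2_factor_sd = 0.1,
                           durations_min = c(180, 210, 240, 270),
                           flow_mean = 445.7, flow_sd = 55.4,
                           flow_range = c(318, 547),
                           frac_post = 1 / 3, post_min = 120) {
  cfg <- as.list(environment())
  stopifnot(all(k1_range > 0), all(k2_range > 0), all(kd_range > 0),
            frac_post >= 0, frac_post <= 1, post_min >= 0)
  structure(cfg, class = "phoskin_patient_config")
}

## Truncated normal by rejection; errors out if the truncation admits almost
## no mass (impossible configuration).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper) abort("Degenerate distribution outside its truncation bounds.")
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (tries in 1:1000) {
    draw <- rnorm(n * 2, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  abort("Truncation bounds reject essentially all draws; check the configuration.")
}

rloguniform <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Generate a cohort of virtual hemodialysis patients
#'
#' Draws anthropometrics, true kinetic parameters, predialytic
#' concentrations, schedules and dialysate flows from the distributions in a
#' [patient_config()]. Deterministic given the seed.
#'
#' @param n Number of patients.
#' @param config A [patient_config()].
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return A tibble with one row per patient: `patient_id`, `sex`, `age`,
#'   `height_cm`, `weight_kg`, true `k1`, `k2`, `kd` (L/h), `c0_hd1`,
#'   `hd2_factor` (mmol/L scale factor for the week-2 predialytic
#'   concentration), `duration_min`, `post_min` (0 for intradialytic-only
#'   patients), `flow_ml_min`, `includes_post`.
#' @export
generate_patients <- function(n, config = patient_config(), seed = 1L) {
  stopifnot(n >= 1)
  cfg <- config
  withr::with_seed(as.integer(seed), {
    n_post <- round(n * cfg$frac_post)
    post_ids <- sample(n, n_post)
    tibble::tibble(
      patient_id = seq_len(n),
      sex = ifelse(runif(n) < cfg$p_male, "male", "female"),
      age = rnorm_trunc(n, cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max),
      height_cm = rnorm_trunc(n, cfg$height_mean, cfg$height_sd, cfg$height_min),
      weight_kg = rnorm_trunc(n, cfg$weight_mean, cfg$weight_sd, cfg$weight_min),
      k1 = rloguniform(n, cfg$k1_range),
      k2 = rloguniform(n, cfg$k2_range),
      kd = runif(n, cfg$kd_range[1], cfg$kd_range[2]),
      c0_hd1 = rnorm_trunc(n, cfg$c0_mean, cfg$c0_sd, cfg$c0_min),
      hd2_factor = rnorm_trunc(n, cfg$hd2_factor_mean, cfg$hd2_factor_sd, 0.5),
      duration_min = cfg$durations_min[sample.int(length(cfg$durations_min),
                                                  n, replace = TRUE)],
      includes_post = .data$patient_id %in% post_ids,
      post_min = ifelse(.data$patient_id %in% post_ids, cfg$post_min, 0),
      flow_ml_min = rnorm_trunc(n, cfg$flow_mean, cfg$flow_sd,
                                cfg$flow_range[1], cfg$flow_range[2])
    )
  })
}

## Multiplicative lognormal assay noise with unit mean and the requested
## coefficient of variation.
noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one treatment's sampled series for a virtual patient
#'
#' Runs the true model for the patient and emits the study's sampling design:
#' plasma at t = 0, every 30 min, and the end of dialysis (plus 30/60/90/120
#' min postdialytic samples for patients with a postdialytic window), and
#' dialysate outflow samples hourly from the 1-h mark. The dialysate
#' concentration is `kd * c1(t) / flow` (in consistent units), which keeps
#' the clearance estimator consistent on synthetic data. Independent
#' multiplicative lognormal assay noise at the configured CV is applied to
#' every emitted concentration. Week 2 uses the same true coefficients but
#' the perturbed predialytic concentration (`c0_hd1 * hd2_factor`).
#'
#' @param patient One row of [generate_patients()] (data frame or list).
#' @param week 1 or 2.
#' @param cv Assay coefficient of variation as a fraction (default 0.056).
#' @param seed Integer seed for the noise draws.
#'
#' @return A list with elements `plasma` (tibble `time_min`, `conc`),
#'   `dialysate` (same columns), and `flow_ml_min`.
#' @export
generate_treatment <- function(patient, week = 1, cv = 0.056, seed = 1L) {
  p <- as.list(tibble::as_tibble(patient)[1, ])
  stopifnot(week %in% c(1, 2), cv >= 0)
  vols <- split_volumes(watson_tbw(p$sex, p$age, p$height_cm, p$weight_kg))
  c0 <- if (week == 1) p$c0_hd1 else p$c0_hd1 * p$hd2_factor
  traj <- phos_simulate(vols, p$k1, p$k2, p$kd, c0,
                        duration_min = p$duration_min, post_min = p$post_min,
                        step_min = stable_step(vols, p$k1, p$k2, p$kd))
  plasma_t <- unique(c(seq(0, p$duration_min, by = 30), p$duration_min))
  if (isTRUE(p$includes_post) && p$post_min > 0) {
    plasma_t <- c(plasma_t, p$duration_min + seq(30, p$post_min, by = 30))
  }
  dial_t <- seq(60, p$duration_min, by = 60)
  c1_plasma <- sample_traj(traj, plasma_t)
  c1_dial <- sample_traj(traj, dial_t)
  flow_l_h <- p$flow_ml_min * MIN_PER_H / 1000
  withr::with_seed(as.integer(seed), {
    plasma <- tibble::tibble(
      time_min = plasma_t,
      conc = c1_plasma * noise_factors(length(plasma_t), cv)
    )
    dialysate <- tibble::tibble(
      time_min = dial_t,
      conc = p$kd * c1_dial / flow_l_h * noise_factors(length(dial_t), cv)
    )
  })
  list(plasma = plasma, dialysate = dialysate, flow_ml_min = p$flow_ml_min)
}

#' Generate a full two-treatment synthetic study
#'
#' Produces, for every patient of a cohort, the HD1 and HD2 sampled series in
#' the pipeline's canonical long layout, plus a treatment table. All
#' randomness derives from `seed`.
#'
#' @param patients A cohort from [generate_patients()].
#' @param cv Assay coefficient of variation (fraction).
#' @param seed Integer seed.
#'
#' @return A list with `samples` (tibble: `patient_id`, `treatment`
#'   ("HD1"/"HD2"), `kind` ("plasma"/"dialysate"), `time_min`, `conc`) and
#'   `treatments` (tibble: `patient_id`, `treatment`, `duration_min`,
#'   `post_min`, `flow_ml_min`).
#' @export
generate_study <- function(patients, cv = 0.056, seed = 1L) {
  seed <- as.integer(seed)
  rows <- tidyr::expand_grid(i = seq_len(nrow(patients)), week = c(1L, 2L))
  parts <- purrr::pmap(rows, function(i, week) {
    p <- patients[i, ]
    sub_seed <- (seed + 7919L * i + 104729L * week) %% .Machine$integer.max
    tr <- generate_treatment(p, week = week, cv = cv, seed = sub_seed)
    label <- paste0("HD", week)
    samples <- dplyr::bind_rows(
      dplyr::mutate(tr$plasma, kind = "plasma"),
      dplyr::mutate(tr$dialysate, kind = "dialysate")
    )
    samples <- dplyr::mutate(samples, patient_id = p$patient_id,
                             treatment = label, .before = 1)
    list(
      samples = dplyr::select(samples, "patient_id", "treatment", "kind",
                              "time_min", "conc"),
      treatments = tibble::tibble(
        patient_id = p$patient_id, treatment = label,
        duration_min = p$duration_min, post_min = p$post_min,
        flow_ml_min = tr$flow_ml_min
      )
    )
  })
  list(
    samples = dplyr::bind_rows(purrr::map(parts, "samples")),
    treatments = dplyr::bind_rows(purrr::map(parts, "treatments"))
  )
}
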