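#' Run the two-treatment modify-then-validate study
#'
#' For every patient: derives compartment volumes from anthropometrics,
#' estimates dialyzer clearance from the first treatment's paired
#' plasma/dialysate samples, fits the two mass transfer coefficients to the
#' first treatment's plasma series, then evaluates the frozen model on the
#' second treatment (only the new predialytic concentration and schedule are
#' taken from HD2 — no component is re-estimated). Reports per-patient
#' parameters, goodness of fit, Fisher r-to-z temporal-robustness tests, and
#' modeled versus measured phosphate removal, plus subgroup summaries
#' (median and inclusive interquartile range of R^2, split by
#' intradialytic-only versus intra+postdialytic sampling).
#'
#' Per-patient failures are isolated: the study continues and the failure is
#' recorded in the `failures` table.
#'
#' @param patients Patient table: `patient_id`, `sex`, `age`, `height_cm`,
#'   `weight_kg`.
#' @param samples Long sample table: `patient_id`, `treatment` ("HD1"/"HD2"),
#'   `kind` ("plasma"/"dialysate"), `time_min`, `conc` (mmol/L).
#' @param treatments Treatment table: `patient_id`, `treatment`,
#'   `duration_min`, `post_min`, `flow_ml_min`.
#' @param control A [fit_control()].
#'
#' @return An object of class `phoskin_study`: a list with tibbles `params`
#'   (per-patient volumes, clearance and fitted coefficients), `fits`
#'   (per-treatment RMSE, R^2 and the per-patient z test), `removal`
#'   (modeled and measured removal per treatment), `summary` (subgroup
#'   medians with inclusive quartiles), `failures`, and `patient_fits`
#'   (the underlying `phoskin_fit` objects, for plotting).
#' @export
run_study <- function(patients, samples, treatments, control = fit_control()) {
  patients <- parameterize_patients(patients)
  samples <- tibble::as_tibble(samples)
  treatments <- tibble::as_tibble(treatments)

  results <- purrr::map(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    tryCatch(run_patient(p, samples, treatments, control),
             error = function(e) {
               warn(sprintf("Patient %s failed: %s", p$patient_id,
                            conditionMessage(e)))
               list(failure = tibble::tibble(patient_id = p$patient_id,
                                             error = conditionMessage(e)))
             })
  })
  ok <- purrr::keep(results, ~ is.null(.x$failure))
  failures <- dplyr::bind_rows(purrr::map(results, "failure"))

  fits <- dplyr::bind_rows(purrr::map(ok, "fit_row"))
  summary <- if (nrow(fits)) summarize_study(fits) else tibble::tibble()
  structure(
    list(
      params = dplyr::bind_rows(purrr::map(ok, "param_row")),
      fits = fits,
      removal = dplyr::bind_rows(purrr::map(ok, "removal_rows")),
      summary = summary,
      failures = failures,
      patient_fits = stats::setNames(purrr::map(ok, "models"),
                                     purrr::map_chr(ok, ~ as.character(.x$param_row$patient_id)))
    ),
    class = "phoskin_study"
  )
}

get_series <- function(samples, id, label, which) {
  out <- dplyr::filter(samples, .data$patient_id == id,
                       .data$treatment == label, .data$kind == which)
  dplyr::arrange(dplyr::select(out, "time_min", "conc"), .data$time_min)
}

get_treatment_row <- function(treatments, id, label) {
  row <- dplyr::filter(treatments, .data$patient_id == id, .data$treatment == label)
  if (nrow(row) != 1) {
    abort(sprintf("Expected exactly one %s treatment row for patient %s.", label, id))
  }
  row
}

run_patient <- function(p, samples, treatments, control) {
  id <- p$patient_id
  vols <- p[c("v1", "v2", "v3")]

  tr1 <- get_treatment_row(treatments, id, "HD1")
  tr2 <- get_treatment_row(treatments, id, "HD2")
  plasma1 <- get_series(samples, id, "HD1", "plasma")
  plasma2 <- get_series(samples, id, "HD2", "plasma")
  dial1 <- get_series(samples, id, "HD1", "dialysate")
  dial2 <- get_series(samples, id, "HD2", "dialysate")

  ## A declared postdialytic window with no postdialytic samples is treated
  ## as intradialytic-only.
  post1 <- effective_post(plasma1, tr1, id, "HD1")
  post2 <- effective_post(plasma2, tr2, id, "HD2")

  kd <- dialyzer_clearance(plasma1, dial1, tr1$flow_ml_min)
  hd1 <- fit_transfer_coefficients(plasma1, vols, as.numeric(kd),
                                   tr1$duration_min, post1, control)
  hd2 <- evaluate_treatment(hd1, plasma2, tr2$duration_min, post2)

  ## A numerically perfect correlation (noise-free data) makes the Fisher
  ## transform infinite: the comparison is undefined, reported as NA and
  ## counted as not significant.
  z <- if (anyNA(c(hd1$r, hd2$r)) ||
           max(abs(hd1$r), abs(hd2$r)) >= 1 - 1e-12) {
    tibble::tibble(z_observed = NA_real_, significant = FALSE)
  } else {
    fisher_z_compare(hd1$r, hd1$n, hd2$r, hd2$n)
  }

  list(
    param_row = tibble::tibble(
      patient_id = id, tbw = p$tbw, v1 = vols$v1, v2 = vols$v2, v3 = vols$v3,
      kd = as.numeric(kd), k1 = hd1$k1, k2 = hd1$k2,
      k2_identifiable = hd1$k2_identifiable, converged = hd1$converged
    ),
    fit_row = tibble::tibble(
      patient_id = id, includes_post = post1 > 0,
      duration_hd1 = tr1$duration_min, rmse_hd1 = hd1$rmse,
      r2_hd1 = hd1$r_squared,
      duration_hd2 = tr2$duration_min, rmse_hd2 = hd2$rmse,
      r2_hd2 = hd2$r_squared,
      z_observed = z$z_observed, significant = z$significant
    ),
    removal_rows = tibble::tibble(
      patient_id = id, treatment = c("HD1", "HD2"),
      duration_min = c(tr1$duration_min, tr2$duration_min),
      modeled_mmol = c(modeled_removal(hd1$trajectory),
                       modeled_removal(hd2$trajectory)),
      measured_mmol = c(
        measured_removal(dial1, tr1$flow_ml_min, tr1$duration_min),
        measured_removal(dial2, tr2$flow_ml_min, tr2$duration_min)
      )
    ),
    models = list(hd1 = hd1, hd2 = hd2)
  )
}

effective_post <- function(plasma, tr, id, label) {
  has_post <- any(plasma$time_min > tr$duration_min + 1e-9)
  if (tr$post_min > 0 && !has_post) {
    warn(sprintf(
      "Patient %s %s declares a postdialytic window but has no postdialytic samples; treated as intradialytic-only.",
      id, label))
    return(0)
  }
  if (has_post) tr$post_min else 0
}

summarize_study <- function(fits) {
  long <- tidyr::pivot_longer(
    dplyr::select(fits, "patient_id", "includes_post", "r2_hd1", "r2_hd2"),
    cols = c("r2_hd1", "r2_hd2"),
    names_to = "treatment", names_prefix = "r2_", values_to = "r_squared"
  )
  long$treatment <- toupper(long$treatment)
  long$subgroup <- ifelse(long$includes_post, "intra+postdialytic",
                          "intradialytic-only")
  dplyr::reframe(
    dplyr::group_by(long, .data$subgroup, .data$treatment),
    n = dplyr::n(),
    inclusive_quartiles(.data$r_squared)
  )
}

#' @export
print.phoskin_study <- function(x, ...) {
  cat(sprintf("<phoskin study: %d patient(s), %d failure(s)>\n",
              nrow(x$params), nrow(x$failures)))
  if (nrow(x$summary)) {
    cat("R^2 summary (median, inclusive IQR):\n")
    print(x$summary)
  }
  invisible(x)
}

#' Tidy a study into its per-treatment fit table
#'
#' @param x A `phoskin_study`.
#' @param ... Unused.
#' @return The per-patient fit tibble (durations, RMSE, R^2, z test).
#' @export
tidy.phoskin_study <- function(x, ...) x$fits

#' Glance at a study's subgroup summaries
#'
#' @param x A `phoskin_study`.
#' @param ... Unused.
#' @return The subgroup R^2 summary tibble.
#' @export
glance.phoskin_study <- function(x, ...) x$summary
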