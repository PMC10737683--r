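#' Modeled dialytic phosphate removal
#'
#' The time integral of the dialyzer elimination flow `s * kd * c1` over the
#' dialysis window, i.e. the cumulative removed mass at the end of dialysis.
#' The integrator accumulates this alongside the compartment masses, so the
#' value equals the total-mass decrease over the dialysis window to machine
#' precision.
#'
#' @param traj A trajectory from [phos_simulate()] covering the dialysis
#'   window.
#' @return Removed phosphate in mmol.
#' @export
modeled_removal <- function(traj) {
  stopifnot(inherits(traj, "phoskin_traj"))
  duration <- attr(traj, "duration_min")
  approx(traj$time_min, traj$removed_mmol, xout = duration)$y
}

#' Measured dialytic phosphate removal from dialysate samples
#'
#' Integrates dialysate phosphate concentration times the mean dialysate flow
#' over the dialysis window. Hourly concentrations are interpolated linearly
#' (trapezoidal rule) and extended as constant from t = 0 to the first sample
#' and from the last sample to the end of dialysis. Immeasurable (missing)
#' samples are dropped with a warning; genuinely low concentrations are kept,
#' since the low-value outlier rule protects the clearance ratio, not the
#' removal integral.
#'
#' @param dialysate Data frame with columns `time_min`, `conc` (mmol/L).
#' @param flow_ml_min Mean dialysate flow rate (mL/min).
#' @param duration_min Dialysis duration (minutes).
#'
#' @return Removed phosphate in mmol.
#' @examples
#' d <- tibble::tibble(time_min = c(60, 120, 180, 240), conc = rep(0.2, 4))
#' measured_removal(d, flow_ml_min = 500, duration_min = 240) # 24 mmol
#' @export
measured_removal <- function(dialysate, flow_ml_min, duration_min) {
  stopifnot(flow_ml_min > 0, duration_min > 0)
  d <- tibble::as_tibble(dialysate)
  stopifnot(all(c("time_min", "conc") %in% names(d)))
  immeasurable <- !is.finite(d$conc)
  if (any(immeasurable)) {
    warn(sprintf("Dropping %d immeasurable dialysate sample(s).", sum(immeasurable)))
    d <- d[!immeasurable, ]
  }
  if (nrow(d) == 0) {
    abort("No valid dialysate samples remain after filtering; cannot compute removal.")
  }
  d <- dplyr::arrange(d, .data$time_min)
  t <- c(0, d$time_min, duration_min)
  conc <- c(d$conc[1], d$conc, d$conc[nrow(d)])
  keep <- !duplicated(t)
  t <- t[keep]; conc <- conc[keep]
  ## trapezoid: mmol/L * L/min integrated over minutes
  auc <- sum(diff(t) * (head(conc, -1) + tail(conc, -1)) / 2)
  auc * flow_ml_min / 1000
}
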