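#' Filter dialysate samples before clearance estimation
#'
#' Drops, in this order, immeasurable samples (missing / non-finite
#' concentration) and low-value outliers below 0.10 mmol/L. Each drop is
#' reported with a warning so that filtering is auditable.
#'
#' @param dialysate Data frame with columns `time_min` and `conc` (mmol/L).
#' @param outlier_threshold Concentrations strictly below this value are
#'   treated as outliers (default 0.10 mmol/L).
#'
#' @return The filtered tibble.
#' @export
filter_dialysate <- function(dialysate, outlier_threshold = 0.10) {
  dialysate <- tibble::as_tibble(dialysate)
  stopifnot(all(c("time_min", "conc") %in% names(dialysate)))
  immeasurable <- !is.finite(dialysate$conc)
  if (any(immeasurable)) {
    warn(sprintf("Dropping %d immeasurable dialysate sample(s) at t = %s min.",
                 sum(immeasurable),
                 paste(dialysate$time_min[immeasurable], collapse = ", ")))
    dialysate <- dialysate[!immeasurable, ]
  }
  low <- dialysate$conc < outlier_threshold
  if (any(low)) {
    warn(sprintf(
      "Dropping %d dialysate outlier(s) below %.2f mmol/L at t = %s min.",
      sum(low), outlier_threshold,
      paste(dialysate$time_min[low], collapse = ", ")))
    dialysate <- dialysate[!low, ]
  }
  dialysate
}

#' Dialyzer phosphate clearance from paired plasma/dialysate samples
#'
#' The clearance is the ratio of summed dialysate to summed plasma phosphate
#' concentrations at the paired sampling times, scaled by the mean dialysate
#' flow rate. Dialysate samples are first passed through [filter_dialysate()];
#' plasma and dialysate samples are then paired by identical nominal time
#' (hourly marks), and unpaired samples on either side are dropped with a
#' warning. Computed in mL/min and returned in L/h.
#'
#' @param plasma Data frame with columns `time_min`, `conc` (mmol/L): plasma
#'   samples, at least at the dialysate sampling times.
#' @param dialysate Data frame with columns `time_min`, `conc` (mmol/L):
#'   hourly dialysate outflow samples.
#' @param flow_ml_min Mean dialysate flow rate (mL/min, > 0).
#'
#' @return Dialyzer clearance kd in L/h, with attribute `n_pairs` giving the
#'   number of sample pairs used.
#' @examples
#' plasma <- tibble::tibble(time_min = c(60, 120), conc = c(1.0, 0.8))
#' dialysate <- tibble::tibble(time_min = c(60, 120), conc = c(0.30, 0.24))
#' dialyzer_clearance(plasma, dialysate, flow_ml_min = 500) # 9 L/h
#' @export
dialyzer_clearance <- function(plasma, dialysate, flow_ml_min) {
  stopifnot(is.numeric(flow_ml_min), length(flow_ml_min) == 1, flow_ml_min > 0)
  plasma <- tibble::as_tibble(plasma)
  stopifnot(all(c("time_min", "conc") %in% names(plasma)))
  dialysate <- filter_dialysate(dialysate)

  paired <- dplyr::inner_join(
    dplyr::select(dialysate, "time_min", cd = "conc"),
    dplyr::select(plasma, "time_min", cp = "conc"),
    by = "time_min"
  )
  if (nrow(dialysate) > nrow(paired)) {
    warn(sprintf("Dropping %d dialysate sample(s) with no plasma sample at the same time.",
                 nrow(dialysate) - nrow(paired)))
  }
  if (nrow(paired) == 0) {
    abort("No valid plasma/dialysate pairs remain after filtering; cannot estimate clearance.")
  }
  sum_cp <- sum(paired$cp)
  if (sum_cp <= 0) {
    abort("Summed plasma concentration is not positive; cannot estimate clearance.")
  }
  kd_ml_min <- sum(paired$cd) / sum_cp * flow_ml_min
  kd <- kd_ml_min * MIN_PER_H / 1000 # mL/min -> L/h
  attr(kd, "n_pairs") <- nrow(paired)
  kd
}
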