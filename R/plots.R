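#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted or evaluated treatment
#'
#' Measured plasma phosphate (points) against the modeled plasma
#' concentration (line), with the cumulative modeled phosphate removal on a
#' secondary axis and, when a postdialytic window is present, a dashed line
#' marking the end of dialysis.
#'
#' @param object A `phoskin_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phoskin_fit <- function(object, ...) {
  traj <- object$trajectory
  removed_max <- max(traj$removed_mmol)
  scale <- if (removed_max > 0) max(traj$c1) / removed_max else 1
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$c1, colour = "modeled plasma")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$removed_mmol * .env$scale,
                                    colour = "removed phosphate")) +
    ggplot2::geom_point(
      data = object$measured,
      ggplot2::aes(y = .data$conc, colour = "measured plasma")
    ) +
    ggplot2::scale_y_continuous(
      name = "plasma phosphate (mmol/L)",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "removed (mmol)")
    ) +
    ggplot2::labs(x = "time (min)", colour = NULL) +
    ggplot2::theme_minimal()
  if (object$post_min > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$duration_min,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot every treatment of a study
#'
#' Measured versus modeled plasma phosphate for each patient and treatment.
#'
#' @param object A `phoskin_study`.
#' @param ... Unused.
#' @return A ggplot object faceted by patient and treatment.
#' @export
autoplot.phoskin_study <- function(object, ...) {
  gather <- function(models, id) {
    purrr::imap(models, function(fit, label) {
      list(
        traj = dplyr::mutate(tibble::as_tibble(fit$trajectory),
                             patient_id = id, treatment = toupper(label)),
        meas = dplyr::mutate(fit$measured, patient_id = id,
                             treatment = toupper(label))
      )
    })
  }
  parts <- purrr::flatten(purrr::imap(object$patient_fits, gather))
  trajs <- dplyr::bind_rows(purrr::map(parts, "traj"))
  meas <- dplyr::bind_rows(purrr::map(parts, "meas"))
  ggplot2::ggplot(trajs, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$c1), colour = "steelblue") +
    ggplot2::geom_point(data = meas, ggplot2::aes(y = .data$conc),
                        size = 0.8) +
    ggplot2::facet_grid(patient_id ~ treatment, scales = "free") +
    ggplot2::labs(x = "time (min)", y = "plasma phosphate (mmol/L)") +
    ggplot2::theme_minimal()
}

#' Per-patient RMSE bar chart for the two treatments
#'
#' @param study A `phoskin_study`.
#' @return A ggplot object.
#' @export
plot_rmse <- function(study) {
  long <- tidyr::pivot_longer(
    dplyr::select(study$fits, "patient_id", "rmse_hd1", "rmse_hd2"),
    cols = -"patient_id", names_to = "treatment", names_prefix = "rmse_",
    values_to = "rmse"
  )
  long$treatment <- toupper(long$treatment)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$patient_id),
                                     y = .data$rmse, fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "patient", y = "RMSE (mmol/L)", fill = NULL) +
    ggplot2::theme_minimal()
}
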