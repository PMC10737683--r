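#' Read a sample table
#'
#' Reads the canonical comma-separated sample layout (`patient_id`,
#' `treatment`, `kind`, `time_min`, `conc`; header row, UTF-8). Malformed or
#' negative concentrations are rejected with the offending row number
#' (1-based, excluding the header).
#'
#' @param path Path to a CSV file.
#' @return A tibble in the canonical sample layout.
#' @export
read_samples <- function(path) {
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      treatment = readr::col_character(),
      kind = readr::col_character(),
      time_min = readr::col_double(),
      conc = readr::col_double()
    )
  ))
  required <- c("patient_id", "treatment", "kind", "time_min", "conc")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("Sample file is missing column(s): ", paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    # problems() counts the header line; report data rows
    abort(sprintf("Malformed value(s) in %s at row(s): %s",
                  path, paste(unique(probs$row - 1), collapse = ", ")))
  }
  bad_time <- which(!is.finite(raw$time_min) | raw$time_min < 0)
  if (length(bad_time)) {
    abort(sprintf("Invalid time(s) in %s at row(s): %s", path,
                  paste(bad_time, collapse = ", ")))
  }
  bad_conc <- which(!is.finite(raw$conc) | raw$conc < 0)
  if (length(bad_conc)) {
    abort(sprintf("Negative or missing concentration(s) in %s at row(s): %s",
                  path, paste(bad_conc, collapse = ", ")))
  }
  bad_kind <- which(!raw$kind %in% c("plasma", "dialysate"))
  if (length(bad_kind)) {
    abort(sprintf("Unknown sample kind in %s at row(s): %s", path,
                  paste(bad_kind, collapse = ", ")))
  }
  raw[required]
}

#' Write a sample table
#'
#' Inverse of [read_samples()]: `read_samples(write_samples(x, path))`
#' returns `x` on canonical form.
#'
#' @param samples A sample tibble in the canonical layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- tibble::as_tibble(samples)
  samples$patient_id <- as.character(samples$patient_id)
  readr::write_csv(
    samples[, c("patient_id", "treatment", "kind", "time_min", "conc")], path)
  invisible(path)
}

#' Write a study report to delimited files
#'
#' Writes the study's four result tables (`params.csv`, `fits.csv`,
#' `removal.csv`, `summary.csv`) into a directory.
#'
#' @param study A `phoskin_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(study, dir) {
  stopifnot(inherits(study, "phoskin_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    params = file.path(dir, "params.csv"),
    fits = file.path(dir, "fits.csv"),
    removal = file.path(dir, "removal.csv"),
    summary = file.path(dir, "summary.csv")
  )
  readr::write_csv(study$params, paths[["params"]])
  readr::write_csv(study$fits, paths[["fits"]])
  readr::write_csv(study$removal, paths[["removal"]])
  readr::write_csv(study$summary, paths[["summary"]])
  invisible(paths)
}
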