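#' Watson total body water from anthropometrics
#'
#' Estimates total body water (TBW, litres) with the Watson regression
#' equations: for males `2.447 - 0.09516*age + 0.1074*height + 0.3362*weight`,
#' for females `-2.097 + 0.1069*height + 0.2466*weight` (no age term).
#' Predialytic body weight is used; ultrafiltration is ignored.
#'
#' @param sex Character vector, `"male"` or `"female"` (case-insensitive).
#' @param age Age in years (> 0). Enters the male equation only.
#' @param height_cm Height in centimetres (> 0).
#' @param weight_kg Predialytic body weight in kilograms (> 0).
#'
#' @return Numeric vector of TBW in litres.
#' @examples
#' watson_tbw("male", age = 70, height_cm = 170, weight_kg = 80)
#' watson_tbw("female", age = 65, height_cm = 160, weight_kg = 60)
#' @export
watson_tbw <- function(sex, age, height_cm, weight_kg) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  stopifnot(all(age > 0), all(height_cm > 0), all(weight_kg > 0))
  tbw <- ifelse(
    sex == "male",
    2.447 - 0.09516 * age + 0.1074 * height_cm + 0.3362 * weight_kg,
    -2.097 + 0.1069 * height_cm + 0.2466 * weight_kg
  )
  if (any(!is.finite(tbw)) || any(tbw <= 0)) {
    abort("Watson TBW is non-positive; check the anthropometric inputs.")
  }
  tbw
}

#' Split total body water into the three compartment volumes
#'
#' Plasma (`v1`) is 1/4 of extracellular fluid, which is itself 1/3 of TBW;
#' the remaining extracellular fluid (`v2`) is 3/4 of ECF; intracellular
#' fluid (`v3`) is 2/3 of TBW. The three volumes always sum to TBW and stand
#' in the fixed ratio 1:3:8. Volumes are held constant over a treatment
#' (ultrafiltration volume loss is ignored).
#'
#' @param tbw Total body water in litres (> 0), e.g. from [watson_tbw()].
#'
#' @return A tibble with columns `v1`, `v2`, `v3` (litres), one row per
#'   element of `tbw`.
#' @examples
#' split_volumes(33.855)
#' @export
split_volumes <- function(tbw) {
  stopifnot(is.numeric(tbw), all(is.finite(tbw)), all(tbw > 0))
  tibble::tibble(
    v1 = tbw * (1 / 3) * (1 / 4),
    v2 = tbw * (1 / 3) * (3 / 4),
    v3 = tbw * (2 / 3)
  )
}

#' Add compartment volumes to a patient table
#'
#' Convenience wrapper applying [watson_tbw()] and [split_volumes()] to a
#' patient table with columns `sex`, `age`, `height_cm`, `weight_kg`.
#'
#' @param patients Data frame with columns `sex`, `age`, `height_cm`,
#'   `weight_kg`; other columns are carried through.
#'
#' @return The input as a tibble with columns `tbw`, `v1`, `v2`, `v3` added.
#' @export
parameterize_patients <- function(patients) {
  required <- c("sex", "age", "height_cm", "weight_kg")
  missing <- setdiff(required, names(patients))
  if (length(missing)) {
    abort(paste0("`patients` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  patients <- tibble::as_tibble(patients)
  patients$tbw <- watson_tbw(patients$sex, patients$age,
                             patients$height_cm, patients$weight_kg)
  dplyr::bind_cols(patients, split_volumes(patients$tbw))
}
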