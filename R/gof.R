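#' Squared Pearson correlation between measured and modeled series
#'
#' Goodness of fit as the square of the Pearson product-moment correlation
#' coefficient between measured and modeled plasma phosphate at the measured
#' sample times.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), typically measured and
#'   modeled concentrations. Both must have nonzero variance.
#'
#' @return A one-row tibble with columns `r`, `r_squared`, `n`.
#' @examples
#' pearson_r2(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (length(x) < 3) abort("At least 3 paired values are required.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined: one of the series has zero variance.")
  }
  r <- cor(x, y)
  tibble::tibble(r = r, r_squared = r^2, n = length(x))
}

#' Fisher r-to-z comparison of two correlations
#'
#' Tests whether two Pearson correlations (e.g. the model's fit to two
#' treatments a week apart) differ, via Fisher's r-to-z transformation:
#' `z_i = atanh(r_i)`, `z_observed = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`.
#' The difference is called significant when `|z_observed| > 1.96` (two-sided,
#' alpha = 0.05). No multiple-testing correction is applied.
#'
#' @param r1,r2 Correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 Sample counts behind each correlation (> 3).
#'
#' @return A one-row tibble with columns `z1`, `z2`, `z_observed`,
#'   `significant`, `n1`, `n2`.
#' @examples
#' fisher_z_compare(r1 = sqrt(0.852), n1 = 12, r2 = sqrt(0.990), n2 = 12)
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1)
  if (n1 <= 3 || n2 <= 3) abort("Fisher z comparison requires n1 > 3 and n2 > 3.")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  z_obs <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(
    z1 = z1, z2 = z2, z_observed = z_obs,
    significant = abs(z_obs) > 1.96, n1 = n1, n2 = n2
  )
}

#' Median and inclusive quartiles
#'
#' Quartiles by the inclusive convention (linear interpolation between order
#' statistics with the extremes included), i.e. the spreadsheet QUARTILE.INC
#' behaviour, which is `stats::quantile()` type 7.
#'
#' @param values Numeric vector (n >= 1, no missing values).
#'
#' @return A one-row tibble with columns `q1`, `median`, `q3`.
#' @examples
#' inclusive_quartiles(c(1, 2, 3, 4))
#' @export
inclusive_quartiles <- function(values) {
  if (length(values) == 0) abort("`values` must contain at least one value.")
  stopifnot(is.numeric(values), !anyNA(values))
  q <- quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(q1 = q[1], median = q[2], q3 = q[3])
}
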