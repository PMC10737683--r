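#' Instantaneous compartment flows
#'
#' The three phosphate flows of the model, in mmol/h: `f1 = s * kd * c1`
#' (elimination through the dialyzer, active only while dialysis runs),
#' `f2 = k1 * (c2 - c1)` and `f3 = k2 * (c3 - c2)` (diffusive exchange driven
#' by the concentration gradients between adjacent compartments). The mass
#' balance is `dm1/dt = f2 - f1`, `dm2/dt = f3 - f2`, `dm3/dt = -f3`.
#'
#' @param c1,c2,c3 Compartment concentrations (mmol/L): plasma, remaining
#'   extracellular fluid, intracellular fluid.
#' @param k1,k2 Mass transfer coefficients (L/h, >= 0).
#' @param kd Dialyzer clearance (L/h, >= 0).
#' @param s Dialysis status, 0 or 1.
#'
#' @return A tibble with columns `f1`, `f2`, `f3` (mmol/h).
#' @examples
#' phos_flows(c1 = 1, c2 = 1.2, c3 = 1.3, k1 = 10, k2 = 5, kd = 9, s = 1)
#' @export
phos_flows <- function(c1, c2, c3, k1, k2, kd, s) {
  vals <- c(c1, c2, c3, k1, k2, kd)
  if (!all(is.finite(vals))) abort("Non-finite state or parameters in `phos_flows()`.")
  stopifnot(all(s %in% c(0, 1)), all(c(k1, k2, kd) >= 0))
  tibble::tibble(
    f1 = s * kd * c1,
    f2 = k1 * (c2 - c1),
    f3 = k2 * (c3 - c2)
  )
}

## Per-minute rate matrix over (m1, m2, m3, removed). Column sums are zero,
## so every one-step transition built from it conserves total mass exactly.
rate_matrix <- function(vols, k1, k2, kd, s) {
  v1 <- vols$v1; v2 <- vols$v2; v3 <- vols$v3
  A <- matrix(0, 4, 4)
  A[1, 1] <- -(k1 + s * kd) / v1
  A[1, 2] <- k1 / v2
  A[2, 1] <- k1 / v1
  A[2, 2] <- -(k1 + k2) / v2
  A[2, 3] <- k2 / v3
  A[3, 2] <- k2 / v2
  A[3, 3] <- -k2 / v3
  A[4, 1] <- s * kd / v1
  A / MIN_PER_H
}

## One RK4 step of the linear system dm/dt = A m is m <- T m with
## T = I + hA + (hA)^2/2 + (hA)^3/6 + (hA)^4/24.
rk4_transition <- function(A, h) {
  hA <- h * A
  T1 <- diag(4) + hA
  hA2 <- hA %*% hA
  T1 + hA2 / 2 + (hA2 %*% hA) / 6 + (hA2 %*% hA2) / 24
}

## Cheap upper bound on the spectral radius of A (per minute): twice the
## largest diagonal decay rate bounds every Gershgorin column disc.
rate_bound <- function(vols, k1, k2, kd) {
  2 * max((k1 + kd) / vols$v1, (k1 + k2) / vols$v2, k2 / vols$v3) / MIN_PER_H
}

#' Largest stable integration step for a parameter set
#'
#' Returns the largest submultiple of `step` that keeps the fixed-step RK4
#' integrator comfortably inside its stability interval for these
#' coefficients (relevant for the very large transfer coefficients the
#' near-flat RMSE regime can produce).
#'
#' @param vols Compartment volumes (`v1`, `v2`, `v3`, litres).
#' @param k1,k2,kd Coefficients in L/h.
#' @param step Base step in minutes.
#' @return A step in minutes of the form `step / n`, `n` integer.
#' @export
stable_step <- function(vols, k1, k2, kd, step = 1) {
  step / max(1L, ceiling(step * rate_bound(vols, k1, k2, kd) / 2.5))
}

check_vols <- function(vols) {
  vols <- as.list(vols)
  stopifnot(all(c("v1", "v2", "v3") %in% names(vols)))
  v <- unlist(vols[c("v1", "v2", "v3")])
  if (!all(is.finite(v)) || !all(v > 0)) abort("Compartment volumes must be finite and positive.")
  vols
}

## Internal integrator: RK4 at fixed step over the two dialysis-status legs,
## returning the mass matrix (rows = grid times) and the grid.
rk4_masses <- function(vols, k1, k2, kd, c0, duration_min, post_min, step_min) {
  if (duration_min %% step_min > 1e-9 || post_min %% step_min > 1e-9) {
    abort("`step_min` must divide both the dialysis duration and the postdialytic window.")
  }
  A_on <- rate_matrix(vols, k1, k2, kd, s = 1)
  A_off <- rate_matrix(vols, k1, k2, kd, s = 0)
  ## Explicit failure when the supplied step is outside the RK4 stability
  ## interval (|h*lambda| < ~2.78 on the negative real axis).
  if (step_min * rate_bound(vols, k1, k2, kd) > 2.78) {
    lam <- max(abs(eigen(A_on, only.values = TRUE)$values),
               abs(eigen(A_off, only.values = TRUE)$values))
    if (step_min * lam > 2.78) {
      abort(sprintf(paste0("Integration step %.3g min is too coarse for these ",
                           "coefficients (|h*lambda| = %.2f > 2.78): reduce `step_min`."),
                    step_min, step_min * lam),
            class = "phoskin_error_step")
    }
  }
  n_on <- round(duration_min / step_min)
  n_off <- round(post_min / step_min)
  T_on <- rk4_transition(A_on, step_min)
  T_off <- rk4_transition(A_off, step_min)
  m <- matrix(NA_real_, n_on + n_off + 1, 4)
  m[1, ] <- c(c0 * vols$v1, c0 * vols$v2, c0 * vols$v3, 0)
  state <- m[1, ]
  if (n_on > 0) {
    for (i in seq_len(n_on)) {
      state <- drop(T_on %*% state)
      m[i + 1, ] <- state
    }
  }
  if (n_off > 0) {
    for (i in seq_len(n_off)) {
      state <- drop(T_off %*% state)
      m[n_on + i + 1, ] <- state
    }
  }
  if (!all(is.finite(m))) {
    abort("Integration diverged: non-finite state encountered. Reduce `step_min`.",
          class = "phoskin_error_step")
  }
  list(time_min = seq(0, duration_min + post_min, by = step_min), m = m)
}

#' Simulate the three-compartment model over a treatment
#'
#' Integrates the phosphate mass balance with a fixed-step 4th-order
#' Runge-Kutta scheme over the dialysis window (dialyzer active) and an
#' optional postdialytic observation window (dialyzer off, compartments
#' re-equilibrate, producing the plasma rebound). All three compartments
#' start at the measured predialytic plasma concentration, i.e. in
#' inter-compartment equilibrium. Volumes are constant in time.
#'
#' @param vols Compartment volumes: a list or one-row data frame with `v1`,
#'   `v2`, `v3` (litres), e.g. from [split_volumes()].
#' @param k1,k2 Mass transfer coefficients (L/h, >= 0).
#' @param kd Dialyzer clearance (L/h, >= 0).
#' @param c0 Predialytic plasma phosphate concentration (mmol/L, > 0).
#' @param duration_min Dialysis duration in minutes (> 0).
#' @param post_min Postdialytic window in minutes (>= 0).
#' @param step_min Integration step in minutes; must divide both windows.
#'   An error is raised (never silent garbage) if the step is too coarse for
#'   numerical stability at the supplied coefficients.
#'
#' @return A tibble of class `phoskin_traj` with columns `time_min`, `c1`,
#'   `c2`, `c3` (mmol/L), `removed_mmol` (cumulative phosphate removed), and
#'   attributes `vols`, `params`, `duration_min`, `post_min`.
#' @examples
#' vols <- split_volumes(40)
#' phos_simulate(vols, k1 = 20, k2 = 10, kd = 9, c0 = 1.4, duration_min = 240)
#' @export
phos_simulate <- function(vols, k1, k2, kd, c0, duration_min, post_min = 0,
                          step_min = 1) {
  vols <- check_vols(vols)
  stopifnot(is.finite(c0), c0 > 0, duration_min > 0, post_min >= 0,
            step_min > 0, k1 >= 0, k2 >= 0, kd >= 0)
  sol <- rk4_masses(vols, k1, k2, kd, c0, duration_min, post_min, step_min)
  out <- tibble::tibble(
    time_min = sol$time_min,
    c1 = sol$m[, 1] / vols$v1,
    c2 = sol$m[, 2] / vols$v2,
    c3 = sol$m[, 3] / vols$v3,
    removed_mmol = sol$m[, 4]
  )
  class(out) <- c("phoskin_traj", class(out))
  attr(out, "vols") <- vols[c("v1", "v2", "v3")]
  attr(out, "params") <- list(k1 = k1, k2 = k2, kd = kd)
  attr(out, "duration_min") <- duration_min
  attr(out, "post_min") <- post_min
  out
}

## Fast path used inside the fitting objective: same RK4 stepping, but only
## plasma concentration at the requested times, no tibble construction.
c1_at_times <- function(vols, k1, k2, kd, c0, duration_min, post_min,
                        step_min, times) {
  sol <- rk4_masses(vols, k1, k2, kd, c0, duration_min, post_min, step_min)
  c1 <- sol$m[, 1] / vols$v1
  approx(sol$time_min, c1, xout = times)$y
}

#' Sample plasma concentration from a trajectory
#'
#' Returns the plasma (compartment 1) concentration at the requested times by
#' linear interpolation between grid points.
#'
#' @param traj A trajectory from [phos_simulate()].
#' @param times Times in minutes, each within the trajectory span.
#'
#' @return Numeric vector of plasma concentrations (mmol/L).
#' @export
sample_traj <- function(traj, times) {
  span <- range(traj$time_min)
  bad <- times < span[1] | times > span[2]
  if (any(bad)) {
    abort(sprintf("Requested time(s) outside the trajectory span [%g, %g] min: %s",
                  span[1], span[2], paste(times[bad], collapse = ", ")))
  }
  approx(traj$time_min, traj$c1, xout = times)$y
}

#' @export
print.phoskin_traj <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<phoskin trajectory: %g min dialysis + %g min post, k1 = %.3g, k2 = %.3g, kd = %.3g L/h>\n",
    attr(x, "duration_min"), attr(x, "post_min"), p$k1, p$k2, p$kd))
  NextMethod()
}
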