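# Independent oracles, written directly from the model equations and the
# textbook definitions; deliberately share no code with the package.

# Forward-Euler integration of the mass balance, flows written out in full.
euler_simulate <- function(v1, v2, v3, k1, k2, kd, c0, duration_min,
                           post_min = 0, step_min = 0.01) {
  times <- seq(0, duration_min + post_min, by = step_min)
  m1 <- c0 * v1; m2 <- c0 * v2; m3 <- c0 * v3; removed <- 0
  out_c1 <- numeric(length(times))
  out_total <- numeric(length(times))
  out_c1[1] <- m1 / v1
  out_total[1] <- m1 + m2 + m3 + removed
  for (i in seq_along(times)[-1]) {
    t_prev <- times[i - 1]
    s <- if (t_prev < duration_min) 1 else 0
    c1 <- m1 / v1; c2 <- m2 / v2; c3 <- m3 / v3
    f1 <- s * kd * c1          # mmol/h
    f2 <- k1 * (c2 - c1)
    f3 <- k2 * (c3 - c2)
    m1 <- m1 + step_min * (f2 - f1) / 60
    m2 <- m2 + step_min * (f3 - f2) / 60
    m3 <- m3 + step_min * (-f3) / 60
    removed <- removed + step_min * f1 / 60
    out_c1[i] <- m1 / v1
    out_total[i] <- m1 + m2 + m3 + removed
  }
  data.frame(time_min = times, c1 = out_c1, total = out_total,
             removed = removed)
}

euler_c1_at <- function(sim, at) sim$c1[match(round(at, 6), round(sim$time_min, 6))]

# Inclusive (endpoints-included) quantile: rank h = (n-1)p + 1, linear
# interpolation between the flanking order statistics.
brute_inclusive_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Pearson correlation from the sum-of-products definition.
brute_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Closed-form plasma concentration when both transfer coefficients are zero:
# single-pool exponential washout at rate kd/v1 (per hour).
closed_form_c1 <- function(c0, kd, v1, t_min) c0 * exp(-kd * t_min / 60 / v1)
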