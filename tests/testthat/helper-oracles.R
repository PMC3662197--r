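# Independent oracles used across the suite.

# Numerical integration of the two-state series system
#   E0' = -k1 E0,  E1' = k1 E0 - k2 E1,  alpha = E0 + alpha1 E1
# as a cross-check of the closed-form residual-activity curve.
ode_alpha <- function(times, alpha1, k1, k2) {
  grid <- sort(unique(c(0, times)))
  deriv <- function(t, y, p) list(c(-k1 * y[1], k1 * y[1] - k2 * y[2]))
  out <- deSolve::lsoda(c(E0 = 1, E1 = 0), grid, deriv, NULL,
                        rtol = 1e-12, atol = 1e-14)
  a <- out[, "E0"] + alpha1 * out[, "E1"]
  a[match(times, out[, "time"])]
}

# plain bisection root-finder, independent of stats::uniroot
bisect <- function(f, lo, hi, tol = 1e-9) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# closed-form OLS slope/intercept, independent of stats::lm
ols_oracle <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - sl * mean(x), slope = sl)
}

# the nine strains singled out for follow-up in the packaged screen
SELECTED_NINE <- c("SP14", "SP22", "SP29", "SP73", "SP75", "SP76",
                   "SP79", "SP83", "SP93")

sp14_70_truth <- function() ground_truth(0.647, 2.24e-2, 1.82e-4, "SP14")
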