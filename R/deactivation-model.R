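#' Residual activity under two-step series deactivation
#'
#' Closed-form residual activity \eqn{\alpha(t)} of an enzyme deactivating
#' through a partially active intermediate,
#' \deqn{E_0 \xrightarrow{k_1} E_1 \xrightarrow{k_2} E_2,}
#' where the intermediate retains a fraction \eqn{\alpha_1 = E_1/E_0} of the
#' native specific activity and the final state is fully inactive.
#' Integrating the series first-order system gives
#' \deqn{\alpha(t) = \left[1 + \frac{\alpha_1 k_1}{k_2 - k_1}\right] e^{-k_1 t}
#'   - \frac{\alpha_1 k_1}{k_2 - k_1} e^{-k_2 t}.}
#' At the removable singularity \eqn{k_1 = k_2} the analytic limit
#' \eqn{\alpha(t) = (1 + \alpha_1 k_1 t)\,e^{-k_1 t}} is used; the branch
#' switches when \eqn{|k_2 - k_1| < 10^{-8} k_1}.
#'
#' @param t time in minutes, non-negative (vectorised).
#' @param alpha1 specific-activity ratio of the intermediate, in \[0, 1\].
#' @param k1,k2 first-order deactivation constants in 1/min, strictly positive.
#' @return numeric vector of residual activity fractions; `alpha(0)` is exactly 1.
#' @examples
#' residual_activity(60, alpha1 = 0.647, k1 = 2.24e-2, k2 = 1.82e-4)
#' @seealso [fit_two_step()], [half_life()]
#' @export
residual_activity <- function(t, alpha1, k1, k2) {
  stopifnot(is.numeric(t), is.numeric(alpha1), is.numeric(k1), is.numeric(k2))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  if (alpha1 < 0 || alpha1 > 1) stop("alpha1 must lie in [0, 1]", call. = FALSE)
  if (k1 <= 0 || k2 <= 0) stop("k1 and k2 must be positive", call. = FALSE)
  if (abs(k2 - k1) < 1e-8 * k1) {
    # analytic limit of the biexponential as k2 -> k1
    return((1 + alpha1 * k1 * t) * exp(-k1 * t))
  }
  cc <- alpha1 * k1 / (k2 - k1)
  # grouped so the two exponentials cancel exactly at t = 0: alpha(0) = 1
  e1 <- exp(-k1 * t)
  e1 + cc * (e1 - exp(-k2 * t))
}

#' Half-life of a two-step deactivating enzyme
#'
#' Time at which the residual activity first reaches 0.5. The curve is
#' monotone decreasing from 1 to 0 for `alpha1` in \[0, 1\], so the root is
#' unique; it is found by bracketed root-finding (`uniroot`, tolerance 1e-9
#' minutes after bracket expansion).
#'
#' @param params a [deact_params] object, or any list with elements
#'   `alpha1`, `k1`, `k2`.
#' @return half-life in minutes.
#' @examples
#' half_life(list(alpha1 = 0, k1 = log(2) / 10, k2 = 1))  # 10 min
#' @export
half_life <- function(params) {
  a1 <- params$alpha1; k1 <- params$k1; k2 <- params$k2
  f <- function(t) residual_activity(t, a1, k1, k2) - 0.5
  upper <- 1 / min(k1, k2)  # slowest time scale; expand until bracketed
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-9)$root
}
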