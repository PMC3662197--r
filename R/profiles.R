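# pH / temperature activity-profile summaries. Profiles are evaluated on the
# measurement grid only: optima and retained fractions are never interpolated
# between assayed pH or temperature values.

#' Activity profile over pH or temperature
#'
#' @param x grid values (pH units or degrees Celsius), strictly increasing.
#' @param activity measured activities (nkat/mL or relative %), >= 0.
#' @param sd optional standard deviations (triplicate determinations).
#' @param enzyme_id optional label.
#' @param axis which variable the profile scans.
#' @return data.frame of class `activity_profile` with attributes `axis`,
#'   `enzyme_id` and `normalized`.
#' @export
activity_profile <- function(x, activity, sd = NULL,
                             enzyme_id = NA_character_,
                             axis = c("pH", "temperature_C")) {
  axis <- match.arg(axis)
  if (length(x) == 0) stop("empty profile", call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  if (any(!is.finite(activity)) || any(activity < 0))
    stop("activities must be finite and >= 0", call. = FALSE)
  df <- data.frame(x = as.numeric(x), activity = as.numeric(activity),
                   sd = if (is.null(sd)) NA_real_ else as.numeric(sd))
  structure(df, axis = axis, enzyme_id = enzyme_id, normalized = FALSE,
            class = c("activity_profile", "data.frame"))
}

#' Normalise a profile to percent of its maximum
#'
#' @param p an [activity_profile()] with a positive maximum.
#' @return the profile rescaled so its maximum is 100 (sd rescaled with it);
#'   idempotent.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "activity_profile"))
  mx <- max(p$activity)
  if (mx <= 0) stop("cannot normalize an all-zero profile", call. = FALSE)
  q <- p
  q$activity <- 100 * p$activity / mx
  q$sd <- 100 * p$sd / mx
  attr(q, "normalized") <- TRUE
  q
}

#' Locate the activity optimum of a profile
#'
#' @param p an [activity_profile()].
#' @return the grid value of maximal activity. Ties are broken toward the
#'   lower grid value and flagged via attribute `tie`; an optimum sitting on
#'   either end of a multi-point grid is flagged via attribute `boundary`
#'   (the true optimum may lie outside the assayed range).
#' @export
find_optimum <- function(p) {
  stopifnot(inherits(p, "activity_profile"))
  mx <- max(p$activity)
  hits <- which(p$activity == mx)
  i <- hits[1]
  structure(p$x[i],
            tie = length(hits) > 1,
            boundary = nrow(p) > 1 && (i == 1 || i == nrow(p)))
}

#' Activity retained at a grid point
#'
#' @param p an [activity_profile()].
#' @param x a value on the profile's measurement grid (no interpolation).
#' @return percent of the maximal activity retained at `x`.
#' @examples
#' p <- activity_profile(c(8, 9, 10), c(80, 100, 31), axis = "pH")
#' fraction_retained(p, 10)  # 31
#' @export
fraction_retained <- function(p, x) {
  stopifnot(inherits(p, "activity_profile"))
  i <- which(abs(p$x - x) <= 1e-9)
  if (length(i) != 1)
    stop("x = ", x, " is not on the measurement grid (no interpolation)",
         call. = FALSE)
  100 * p$activity[i] / max(p$activity)
}

#' Simulate a unimodal activity profile
#'
#' Gaussian-bump profile peaked at `optimum` with optional triplicate
#' measurement noise; used to exercise the profile summaries.
#'
#' @param grid measurement grid (strictly increasing).
#' @param optimum peak location (need not be on the grid).
#' @param width bump width (same units as the grid).
#' @param peak_activity activity at the peak, nkat/mL.
#' @param noise_sd Gaussian noise sd on the activity scale.
#' @param seed integer seed.
#' @inheritParams activity_profile
#' @return an [activity_profile()].
#' @export
simulate_profile <- function(grid, optimum, width, peak_activity = 1,
                             noise_sd = 0, seed = 1,
                             axis = c("pH", "temperature_C"),
                             enzyme_id = NA_character_) {
  mu <- peak_activity * exp(-((grid - optimum) / width)^2 / 2)
  act <- with_preserved_seed(seed,
    pmax(mu + stats::rnorm(length(grid), sd = noise_sd), 0))
  activity_profile(grid, act, sd = rep(noise_sd, length(grid)),
                   enzyme_id = enzyme_id, axis = match.arg(axis))
}
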