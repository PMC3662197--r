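# Arrhenius analysis of deactivation rate constants.

#' @rdname fit_arrhenius
#' @format NULL
#' @export
GAS_CONSTANT <- 8.314  # J / (mol K)

#' Arrhenius regression of rate constants on temperature
#'
#' Ordinary least-squares regression of \eqn{\ln k} on \eqn{1/T} (T in kelvin,
#' `temp_c + 273.15`); the activation energy is `-slope * R`, reported in
#' kJ/mol with R = 8.314 J/(mol K). An optional weighted mode
#' (weights \eqn{1/\mathrm{SE}(k)^2}, mapped to the log scale by the delta
#' method) is available but unweighted point-estimate regression is the
#' default.
#'
#' @param temps_c temperatures in degrees Celsius (>= 2 distinct values).
#' @param ks rate constants in 1/min, strictly positive.
#' @param weights optional standard errors of `ks`; when supplied the
#'   regression is weighted by `(k/se)^2`.
#' @return list of class `arrhenius_fit` with `ea` (kJ/mol), `ln_a`
#'   (intercept, ln of 1/min), `r2`, `n_temps` and `degenerate` (TRUE when all
#'   rates are equal, in which case `ea = 0` and `r2` is reported as 0).
#' @examples
#' fit_arrhenius(c(70, 80), c(0.01, 0.02))  # Ea ~ 69.8 kJ/mol
#' @export
fit_arrhenius <- function(temps_c, ks, weights = NULL) {
  temps_c <- as.numeric(temps_c); ks <- as.numeric(ks)
  if (length(temps_c) != length(ks))
    stop("temps_c and ks must have the same length", call. = FALSE)
  if (any(!is.finite(ks)) || any(ks <= 0))
    stop("rate constants must be positive and finite", call. = FALSE)
  tk <- temps_c + 273.15
  if (any(tk <= 0)) stop("temperatures must exceed 0 K", call. = FALSE)
  if (length(unique(tk)) < 2)
    stop("need at least 2 distinct temperatures", call. = FALSE)

  x <- 1 / tk
  y <- log(ks)
  fit <- if (is.null(weights)) {
    stats::lm(y ~ x)
  } else {
    # delta method: Var(ln k) = (se/k)^2, so weight by (k/se)^2
    stats::lm(y ~ x, weights = (ks / weights)^2)
  }
  co <- stats::coef(fit)
  degenerate <- stats::var(y) == 0
  r2 <- if (degenerate) 0 else 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(ea = -co[[2]] * GAS_CONSTANT / 1000, ln_a = co[[1]], r2 = r2,
         n_temps = length(unique(tk)), degenerate = degenerate),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.2f kJ/mol, ln A = %.3f, R2 = %.4f (%d temperatures)%s\n",
              x$ea, x$ln_a, x$r2, x$n_temps,
              if (isTRUE(x$degenerate)) " [degenerate: constant k]" else ""))
  invisible(x)
}

#' Predict a rate constant from an Arrhenius fit
#'
#' @param fit an `arrhenius_fit`.
#' @param temp_c temperature in degrees Celsius (vectorised).
#' @return predicted rate constant(s) in 1/min,
#'   \eqn{\exp(\ln A - E_a/(R T))}.
#' @export
predict_k <- function(fit, temp_c) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  exp(fit$ln_a - fit$ea * 1000 / (GAS_CONSTANT * (temp_c + 273.15)))
}

#' Activation energies for a fitted-parameter table
#'
#' Runs [fit_arrhenius()] per enzyme on the `k1` and/or `k2` columns of a
#' parameter table in the [deact_params_table()] dialect.
#'
#' @param params data.frame with columns `enzyme`, `temperature_c`, `k1`, `k2`.
#' @param rate which rate constant(s) to analyse.
#' @return data.frame with columns `enzyme`, `rate`, `ea_kj_mol`, `ln_a`, `r2`.
#' @export
activation_energy_table <- function(params, rate = c("k1", "k2")) {
  rate <- match.arg(rate, several.ok = TRUE)
  out <- lapply(split(params, params$enzyme), function(d) {
    do.call(rbind, lapply(rate, function(r) {
      f <- fit_arrhenius(d$temperature_c, d[[r]])
      data.frame(enzyme = d$enzyme[1], rate = r, ea_kj_mol = f$ea,
                 ln_a = f$ln_a, r2 = f$r2)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$enzyme, out$rate), ]
}
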