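# Synthetic-data generators emulating the statistical structure of the
# assays: triplicate residual-activity time courses with additive Gaussian
# noise, Arrhenius-consistent rate-constant series, and screening tables with
# prescribed class proportions.

#' Ground-truth deactivation parameters for simulation
#'
#' @param alpha1 specific-activity ratio of the intermediate, in \[0, 1\].
#' @param k1,k2 first-order deactivation constants in 1/min, > 0.
#' @param label optional strain/temperature tag.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(alpha1, k1, k2, label = NA_character_) {
  if (!is.finite(alpha1) || alpha1 < 0 || alpha1 > 1)
    stop("alpha1 must lie in [0, 1]", call. = FALSE)
  if (!is.finite(k1) || k1 <= 0 || !is.finite(k2) || k2 <= 0)
    stop("k1 and k2 must be positive", call. = FALSE)
  structure(list(alpha1 = alpha1, k1 = k1, k2 = k2, label = label),
            class = "ground_truth")
}

#' Simulation configuration
#'
#' Defaults mirror the thermostability experiments the generator emulates:
#' triplicate determinations on a 0-60 min sampling grid (5-min steps, the
#' 1 h incubation window) with additive Gaussian measurement noise of
#' standard deviation 0.02 activity-fraction units. Truncation of negative
#' noisy observations at zero is available but off by default so that
#' least-squares fitting of the simulated data stays unbiased.
#'
#' @param seed integer seed; the same configuration and seed always produce
#'   identical data, and the global RNG state is never disturbed.
#' @param n_replicates replicates per time point (default 3).
#' @param time_grid strictly increasing sampling times in minutes, starting
#'   at 0.
#' @param noise_sd Gaussian noise standard deviation (activity-fraction
#'   units, >= 0).
#' @param truncate_at_zero clamp negative observations to 0.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n_replicates = 3, time_grid = seq(0, 60, by = 5),
                       noise_sd = 0.02, truncate_at_zero = FALSE) {
  if (any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing", call. = FALSE)
  if (time_grid[1] != 0)
    stop("time_grid must start at 0", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("need at least one replicate", call. = FALSE)
  structure(list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
                 time_grid = as.numeric(time_grid), noise_sd = noise_sd,
                 truncate_at_zero = isTRUE(truncate_at_zero)),
            class = "sim_config")
}

#' Simulate a residual-activity time course
#'
#' Evaluates the two-step deactivation curve ([residual_activity()]) at the
#' configured time grid and adds independent Gaussian noise per replicate and
#' time point.
#'
#' @param truth a [ground_truth()].
#' @param config a [sim_config()].
#' @param enzyme_id,temperature optional metadata for the result.
#' @return a [timecourse] carrying the truth and seed in its metadata.
#' @examples
#' tc <- simulate_timecourse(ground_truth(0.647, 2.24e-2, 1.82e-4),
#'                           sim_config(seed = 1))
#' @export
simulate_timecourse <- function(truth, config,
                                enzyme_id = truth$label,
                                temperature = NA_real_) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  tg <- config$time_grid
  mu <- residual_activity(tg, truth$alpha1, truth$k1, truth$k2)
  nrep <- config$n_replicates
  obs <- with_preserved_seed(config$seed, {
    rep(mu, times = nrep) +
      stats::rnorm(length(tg) * nrep, sd = config$noise_sd)
  })
  if (config$truncate_at_zero) obs <- pmax(obs, 0)
  timecourse(time = rep(tg, times = nrep), alpha_obs = obs,
             replicate = rep(seq_len(nrep), each = length(tg)),
             enzyme_id = enzyme_id, temperature = temperature,
             truth = truth, seed = config$seed)
}

#' Simulate an Arrhenius-consistent rate-constant series
#'
#' @param ea activation energy in kJ/mol.
#' @param k_ref rate constant (1/min) at the reference temperature.
#' @param t_ref_k reference temperature in kelvin.
#' @param temps_k temperatures in kelvin at which to evaluate.
#' @return rate constants
#'   \eqn{k(T) = k_{ref} \exp(-E_a/R \cdot (1/T - 1/T_{ref}))}.
#' @examples
#' simulate_arrhenius_series(93.7, 2.24e-2, 343.15, c(343.15, 353.15, 363.15))
#' @export
simulate_arrhenius_series <- function(ea, k_ref, t_ref_k, temps_k) {
  if (k_ref <= 0) stop("k_ref must be positive", call. = FALSE)
  if (any(temps_k <= 0) || t_ref_k <= 0)
    stop("temperatures must exceed 0 K", call. = FALSE)
  k_ref * exp(-ea * 1000 / GAS_CONSTANT * (1 / temps_k - 1 / t_ref_k))
}

#' Phase-spanning sampling design for parameter-recovery experiments
#'
#' Thirteen sampling times placed relative to the two decay time scales of a
#' ground truth: t = 0, six points across the fast phase (multiples 0.2-2.8
#' of \eqn{1/k_1}) and six across the slow phase (multiples 0.25-2.4 of
#' \eqn{1/k_2}). Both deactivation phases must be observed for the three
#' parameters to be identifiable; a grid confined to the fast phase leaves
#' `k2` (and with it `alpha1`, `k1`) essentially unconstrained at realistic
#' noise levels.
#'
#' @param k1,k2 the true rate constants in 1/min.
#' @return sorted vector of sampling times in minutes (13 values when the
#'   phases are well separated; duplicates are merged when they overlap).
#' @export
recovery_design <- function(k1, k2) {
  if (k1 <= 0 || k2 <= 0) stop("rates must be positive", call. = FALSE)
  sort(unique(c(0, c(0.2, 0.5, 0.9, 1.4, 2.0, 2.8) / k1,
                c(0.25, 0.5, 0.8, 1.2, 1.7, 2.4) / k2)))
}

#' Linearised parameter uncertainty of a simulation design
#'
#' Standard errors of (`alpha1`, `k1`, `k2`) implied by the Fisher
#' information of a noisy time-course design at a given ground truth:
#' \eqn{\mathrm{cov} = \sigma^2 (J^T J)^{-1}} with J the model Jacobian over
#' all replicate observations. Used to decide, before simulating anything,
#' which parameters a design can actually determine.
#'
#' @param truth a [ground_truth()].
#' @param config a [sim_config()] (grid, replicates and noise are used).
#' @return named vector `se_alpha1`, `se_k1`, `se_k2` (Inf when the design
#'   information matrix is singular).
#' @export
design_se <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  t <- rep(config$time_grid, times = config$n_replicates)
  J <- .jacobian_natural(truth$alpha1, truth$k1, truth$k2, t)
  se <- tryCatch(sqrt(diag(solve(crossprod(J)) * config$noise_sd^2)),
                 error = function(e) rep(Inf, 3))
  stats::setNames(se, c("se_alpha1", "se_k1", "se_k2"))
}

# class-conditional liquid activities (48 h, 72 h) in nkat/mL
.draw_activities <- function(class) {
  switch(class,
    none = c(NA_real_, NA_real_),
    low = stats::runif(2, 0.01, 0.049),
    significant = {
      m <- 0.06 + stats::rlnorm(1, meanlog = log(0.3), sdlog = 0.8)
      u <- stats::runif(1, 0, 0.5)
      c(m * (1 + u), m * (1 - u))
    })
}

#' Simulate a screening table
#'
#' Draws each strain's liquid class from a multinomial with the requested
#' proportions and generates activities consistent with that class
#' (`none`: both entries non-detected; `low`: detectable but mean <= 0.05
#' nkat/mL; `significant`: mean > 0.05 nkat/mL). Halo scores are drawn
#' independently of the liquid class (with probability `halo_prob` of a
#' positive halo), reproducing the observed discordance between the two
#' screening modes.
#'
#' @param n_strains number of strains (0 gives an empty table).
#' @param class_proportions probabilities of (none, low, significant);
#'   must sum to 1.
#' @param seed integer seed.
#' @param halo_prob marginal probability that a strain produces a halo.
#' @return a [screening_table()].
#' @examples
#' sim <- simulate_screen(101, c(0.26, 0.19, 0.55), seed = 1)
#' summarize_screen(sim)
#' @export
simulate_screen <- function(n_strains, class_proportions, seed,
                            halo_prob = 0.17) {
  if (abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0))
    stop("class_proportions must be a probability vector summing to 1",
         call. = FALSE)
  n_strains <- as.integer(n_strains)
  classes <- c("none", "low", "significant")
  ids <- sprintf("S%03d", seq_len(n_strains))
  if (n_strains == 0)
    return(screening_table(character(), character(), character(),
                           numeric(), numeric()))
  with_preserved_seed(seed, {
    cls <- sample(classes, n_strains, replace = TRUE,
                  prob = class_proportions)
    acts <- t(vapply(cls, .draw_activities, numeric(2)))
    halo <- stats::runif(n_strains) < halo_prob
    # among producers: mostly partial halos, full coverage is rare
    h24 <- ifelse(halo,
                  sample(c("-", "+", "++"), n_strains, replace = TRUE,
                         prob = c(0.55, 0.40, 0.05)), "-")
    h48 <- ifelse(halo,
                  sample(c("+", "++"), n_strains, replace = TRUE,
                         prob = c(0.85, 0.15)), "-")
    screening_table(ids, h24, h48, acts[, 1], acts[, 2])
  })
}
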