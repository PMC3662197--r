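test_that("zero-noise simulation equals the closed-form curve at every point", {
  tr <- sp14_70_truth()
  tc <- simulate_timecourse(tr, sim_config(seed = 1, noise_sd = 0))
  mu <- residual_activity(tc$data$time, tr$alpha1, tr$k1, tr$k2)
  expect_identical(tc$data$alpha_obs, mu)
  expect_equal(tc$data$alpha_obs[tc$data$time == 60][1], 0.736,
               tolerance = 1e-3)
})

test_that("simulation is byte-identical under a fixed seed and leaves the RNG alone", {
  cfg <- sim_config(seed = 99)
  before <- .Random.seed
  a <- simulate_timecourse(sp14_70_truth(), cfg)
  b <- simulate_timecourse(sp14_70_truth(), cfg)
  expect_identical(a$data, b$data)
  expect_identical(.Random.seed, before)
  expect_false(identical(
    a$data, simulate_timecourse(sp14_70_truth(), sim_config(seed = 100))$data))
})

test_that("noise is additive Gaussian per replicate/time point; truncation is opt-in", {
  tr <- ground_truth(0.3, 0.2, 0.15)  # decays near zero quickly
  grid <- seq(0, 200, 10)
  raw <- simulate_timecourse(tr, sim_config(seed = 3, noise_sd = 0.05,
                                            time_grid = grid))
  expect_true(any(raw$data$alpha_obs < 0))
  trunc <- simulate_timecourse(tr, sim_config(seed = 3, noise_sd = 0.05,
                                              time_grid = grid,
                                              truncate_at_zero = TRUE))
  expect_true(all(trunc$data$alpha_obs >= 0))
  expect_identical(pmax(raw$data$alpha_obs, 0), trunc$data$alpha_obs)
  # residuals behave like the configured noise
  mu <- residual_activity(raw$data$time, tr$alpha1, tr$k1, tr$k2)
  expect_lt(abs(sd(raw$data$alpha_obs - mu) - 0.05), 0.02)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(seed = 1, time_grid = c(0, 10, 10)), "increasing")
  expect_error(sim_config(seed = 1, time_grid = c(5, 10)), "start at 0")
  expect_error(sim_config(seed = 1, noise_sd = -0.1), "noise_sd")
  expect_error(ground_truth(1.2, 0.1, 0.01), "alpha1")
})

test_that("the noiseless mean curve is nonincreasing over the grid", {
  set.seed(21)
  for (i in 1:10) {
    tr <- ground_truth(runif(1), 10^runif(1, -3, 0), 10^runif(1, -5, -1))
    tc <- simulate_timecourse(tr, sim_config(seed = i, noise_sd = 0))
    mu <- tc$data$alpha_obs[tc$data$replicate == 1]
    expect_true(all(diff(mu) <= 1e-12))
  }
})

test_that("arrhenius series generator hits its defining identities", {
  temps <- c(343.15, 353.15, 363.15)
  expect_equal(simulate_arrhenius_series(0, 0.02, 343.15, temps),
               rep(0.02, 3))
  # Ea chosen so k doubles between 70C and 80C
  ea2 <- 8.314 * log(2) / (1 / 343.15 - 1 / 353.15) / 1000
  ks <- simulate_arrhenius_series(ea2, 0.01, 343.15, c(343.15, 353.15))
  expect_equal(ks[2] / ks[1], 2, tolerance = 1e-12)
  expect_equal(ea2, 69.83, tolerance = 1e-3)
})

test_that("simulated screens honour the requested class structure", {
  all_none <- simulate_screen(20, c(1, 0, 0), seed = 1)
  expect_true(all(is.na(all_none$olm_48h) & is.na(all_none$olm_72h)))

  all_sig <- simulate_screen(50, c(0, 0, 1), seed = 2)
  expect_identical(summarize_screen(all_sig)$n_significant, 50L)

  expect_identical(nrow(simulate_screen(0, c(0, 0, 1), seed = 3)), 0L)

  # study-sized draw: counts near the configured multinomial expectation
  sim <- simulate_screen(101, c(0.26, 0.19, 0.55), seed = 4)
  sm <- summarize_screen(sim)
  expect_lt(abs(sm$n_none - 26.26), 4 * sqrt(101 * 0.26 * 0.74))
  expect_lt(abs(sm$n_low - 19.19), 4 * sqrt(101 * 0.19 * 0.81))
  expect_lt(abs(sm$n_significant - 55.55), 4 * sqrt(101 * 0.55 * 0.45))
  # determinism
  expect_identical(sim, simulate_screen(101, c(0.26, 0.19, 0.55), seed = 4))
  expect_error(simulate_screen(10, c(0.5, 0.2, 0.2), seed = 1), "sum")
})

test_that("recovery design spans both decay phases and supports identification", {
  g <- recovery_design(2.24e-2, 1.82e-4)
  expect_identical(g[1], 0)
  expect_identical(length(g), 13L)
  expect_true(any(g > 0 & g <= 2 / 2.24e-2))   # fast phase sampled
  expect_gt(max(g), 1 / 1.82e-4)               # slow phase sampled
  se <- design_se(sp14_70_truth(),
                  sim_config(seed = 1, time_grid = g, noise_sd = 0.02))
  expect_equal(se[["se_alpha1"]], 0.0122, tolerance = 0.02)
  expect_equal(se[["se_k1"]] / 2.24e-2, 0.087, tolerance = 0.02)
  # the default 0-60 min window cannot identify this truth
  se60 <- design_se(sp14_70_truth(), sim_config(seed = 1, noise_sd = 0.02))
  expect_equal(se60[["se_alpha1"]], 0.53, tolerance = 0.02)
  expect_equal(se60[["se_k1"]] / 2.24e-2, 1.65, tolerance = 0.02)
})

test_that("time-course CSV round trip preserves observations and grouping", {
  tcs <- list(simulate_timecourse(sp14_70_truth(), sim_config(seed = 5),
                                  enzyme_id = "SP14", temperature = 70),
              simulate_timecourse(ground_truth(0.3, 0.2, 2e-3),
                                  sim_config(seed = 6),
                                  enzyme_id = "SP22", temperature = 80))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(tcs, tmp)
  back <- read_timecourse_csv(tmp)
  expect_identical(names(back), c("SP14_70C", "SP22_80C"))
  expect_equal(back$SP14_70C$data$alpha_obs, tcs[[1]]$data$alpha_obs)
})
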