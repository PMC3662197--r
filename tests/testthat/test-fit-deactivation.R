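test_that("zero-noise generator round trip recovers the truth to 1e-6 relative", {
  truths <- list(sp14_70_truth(),
                 ground_truth(0.328, 3.59e-1, 7.84e-3),
                 ground_truth(0.879, 3.45e-1, 4.85e-4))
  for (tr in truths) {
    grid <- recovery_design(tr$k1, tr$k2)
    tc <- simulate_timecourse(tr, sim_config(seed = 1, noise_sd = 0,
                                             time_grid = grid))
    f <- fit_two_step(tc, seed = 2)
    expect_lt(abs(f$alpha1 - tr$alpha1) / tr$alpha1, 1e-6)
    expect_lt(abs(f$k1 - tr$k1) / tr$k1, 1e-6)
    expect_lt(abs(f$k2 - tr$k2) / tr$k2, 1e-6)
    expect_lt(f$ssr, 1e-12)
  }
})

test_that("fewer than 4 distinct time points is an input error", {
  tc <- timecourse(rep(c(0, 10, 20), 2), rep(c(1, 0.6, 0.4), 2),
                   replicate = rep(1:2, each = 3))
  expect_error(fit_two_step(tc), "4 distinct time points")
})

test_that("single-exponential data sit on a degenerate ridge but are fit to SSR ~ 0", {
  t <- seq(0, 60, 5)
  tc <- timecourse(t, exp(-0.1 * t))
  f <- fit_two_step(tc, seed = 3)
  expect_lt(f$ssr, 1e-10)  # SSR is the contract here, not the parameters
})

test_that("first-order fit recovers a pure exponential exactly", {
  t <- seq(0, 100, 10)
  f <- fit_first_order(timecourse(t, exp(-0.05 * t)))
  expect_equal(f$k, 0.05, tolerance = 1e-8)
  expect_lt(f$ssr, 1e-14)
  expect_false(f$non_identifiable)
})

test_that("constant residual activity drives the first-order rate to its bound, flagged", {
  f <- fit_first_order(timecourse(seq(0, 60, 10), rep(1, 7)))
  expect_true(f$non_identifiable)
})

test_that("two-step SSR never exceeds first-order SSR (nesting)", {
  for (s in 1:8) {
    tr <- ground_truth(runif(1), 10^runif(1, -2, -0.5), 10^runif(1, -4, -2))
    tc <- simulate_timecourse(tr, sim_config(seed = 100 + s, noise_sd = 0.02))
    expect_lte(fit_two_step(tc, seed = s)$ssr,
               fit_first_order(tc)$ssr + 1e-12)
  }
})

test_that("strongly biphasic data are fit much better by the two-step model", {
  tr <- ground_truth(0.5, 0.3, 1e-4)
  tc <- simulate_timecourse(tr, sim_config(seed = 5, noise_sd = 0,
                                           time_grid = recovery_design(0.3, 1e-4)))
  expect_gt(fit_first_order(tc)$ssr, fit_two_step(tc, seed = 6)$ssr + 0.1)
})

test_that("model comparison prefers the right member on clear-cut data", {
  grid <- recovery_design(0.3, 1e-4)
  biphasic <- simulate_timecourse(ground_truth(0.5, 0.3, 1e-4),
                                  sim_config(seed = 8, noise_sd = 0.02,
                                             time_grid = grid))
  cmp <- compare_models(biphasic, seed = 9)
  expect_identical(cmp$preferred, "two_step")
  expect_gt(cmp$delta_aic, 10)

  t <- seq(0, 60, 5)
  pure <- simulate_timecourse(ground_truth(0, 0.05, 0.05),
                              sim_config(seed = 10, noise_sd = 0.02))
  cmp2 <- compare_models(pure, seed = 11)
  expect_identical(cmp2$preferred, "first_order")

  noiseless <- simulate_timecourse(ground_truth(0.5, 0.3, 1e-4),
                                   sim_config(seed = 12, noise_sd = 0,
                                              time_grid = grid))
  cmp3 <- compare_models(noiseless, seed = 13)
  expect_identical(cmp3$preferred, "two_step")
  expect_identical(cmp3$delta_aic, Inf)
})

test_that("fits are reproducible for a fixed seed and report sensible diagnostics", {
  tc <- simulate_timecourse(sp14_70_truth(), sim_config(seed = 20))
  f1 <- fit_two_step(tc, seed = 21)
  f2 <- fit_two_step(tc, seed = 21)
  expect_identical(f1[c("alpha1", "k1", "k2", "ssr")],
                   f2[c("alpha1", "k1", "k2", "ssr")])
  expect_identical(f1$n_obs, 39L)
  expect_true(f1$r2 > 0.9 && f1$r2 <= 1)
})

test_that("linearised standard errors track the design-based uncertainty", {
  tr <- sp14_70_truth()
  grid <- recovery_design(tr$k1, tr$k2)
  cfg <- sim_config(seed = 30, noise_sd = 0.02, time_grid = grid)
  f <- fit_two_step(simulate_timecourse(tr, cfg), seed = 31)
  se <- design_se(tr, cfg)
  # same order of magnitude as the Fisher prediction
  expect_lt(abs(log10(f$se_alpha1 / se["se_alpha1"])), 1)
  expect_lt(abs(log10(f$se_k1 / se["se_k1"])), 1)
})
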