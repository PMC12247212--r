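test_that("dof-corrected RMSE matches hand arithmetic and guards N > p", {
  expect_equal(goodness_of_fit(rep(0, 10), 3), 0)
  # residuals (+0.1, -0.1, +0.1, -0.1), p = 2: sqrt(0.04 / 2)
  expect_equal(goodness_of_fit(c(0.1, -0.1, 0.1, -0.1), 2), sqrt(0.02))
  expect_equal(round(goodness_of_fit(c(0.1, -0.1, 0.1, -0.1), 2), 5),
               0.14142)
  expect_error(goodness_of_fit(c(0.1, -0.1), 2), class = "scbli_dof_error")
})

test_that("initial guesses land within a decade of the generating rates", {
  sched <- nb_schedule()
  truth <- nb_params()
  sg <- simulate_sensorgram(sched, truth, noiseless(), grid = 0.5)
  g <- initial_guess(sg, sched)
  expect_lt(abs(log10(g$k_on / truth$k_on)), 1)
  expect_lt(abs(log10(g$k_off / truth$k_off)), 1)
  # clamped to the optimizer bounds
  o <- fit_options()
  expect_gte(g$k_on, o$k_on_bounds[1]); expect_lte(g$k_on, o$k_on_bounds[2])
  expect_gte(g$k_off, o$k_off_bounds[1]); expect_lte(g$k_off, o$k_off_bounds[2])
  expect_gte(g$R_max, o$R_max_bounds[1]); expect_lte(g$R_max, o$R_max_bounds[2])
  # a flat trace has no signal to guess from
  flat <- sensorgram(sg$times, rep(0, length(sg)), sg$step_index, sched)
  expect_error(initial_guess(flat, sched), class = "scbli_guess_error")
})

test_that("noiseless global fits recover the generating parameters", {
  sched <- nb_schedule()
  truth <- nb_params()
  sg <- simulate_sensorgram(sched, truth, noiseless(), grid = 0.5)
  fit <- fit_single_cycle(sg, sched, "standard")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$k_on - truth$k_on) / truth$k_on, 1e-4)
  expect_lt(abs(fit$params$k_off - truth$k_off) / truth$k_off, 1e-4)
  expect_lt(fit$rmse, 1e-9)
  expect_identical(fit$rmse, goodness_of_fit(fit$residuals, fit$p))
  expect_equal(fit$p, 3L)
  expect_equal(fit$N, length(fit$residuals))

  # partial-dissociation truth: phi recovered to < 0.01 on noiseless data
  pp <- partial_params(truth, "global", phi = 0.30)
  sgp <- simulate_sensorgram(sched, pp, noiseless(), grid = 0.5)
  fitp <- fit_single_cycle(sgp, sched, "partial_global")
  expect_lt(abs(fitp$params$phi - 0.30), 0.01)
  expect_lt(abs(fitp$params$k_on - truth$k_on) / truth$k_on, 1e-4)
  expect_equal(fitp$p, 4L)

  # local-plateau variant on the same data (plateaus phi * R0 per segment)
  fitl <- fit_single_cycle(sgp, sched, "partial_local")
  expect_lt(fitl$rmse, 1e-6)
  expect_lt(abs(fitl$params$k_off - truth$k_off) / truth$k_off, 1e-3)
})

test_that("fitting phi = 0 data with either model gives the same rates", {
  sched <- nb_schedule()
  truth <- nb_params()
  sg <- simulate_sensorgram(sched, truth, noiseless(), grid = 0.5)
  f_std <- fit_single_cycle(sg, sched, "standard")
  f_par <- fit_single_cycle(sg, sched, "partial_global")
  expect_lt(abs(f_par$params$k_on - f_std$params$k_on) / f_std$params$k_on,
            1e-3)
  expect_lt(abs(f_par$params$k_off - f_std$params$k_off) / f_std$params$k_off,
            1e-3)
  expect_lte(f_par$params$phi, 0.01)
  # the parsimony helper then keeps the standard model
  expect_identical(select_model(f_std, f_par)$model, "standard")
})

test_that("the optimum is invariant to sample order within segments", {
  sched <- nb_schedule()
  sg <- simulate_sensorgram(sched, nb_params(),
                            noise_model(sigma = 0.005, seed = 3), grid = 0.5)
  fit <- fit_single_cycle(sg, sched, "standard")
  # residuals enter as a sum of squares, so any permutation that keeps the
  # (time, response) pairing leaves the objective unchanged; verify via the
  # deviance of the fitted parameters under a shuffled evaluation order
  set.seed(9)
  perm <- sample(length(sg$times))
  dev_perm <- sum((sg$responses[perm] -
                   predict_trace(sched, fit$params,
                                 times = sg$times)$responses[perm])[
                     !is.na(sg$step_index[perm])]^2)
  expect_equal(dev_perm, fit$deviance, tolerance = 1e-12)
})

test_that("fitted parameters respect their bounds under noise", {
  sched <- nb_schedule()
  for (s in 1:3) {
    sg <- simulate_sensorgram(sched, nb_params(),
                              noise_model(sigma = 0.01, seed = s))
    f <- fit_single_cycle(sg, sched, "partial_global")
    expect_gte(f$params$phi, 0); expect_lte(f$params$phi, 0.95)
    expect_gt(f$params$k_on, 0); expect_gt(f$params$k_off, 0)
  }
})

test_that("steady-state isotherm fit recovers K_D and R_max", {
  C <- c(25, 50, 100, 200, 400, 800, 1600) * 1e-9
  req <- 0.2 * C / (C + 100e-9)
  ss <- fit_steady_state(C, req)
  expect_lt(abs(ss$K_D - 100e-9) / 100e-9, 1e-4)
  expect_lt(abs(ss$R_max - 0.2) / 0.2, 1e-4)
  # scale equivariance: responses x c leave K_D alone, scale R_max
  ss3 <- fit_steady_state(C, 3 * req)
  expect_equal(ss3$K_D, ss$K_D, tolerance = 1e-6)
  expect_equal(ss3$R_max, 3 * ss$R_max, tolerance = 1e-6)
  expect_error(fit_steady_state(C[1:2], req[1:2]), class = "scbli_data_error")
  # responses proportional to C carry no K_D information
  expect_error(
    suppressWarnings(fit_steady_state(C, 1e5 * C)),
    class = "scbli_data_error")
})

test_that("asymptotic standard errors behave in the zero-noise limit and calibrate under noise", {
  sched <- nb_schedule()
  truth <- nb_params()
  sg <- simulate_sensorgram(sched, truth, noiseless(), grid = 0.5)
  fit <- fit_single_cycle(sg, sched, "standard")
  se <- parameter_uncertainty(fit)
  expect_named(se, c("k_on", "k_off", "R_max"))
  expect_lt(se[["k_on"]] / truth$k_on, 1e-6)
  expect_lt(se[["k_off"]] / truth$k_off, 1e-6)
  expect_true(is.finite(attr(se, "condition_number")))

  # calibration: empirical SD of estimates across seeded noisy replicates
  # should sit within a factor of 2 of the mean reported SE
  ests <- t(sapply(1:24, function(s) {
    sgn <- simulate_sensorgram(sched, truth,
                               noise_model(sigma = 0.005, seed = 100 + s))
    f <- fit_single_cycle(sgn, sched, "standard")
    c(f$params$k_on, f$params$k_off, parameter_uncertainty(f)[1:2])
  }))
  for (j in 1:2) {
    ratio <- sd(ests[, j]) / mean(ests[, j + 2])
    expect_gt(ratio, 0.5); expect_lt(ratio, 2)
  }
})

test_that("loading traces rank by capture rate with saturation flags", {
  nm <- function(seed) noise_model(sigma = 0.002, seed = seed)
  segs <- list(
    fast = simulate_loading(100e-9, 1e5, 0.15, 600, nm(1)),
    mid  = simulate_loading(50e-9, 1e5, 0.15, 600, nm(2)),
    slow = simulate_loading(10e-9, 1e5, 0.15, 600, nm(3)))
  rk <- rank_expression(segs)
  expect_equal(rk$sensor, c("fast", "mid", "slow"))  # 10:5:1 rate ratio
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$rank_score, rk$k_obs)
  expect_true(rk$saturated[1])   # k C t = 0.01 * 600 >> 5 at the top rate
  expect_false(rk$saturated[3])  # 0.001 * 600 = 0.6 time constants

  # identical traces tie
  same <- simulate_loading(50e-9, 1e5, 0.15, 600, noiseless())
  rk2 <- rank_expression(list(a = same, b = same))
  expect_lt(abs(rk2$k_obs[1] - rk2$k_obs[2]), 1e-9)

  # a constant-zero trace cannot be ranked and raises a quality warning
  zero <- sensorgram(seq(0, 600, 0.5), rep(0, 1201))
  expect_warning(rk3 <- rank_expression(list(dead = zero, live = same)),
                 class = "scbli_quality_warning")
  expect_true(is.na(rk3$k_obs[rk3$sensor == "dead"]))
  expect_equal(rk3$sensor[1], "live")
})
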