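test_that("noiseless simulation equals the analytic prediction exactly", {
  sched <- nb_schedule()
  sim <- simulate_sensorgram(sched, nb_params(), noiseless(), grid = 0.5)
  pred <- predict_trace(sched, nb_params(), grid = 0.5)
  expect_identical(sim$responses, pred$responses)
  expect_identical(sim$times, pred$times)
})

test_that("the seed fixes the whole simulated stream", {
  sched <- nb_schedule()
  nm <- noise_model(sigma = 0.005, drift = 1e-5, step_shift_sd = 0.01,
                    seed = 42)
  a <- simulate_sensorgram(sched, nb_params(), nm)
  b <- simulate_sensorgram(sched, nb_params(), nm)
  expect_identical(a$responses, b$responses)
  c <- simulate_sensorgram(sched, nb_params(),
                           noise_model(sigma = 0.005, drift = 1e-5,
                                       step_shift_sd = 0.01, seed = 43))
  expect_gt(max(abs(a$responses - c$responses)), 1e-12)
  # seeding must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_sensorgram(sched, nb_params(), nm))
  expect_identical(runif(1), before)
})

test_that("simulated noise has the requested moments", {
  sched <- nb_schedule()
  clean <- predict_trace(sched, nb_params(), grid = 0.5)
  sim <- simulate_sensorgram(sched, nb_params(),
                             noise_model(sigma = 0.005, seed = 7), grid = 0.5)
  resid <- sim$responses - clean$responses
  expect_gte(length(resid), 1000)
  expect_lt(abs(sd(resid) - 0.005) / 0.005, 0.05)
  expect_lt(abs(mean(resid)), 5 * 0.005 / sqrt(length(resid)))
})

test_that("drift and bulk shifts enter as modelled, and shift correction undoes them", {
  sched <- nb_schedule()
  clean <- predict_trace(sched, nb_params(), grid = 0.5)
  # pure drift: difference from clean is exactly drift * t
  dr <- simulate_sensorgram(sched, nb_params(),
                            noise_model(sigma = 0, drift = 2e-5), grid = 0.5)
  expect_equal(dr$responses - clean$responses, 2e-5 * dr$times,
               tolerance = 1e-12)
  # bulk shifts accumulate: piecewise-constant offsets, constant within steps
  sh <- simulate_sensorgram(sched, nb_params(),
                            noise_model(sigma = 0, step_shift_sd = 0.05,
                                        seed = 5), grid = 0.5)
  off <- sh$responses - clean$responses
  for (k in unique(sh$step_index))
    expect_lt(diff(range(off[sh$step_index == k])), 1e-12)
  expect_gt(diff(range(off)), 1e-3)
  # rigid re-joining removes them up to one sample's genuine kinetics
  fixed <- correct_interstep_shifts(sh, sched)
  expect_lt(max(abs(fixed$responses - clean$responses)), 5e-3)
})

test_that("loading simulation reflects irreversible pseudo-first-order capture", {
  t95 <- function(sg, rsat) sg$times[min(which(sg$responses >= 0.95 * rsat))]
  hi <- simulate_loading(100e-9, 1e4, 0.2, 2e5, noiseless(), grid = 5)
  lo <- simulate_loading(10e-9, 1e4, 0.2, 2e5, noiseless(), grid = 5)
  # 10x concentration -> 10x faster approach to saturation
  expect_equal(t95(lo, 0.2) / t95(hi, 0.2), 10, tolerance = 0.01)
  # both plateau at R_sat: capture is covalent, density ends up equivalent
  expect_lt(abs(tail(hi$responses, 1) - 0.2), 1e-6)
  expect_lt(abs(tail(lo$responses, 1) - 0.2), 1e-3)
  # cross-module oracle: ranking recovers the generating concentration order
  nm <- function(s) noise_model(sigma = 0.002, seed = s)
  segs <- list(c100 = simulate_loading(100e-9, 1e5, 0.15, 600, nm(1)),
               c50  = simulate_loading(50e-9, 1e5, 0.15, 600, nm(2)),
               c10  = simulate_loading(10e-9, 1e5, 0.15, 600, nm(3)))
  expect_equal(rank_expression(segs)$sensor, c("c100", "c50", "c10"))
})

test_that("fixture plates round-trip and are byte-identical for a fixed seed", {
  sched <- nb_schedule()
  spec <- list(
    s1 = list(params = nb_params(), schedule = sched,
              noise = noise_model(sigma = 0.005, seed = 11)),
    s2 = list(params = kinetic_params(1.7e5, 1.13e-3, 0.75), schedule = sched,
              noise = noise_model(sigma = 0.005, seed = 12)),
    s3 = list(params = partial_params(nb_params(), "global", phi = 0.3),
              schedule = sched, noise = noise_model(sigma = 0.005, seed = 13)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_fixture_plate(spec, d1, include_reference = TRUE)
  p2 <- make_fixture_plate(spec, d2, include_reference = TRUE)
  expect_length(p1$sensorgrams, 3)
  expect_true(file.exists(p1$reference))
  for (i in seq_along(p1$sensorgrams))
    expect_identical(readLines(p1$sensorgrams[i]),
                     readLines(p2$sensorgrams[i]))
  expect_identical(readLines(p1$reference), readLines(p2$reference))

  # everything written is parseable and aligned to the emitted schedule
  sched2 <- read_schedule(p1$schedule)
  sg <- read_sensorgram_table(p1$sensorgrams[1])
  al <- align_to_assay_clock(sg, sched2)
  expect_equal(length(al), length(sg))
  man <- jsonlite::read_json(p1$manifest)
  expect_equal(man$s1$K_D, dissociation_constant(nb_params()))

  # the reference trace is pure noise around zero
  ref <- read_sensorgram_table(p1$reference)
  expect_lt(abs(mean(ref$responses)), 3 * 0.005 / sqrt(length(ref)) + 1e-3)
  expect_lt(abs(sd(ref$responses) - 0.005) / 0.005, 0.1)
})

test_that("fits of plate fixtures recover the generating affinities end-to-end", {
  sched <- nb_schedule()
  spec <- list(s1 = list(params = nb_params(), schedule = sched,
                         noise = noise_model(sigma = 0.005, seed = 21)))
  d <- withr::local_tempdir()
  paths <- make_fixture_plate(spec, d)
  sg <- align_to_assay_clock(read_sensorgram_table(paths$sensorgrams[1]),
                             read_schedule(paths$schedule))
  fit <- fit_single_cycle(sg, sched, "standard")
  kd_true <- dissociation_constant(nb_params())
  expect_lt(abs(dissociation_constant(fit$params) - kd_true) / kd_true, 0.15)
})
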