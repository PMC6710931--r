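test_that("random networks are grammar-valid and reproducible", {
  m <- generateRandomNetwork(2, 6, seed = 1)
  expect_equal(nrow(states(m)), 5L)  # 2 pairs + stress pool
  expect_equal(nrow(pathways(m)), 6L)
  expect_true(validateModel(m)@ok)
  expect_identical(serializeModel(generateRandomNetwork(2, 6, seed = 1)),
                   serializeModel(m))
  # property sweep: validation and rate-system construction never fail
  for (s in 1:100) {
    mr <- generateRandomNetwork(2 + (s %% 3), 4 + (s %% 7), seed = s)
    expect_true(validateModel(mr)@ok)
    expect_s4_class(buildRateSystem(mr), "RateSystem")
  }
  # smallest grammar: one neuron pair + stress, all 6 possible edges
  m1 <- generateRandomNetwork(1, 6, seed = 2)
  expect_s4_class(buildRateSystem(m1), "RateSystem")
  expect_error(generateRandomNetwork(1, 100, seed = 1), "infeasible")
  expect_error(generateRandomNetwork(0, 1, seed = 1), "between 1 and 4")
})

test_that("observation noise is multiplicative with the requested scale", {
  toy <- exponentialToy()
  # zero noise reproduces the simulation exactly
  obs0 <- generateNoisyObservations(toy, times = 0:20, noise_sd = 0,
                                    seed = 2, lambda_degradation = 0)
  sys <- buildRateSystem(toy, lambda_degradation = 0)
  sim <- trajectoryStates(simulateTrajectory(
    sys, opts = solverOptions(output_grid = 0:20)))
  expect_equal(obs0@observed, sim, tolerance = 1e-12)
  # fixed seed: bit-identical observations
  obs1 <- generateNoisyObservations(toy, times = 0:20, noise_sd = 0.01,
                                    seed = 3, lambda_degradation = 0)
  obs2 <- generateNoisyObservations(toy, times = 0:20, noise_sd = 0.01,
                                    seed = 3, lambda_degradation = 0)
  expect_identical(obs1@observed, obs2@observed)
  # empirical relative deviation over ~1000 cells is close to noise_sd
  m <- defaultModel()
  obs <- generateNoisyObservations(m, times = 0:120, noise_sd = 0.01,
                                   seed = 4)
  simd <- trajectoryStates(simulateTrajectory(
    buildRateSystem(m), opts = solverOptions(output_grid = 0:120)))
  rel <- (obs@observed / simd - 1)[simd > 0]
  expect_gte(length(rel), 1000L)
  expect_gte(stats::sd(rel), 0.008)
  expect_lte(stats::sd(rel), 0.012)
  expect_true(all(obs@observed >= 0))
  expect_identical(obs@truth, rateValues(m))
})

test_that("zero-noise recovery finds a free rate to high precision", {
  toy <- exponentialToy(k3 = 0.1)
  obs <- generateNoisyObservations(toy, times = 0:20, noise_sd = 0,
                                   seed = 7, lambda_degradation = 0)
  fit <- recoverParameters(obs, toy, "k3", lambda_degradation = 0)
  expect_lt(abs(fit$rates[["k3"]] - 0.1) / 0.1, 1e-6)
  expect_length(fit$non_identifiable, 0)
  # objective at the truth is no worse than at the 2x start
  f <- RGCglia:::.recoveryObjective(obs, toy, "k3", 0, solverOptions())
  expect_lte(f(log(0.1)), f(log(0.2)))
})

test_that("rates with no observable effect are flagged non-identifiable", {
  # in the homeostatic default regime the clipped hazard is zero, so the
  # death-channel rate k3 cannot be identified from trajectories
  m <- defaultModel()
  obs <- generateNoisyObservations(m, times = seq(0, 20, by = 2),
                                   noise_sd = 0, seed = 9)
  expect_warning(fit <- recoverParameters(obs, m, c("k3", "k12")),
                 "non-identifiable")
  expect_identical(fit$non_identifiable, "k3")
  expect_error(recoverParameters(
    new("ObservationSet", times = c(0, 1),
        observed = obs@observed[1:2, ], noise_sd = 0, seed = 1L,
        truth = obs@truth),
    m, "k12"), ">= 3 time points")
})

test_that("recovery error shrinks as observation noise decreases", {
  toy <- exponentialToy(k3 = 0.1)
  noise_levels <- c(0.05, 0.02, 0.01, 0)
  med_err <- vapply(noise_levels, function(ns) {
    errs <- vapply(1:20, function(s) {
      obs <- generateNoisyObservations(toy, times = 0:20, noise_sd = ns,
                                       seed = s, lambda_degradation = 0)
      fit <- recoverParameters(obs, toy, "k3", lambda_degradation = 0)
      abs(fit$rates[["k3"]] - 0.1) / 0.1
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0))
})

test_that("observation sets round-trip through CSV plus sidecar", {
  toy <- exponentialToy()
  obs <- generateNoisyObservations(toy, times = 0:10, noise_sd = 0.02,
                                   seed = 5, lambda_degradation = 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeObservations(obs, tmp)
  back <- readObservations(tmp)
  expect_equal(back@observed, obs@observed, tolerance = 1e-12)
  expect_identical(back@seed, obs@seed)
  expect_equal(back@noise_sd, obs@noise_sd)
  expect_equal(back@truth, obs@truth)
})
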