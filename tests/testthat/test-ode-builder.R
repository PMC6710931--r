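test_that("edge classification follows the term grammar", {
  m <- defaultModel()
  t1 <- classifyEdgeTerm("k1", m)     # Aa -> Rs
  expect_equal(t1$kind, "protective_hazard")
  expect_equal(t1$catalyst, "Aa")
  expect_equal(t1$normalization, 101000)  # astroglia lineage total at t = 0
  t14 <- classifyEdgeTerm("k14", m)   # Ma -> Mb, same lineage
  expect_equal(t14$kind, "conversion")
  expect_equal(t14$substrate, "Ma")
  expect_equal(t14$product, "Mb")
  t15 <- classifyEdgeTerm("k15", m)   # Rs -> Cs
  expect_equal(t15$kind, "stress_production")
  expect_equal(t15$catalyst, "Rs")
  t3 <- classifyEdgeTerm("k3", m)     # Mb -> Rd
  expect_equal(t3$kind, "harmful_hazard")
  t12 <- classifyEdgeTerm("k12", m)   # Aa -> Mb: catalyzed Ma -> Mb
  expect_equal(t12$kind, "catalyzed_conversion")
  expect_equal(t12$substrate, "Ma")
  expect_equal(t12$product, "Mb")
  # expected split over the default model
  tt <- termTable(buildRateSystem(m))
  expect_equal(nrow(tt), 22L)
  expect_equal(sum(tt$kind == "protective_hazard"), 2L)  # k1, k17
  expect_equal(sum(tt$kind == "harmful_hazard"), 3L)     # k2, k3, k18
  expect_equal(sum(tt$kind == "stress_production"), 2L)  # k15, k16
  expect_equal(sum(tt$kind == "conversion"), 2L)         # k9, k14
  expect_equal(sum(tt$kind == "catalyzed_conversion"), 13L)
})

test_that("the default system has 7 cell equations plus 1 stress equation", {
  sys <- buildRateSystem(defaultModel())
  expect_equal(length(dynamicalStates(sys)), 8L)
  expect_false(is.na(sys@stress_id))
  expect_equal(length(setdiff(dynamicalStates(sys), sys@stress_id)), 7L)
  expect_equal(sys@bookkept$dead_id, "Rd")
  expect_equal(sys@bookkept$total, 10100)
  # one term per pathway, and an equation line per dynamical state
  expect_equal(nrow(termTable(sys)), nrow(pathways(defaultModel())))
  eq <- equationText(sys)
  expect_true(all(sprintf("d[%s]/dt", dynamicalStates(sys)) %in%
                    vapply(strsplit(eq, " = "), `[`, "", 1)))
  # microglia-pair toy: 2 equations, no hazard, no stress
  sys2 <- buildRateSystem(microgliaPairToy())
  expect_equal(length(dynamicalStates(sys2)), 2L)
  expect_true(is.na(sys2@stress_id))
  expect_equal(nrow(sys2@bookkept), 0L)
})

test_that("hazard assembles as clipped harmful-minus-protective", {
  m <- setRateValues(defaultModel(),
                     c(stats::setNames(rep(0, 22), paste0("k", 1:22)),
                       k1 = 0.2, k3 = 0.2))
  sys <- buildRateSystem(m)
  at_norm <- c(Rs = 1e4, Aa = 101000, Ab = 0, Ma = 0, Mb = 101000,
               Ga = 0, Gb = 0, Cs = 1e3)
  # exact cancellation then clip
  expect_equal(hazardValue(sys, at_norm), 0)
  # single harmful term at its normalization value
  m2 <- setRateValues(m, c(k1 = 0))
  expect_equal(hazardValue(buildRateSystem(m2), at_norm), 0.2)
  # protective excess clips at zero, never negative
  m3 <- setRateValues(m, c(k1 = 0.5))
  expect_equal(hazardValue(buildRateSystem(m3), at_norm), 0)
  expect_error(hazardValue(sys, at_norm[-2]), "missing")
})

test_that("derivatives obey conversion kinetics and lineage conservation", {
  sys <- buildRateSystem(microgliaPairToy(k = 0.5))
  d <- evaluateDerivatives(sys, 0, c(Ma = 100, Mb = 0))
  expect_equal(unname(d["Ma"]), -50)
  expect_equal(unname(d["Mb"]), 50)
  # absorbing origin
  d0 <- evaluateDerivatives(sys, 0, c(Ma = 0, Mb = 0))
  expect_true(all(d0 == 0))
  # default model at the default state: astroglia pair sum is conserved
  sysd <- buildRateSystem(defaultModel())
  dd <- evaluateDerivatives(sysd, 0, sysd@init)
  expect_equal(unname(dd["Aa"] + dd["Ab"]), 0)
  expect_equal(unname(dd["Ma"] + dd["Mb"]), 0)
  expect_equal(unname(dd["Ga"] + dd["Gb"]), 0)
  # all rates zero: derivative identically zero (stress still degrades)
  mz <- setRateValues(defaultModel(),
                      stats::setNames(rep(0, 22), paste0("k", 1:22)))
  sz <- buildRateSystem(mz, lambda_degradation = 0)
  expect_true(all(evaluateDerivatives(sz, 0, sz@init) == 0))
  expect_error(evaluateDerivatives(sysd, 0, c(sysd@init[-1], Rs = NaN)),
               "non-finite")
})

test_that("compiled integrator right-hand side equals the reference", {
  # brute-force equivalence at random states
  sys <- buildRateSystem(defaultModel())
  cs <- RGCglia:::.compileSystem(sys)
  set.seed(11)
  for (i in 1:100) {
    y <- stats::setNames(runif(8, 0, 1e5), dynamicalStates(sys))
    y["Rs"] <- runif(1, 0, 10100)
    d_ref <- evaluateDerivatives(sys, 0, y)
    d_fast <- RGCglia:::.compiledDerivs(cs, unname(y[dynamicalStates(sys)]),
                                        unname(sys@rate_values))
    expect_lt(max(abs(d_ref - d_fast)) / max(1, max(abs(d_ref))), 1e-12)
  }
})

test_that("random grammar-valid networks always build a rate system", {
  for (s in 1:30) {
    m <- generateRandomNetwork(2, 6, seed = s)
    expect_true(validateModel(m)@ok)
    expect_s4_class(buildRateSystem(m), "RateSystem")
  }
})
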