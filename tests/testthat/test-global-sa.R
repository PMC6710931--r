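test_that("Latin hypercube samples are exactly stratified per parameter", {
  # one parameter on [0, 1], n = 4: exactly one draw per quartile
  d <- lhsSample(matrix(c(0, 1), 1, 2,
                        dimnames = list("p1", c("low", "high"))),
                 n = 4, seed = 1, log_scale = FALSE)
  expect_equal(as.integer(table(cut(d@samples[, 1], seq(0, 1, 0.25)))),
               rep(1L, 4))
  # determinism under a fixed seed
  r <- defaultRanges(defaultModel())
  d1 <- lhsSample(r, n = 50, seed = 99)
  d2 <- lhsSample(r, n = 50, seed = 99)
  expect_identical(d1@samples, d2@samples)
  # 22 parameters, log-uniform: stratified in log space for every column
  d3 <- lhsSample(r, n = 200, seed = 7)
  for (j in seq_len(ncol(d3@samples))) {
    breaks <- seq(log(r[j, 1]), log(r[j, 2]), length.out = 201)
    counts <- table(findInterval(log(d3@samples[, j]), breaks,
                                 rightmost.closed = TRUE))
    expect_true(all(counts == 1L) && length(counts) == 200L)
  }
  expect_error(lhsSample(r, n = 1, seed = 1), ">= 2")
})

test_that("PRCC matches a brute-force partial-correlation-on-ranks oracle", {
  # 10-row fixture table: three inputs, one output
  X <- cbind(x1 = c(0.12, 0.47, 0.81, 0.23, 0.95, 0.34, 0.58, 0.71, 0.05, 0.66),
             x2 = c(0.88, 0.14, 0.42, 0.67, 0.29, 0.91, 0.07, 0.53, 0.76, 0.38),
             x3 = c(0.31, 0.72, 0.18, 0.84, 0.56, 0.09, 0.63, 0.27, 0.45, 0.98))
  y <- c(3.7, 1.2, 8.4, 5.5, 9.9, 0.6, 4.1, 7.3, 2.8, 6.0)
  res <- prcc(X, y)
  expect_equal(res$prcc, prccOracle(X, y), tolerance = 1e-12)
  # perfect monotone association gives PRCC 1
  set.seed(3)
  X2 <- cbind(x1 = runif(40), x2 = runif(40), x3 = runif(40))
  y2 <- exp(3 * X2[, "x1"])  # strictly increasing, no noise
  res2 <- prcc(X2, y2)
  expect_equal(res2$prcc[res2$parameter == "x1"], 1, tolerance = 1e-9)
  expect_lt(res2$p_value[res2$parameter == "x1"], 1e-12)
  # degenerate inputs are refused
  expect_error(prcc(X, rep(1, 10)), "constant output")
  expect_error(prcc(cbind(X, x4 = rep(2, 10)), y), "constant design")
  expect_error(prcc(X[1:4, ], y[1:4]), "n > p")
})

test_that("PRCC is invariant under monotone transforms of inputs/outputs", {
  set.seed(8)
  X <- cbind(a = runif(60), b = runif(60), c = runif(60))
  y <- 2 * X[, "a"] - X[, "b"] + rnorm(60, 0, 0.1)
  base <- prcc(X, y)$prcc
  Xt <- X
  Xt[, "a"] <- exp(5 * X[, "a"])       # strictly increasing transform
  expect_equal(prcc(Xt, y)$prcc, base, tolerance = 1e-12)
  expect_equal(prcc(X, y^3 + 10)$prcc, base, tolerance = 1e-12)
})

test_that("null inputs are rejected at close to the nominal rate", {
  # independent inputs and output: type-I rate at p < 0.01 stays within
  # binomial tolerance of the nominal level over 1000 replicates
  n <- 50; p <- 5
  hits <- 0L; total <- 0L
  for (s in 1:1000) {
    set.seed(s)
    X <- matrix(runif(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    pv <- prcc(X, y)$p_value
    hits <- hits + sum(pv < 0.01)
    total <- total + p
  }
  rate <- hits / total
  expect_gte(rate, 0.001)
  expect_lte(rate, 0.03)
})

test_that("a pure-noise parameter is rarely called significant", {
  # y depends on x1 only; x2's PRCC should be non-significant in >= 95%
  # of seeded repeats at n = 200
  nonsig <- 0L
  for (s in 1:100) {
    set.seed(s + 1000)
    X <- cbind(x1 = runif(200), x2 = runif(200), x3 = runif(200))
    y <- 3 * X[, "x1"] + rnorm(200, 0, 0.5)
    pv <- prcc(X, y)$p_value[2]
    if (pv > 0.01) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 95L)
})

test_that("time-resolved PRCC has the contracted shape and reproducibility", {
  m <- defaultModel()
  d <- lhsSample(defaultRanges(m), n = 30, seed = 5)
  pr <- timeResolvedPRCC(m, d, output_times = 0:20)
  expect_identical(dim(pr@coefficients), c(22L, 2L, 21L))
  expect_identical(dimnames(pr@coefficients)[[2]], c("Rs", "Cs"))
  expect_identical(pr@n_failed, 0L)
  # t = 0: every output equals its initial value -> undefined, not significant
  expect_true(all(is.na(pr@coefficients[, , "0"])))
  expect_true(all(!pr@significant[, , "0"]))
  expect_true(all(abs(pr@coefficients[, , "20"]) <= 1))
  # bit-identical rerun from the same seed
  pr2 <- timeResolvedPRCC(m, lhsSample(defaultRanges(m), n = 30, seed = 5),
                          output_times = 0:20)
  expect_identical(pr@coefficients, pr2@coefficients)
  expect_identical(pr@p_values, pr2@p_values)
})

test_that("PRCC long-format writer and design writer record provenance", {
  m <- defaultModel()
  d <- lhsSample(defaultRanges(m), n = 30, seed = 5)
  pr <- timeResolvedPRCC(m, d, output_times = c(0, 10, 20))
  tmp <- withr::local_tempfile(fileext = ".csv")
  writePRCC(pr, tmp)
  df <- utils::read.csv(tmp)
  expect_identical(names(df), c("parameter", "output", "time_years",
                                "prcc", "p_value", "significant"))
  expect_equal(nrow(df), 22 * 2 * 3)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeDesign(d, tmp2)
  expect_match(readLines(tmp2, n = 1), "seed: 5")
  df2 <- utils::read.csv(tmp2, comment.char = "#")
  expect_equal(dim(df2), c(30L, 22L))
})
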