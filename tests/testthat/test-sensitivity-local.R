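test_that("finite differences converge to the closed-form derivative", {
  # dRs(T)/dk = -T Rs(0) exp(-kT) for the frozen-catalyst toy
  toy <- exponentialToy(k3 = 0.1)
  closed <- -20 * 1e4 * exp(-2)
  psi3pc <- localSensitivity(toy, "k3", "Rs", horizon = 20,
                             perturbation = 0.03, lambda_degradation = 0)
  expect_lt(abs(psi3pc - closed) / abs(closed), 1e-3)
  psi03pc <- localSensitivity(toy, "k3", "Rs", horizon = 20,
                              perturbation = 0.003, lambda_degradation = 0)
  expect_lt(abs(psi03pc - closed) / abs(closed), 1e-5)
  # conservation antisymmetry: what Rs loses, Rd gains
  psi_rd <- localSensitivity(toy, "k3", "Rd", horizon = 20,
                             perturbation = 0.03, lambda_degradation = 0)
  expect_equal(psi3pc + psi_rd, 0, tolerance = 1e-7)
})

test_that("zero base rates demand the absolute-perturbation mode", {
  m <- setRateValues(defaultModel(), c(k3 = 0))
  expect_error(localSensitivity(m, "k3", "Rs"), "absolute")
  psi <- localSensitivity(m, "k3", "Rs", absolute = TRUE,
                          perturbation = 0.01)
  expect_true(is.finite(psi))
})

test_that("sensitivity matrix covers all rates and states with correct signs", {
  res <- sensitivityMatrix(defaultModel(), horizon = 20)
  expect_identical(dim(res@matrix), c(22L, 9L))
  expect_identical(rownames(res@matrix), paste0("k", 1:22))
  expect_setequal(colnames(res@matrix),
                  c("Rs", "Rd", "Aa", "Ab", "Mb", "Ma", "Cs", "Ga", "Gb"))
  expect_true(all(is.finite(res@matrix)))
  # harmful edge k3: never helps survival, never lowers deaths
  expect_lte(res@matrix["k3", "Rs"], 0)
  expect_gte(res@matrix["k3", "Rd"], 0)
  # conservation antisymmetry across every rate
  expect_lt(max(abs(res@matrix[, "Rs"] + res@matrix[, "Rd"])), 1e-4)
  # activation rate k14 drives proinflammatory microglia up
  expect_gt(res@matrix["k14", "Mb"], 0)
  expect_lt(res@matrix["k14", "Ma"], 0)
})

test_that("microglial activation dominates the harmful RGC sensitivities", {
  # in the pathogenic regime the largest-magnitude NEGATIVE Psi(Rs, .)
  # among pathogenic edges belongs to an edge producing proinflammatory
  # microglia (survival is inversely related to microglial activation)
  m <- diseaseVariant()
  res <- sensitivityMatrix(m, horizon = 20)
  pw <- pathways(m)
  path_edges <- pw$rate_name[pw$annotation == "pathogenic"]
  psi_rs <- res@matrix[path_edges, "Rs"]
  harmful <- psi_rs[psi_rs < 0]
  expect_gt(length(harmful), 0)
  winner <- names(which.min(harmful))
  expect_equal(pw$target[pw$rate_name == winner], "Mb")
  # and the activation edges k11, k12, k14, k22 all depress survival
  expect_true(all(psi_rs[c("k11", "k12", "k14", "k22")] < 0))
})

test_that("disconnected rates have zero sensitivity", {
  # an edge acting inside an otherwise uncoupled lineage cannot move RGCs
  m <- loadModel('
states:
  - {id: Rs, display_name: Rs, lineage: rgc, mode: surviving, initial_value: 1.0e4}
  - {id: Rd, display_name: Rd, lineage: rgc, mode: dead, initial_value: 1.0e2}
  - {id: Ma, display_name: Ma, lineage: microglia, mode: quiescent, initial_value: 0}
  - {id: Mb, display_name: Mb, lineage: microglia, mode: activated, initial_value: 1.0e5}
  - {id: Ga, display_name: Ga, lineage: mueller, mode: quiescent, initial_value: 100}
  - {id: Gb, display_name: Gb, lineage: mueller, mode: activated, initial_value: 0}
pathways:
  - {id: 1, source: Mb, target: Rd, rate_name: k3, rate_value: 0.1, annotation: pathogenic, efficacy_tier: low}
  - {id: 2, source: Ga, target: Gb, rate_name: kx, rate_value: 0.2, annotation: pathogenic, efficacy_tier: low}
')
  tight <- solverOptions(rel_tol = 1e-10, abs_tol = 1e-12)
  psi <- localSensitivity(m, "kx", "Rs", horizon = 20,
                          lambda_degradation = 0, opts = tight)
  # zero up to finite-difference amplification of the solver tolerance
  expect_lt(abs(psi), 1e-3)
})

test_that("heatmap clustering orders rows by profile similarity", {
  # two identical rows merge first and sit adjacent
  M <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 4))
  ch <- clusterHeatmap(M)
  expect_equal(abs(match(1, ch$row_order) - match(2, ch$row_order)), 1)
  # hand-computed average-linkage merge sequence on three profiles
  M2 <- rbind(r1 = c(0, 0, 1), r2 = c(0, 1, 3), r3 = c(5, 1, 0))
  z <- t(apply(M2, 1, function(r) (r - mean(r)) / stats::sd(r)))
  d <- stats::dist(z)
  hc <- stats::hclust(d, method = "average")
  expect_identical(clusterHeatmap(M2)$row_order, hc$order)
  # degenerate inputs
  suppressWarnings(ch1 <- clusterHeatmap(matrix(5, 1, 1)))
  expect_identical(ch1$row_order, 1L)
  expect_identical(ch1$col_order, 1L)
  expect_warning(clusterHeatmap(matrix(1, 3, 3)), "degenerate")
  expect_error(clusterHeatmap(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("sensitivity CSV writer round-trips the matrix", {
  res <- sensitivityMatrix(exponentialToy(), horizon = 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeSensitivity(res, tmp)
  df <- utils::read.csv(tmp, check.names = FALSE)
  expect_identical(df$rate_name, rownames(res@matrix))
  expect_equal(as.matrix(df[, -1]), res@matrix, ignore_attr = TRUE)
})
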