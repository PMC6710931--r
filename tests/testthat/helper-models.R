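# Toy fixtures built in code.

# Single harmful edge with a frozen catalyst at its normalization value:
# h = k3 exactly, so Rs(t) = Rs(0) exp(-k3 t) in closed form.
exponentialToy <- function(k3 = 0.1) {
  loadModel(sprintf('
states:
  - {id: Rs, display_name: Rs, lineage: rgc, mode: surviving, initial_value: 1.0e4}
  - {id: Rd, display_name: Rd, lineage: rgc, mode: dead, initial_value: 1.0e2}
  - {id: Ma, display_name: Ma, lineage: microglia, mode: quiescent, initial_value: 0}
  - {id: Mb, display_name: Mb, lineage: microglia, mode: activated, initial_value: 1.0e5}
pathways:
  - {id: 1, source: Mb, target: Rd, rate_name: k3, rate_value: %g, annotation: pathogenic, efficacy_tier: low}
', k3))
}

# Microglia pair only: one first-order conversion, no hazard, no stress.
microgliaPairToy <- function(k = 0.5) {
  loadModel(sprintf('
states:
  - {id: Ma, display_name: Ma, lineage: microglia, mode: quiescent, initial_value: 100}
  - {id: Mb, display_name: Mb, lineage: microglia, mode: activated, initial_value: 0}
pathways:
  - {id: 1, source: Ma, target: Mb, rate_name: k14, rate_value: %g, annotation: pathogenic, efficacy_tier: very_high}
', k))
}

# Default model pushed into the pathogenic regime: protective signalling
# cut so the one-hit hazard is strictly positive along the trajectory.
diseaseVariant <- function() {
  setRateValues(defaultModel(), c(k1 = 0.02, k17 = 0.02, k3 = 0.5))
}

# Brute-force partial correlation on ranks via the precision matrix,
# independent of the residualization route used by prcc().
prccOracle <- function(X, y) {
  R <- apply(cbind(y, X), 2, rank, ties.method = "average")
  S <- stats::cor(R)
  P <- solve(S)
  vapply(seq_len(ncol(X)), function(j) {
    -P[1, j + 1] / sqrt(P[1, 1] * P[j + 1, j + 1])
  }, numeric(1))
}
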