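# Local sensitivity coefficients Psi = d x(T) / d k by central finite
# differences with a +/-3% relative perturbation of each rate constant
# (the "+/-" of the published definition is read as the signed central
# difference; the sign carries the direction of change).

.stateAtHorizon <- function(model, horizon, lambda_degradation, opts) {
  sys <- buildRateSystem(model, lambda_degradation = lambda_degradation)
  o <- new("SolverOptions", method = opts@method, rel_tol = opts@rel_tol,
           abs_tol = opts@abs_tol, max_step = opts@max_step,
           output_grid = if (horizon > 0) c(0, horizon) else c(0, 1))
  traj <- simulateTrajectory(sys, opts = o)
  i <- if (horizon > 0) which(abs(traj@times - horizon) < 1e-9) else 1L
  trajectoryStates(traj)[i, ]
}

#' Local sensitivity coefficient of one output state to one rate constant
#'
#' \eqn{\Psi = [x(k(1+\delta), T) - x(k(1-\delta), T)] / (2\delta k)}
#' by two simulations of the perturbed model.  For a zero base rate the
#' relative perturbation is undefined; \code{absolute = TRUE} switches to
#' an absolute perturbation \eqn{k \pm \delta} (one-sided at \eqn{k = 0}
#' to respect rate nonnegativity).
#'
#' @param model a [NetworkModel-class].
#' @param rate_name rate constant to perturb (e.g. \code{"k12"}).
#' @param output_state output state id, including the bookkept dead pool.
#' @param horizon evaluation time T in years (default 20).
#' @param perturbation perturbation fraction delta (default 0.03), or the
#'   absolute per-year step when \code{absolute = TRUE}.
#' @param absolute use an absolute rather than relative perturbation.
#' @param lambda_degradation stress degradation passed to
#'   [buildRateSystem()].
#' @param opts a [SolverOptions-class] (its output grid is replaced by
#'   \code{c(0, horizon)}).
#' @return the sensitivity coefficient (output-state units per unit rate).
#' @export
localSensitivity <- function(model, rate_name, output_state, horizon = 20,
                             perturbation = 0.03, absolute = FALSE,
                             lambda_degradation = 0.5,
                             opts = solverOptions()) {
  k <- rateValues(model)
  if (!(rate_name %in% names(k))) stop("unknown rate: ", rate_name)
  k0 <- unname(k[rate_name])
  if (!absolute && k0 <= 0)
    stop("rate ", rate_name, " has zero base value; a relative ",
         "perturbation is undefined (use absolute = TRUE)")
  if (absolute) {
    lo <- max(0, k0 - perturbation)
    hi <- k0 + perturbation
  } else {
    lo <- k0 * (1 - perturbation)
    hi <- k0 * (1 + perturbation)
  }
  x_hi <- .stateAtHorizon(setRateValues(model, stats::setNames(hi, rate_name)),
                          horizon, lambda_degradation, opts)
  x_lo <- .stateAtHorizon(setRateValues(model, stats::setNames(lo, rate_name)),
                          horizon, lambda_degradation, opts)
  if (!(output_state %in% names(x_hi)))
    stop("unknown output state: ", output_state)
  unname((x_hi[output_state] - x_lo[output_state]) / (hi - lo))
}

#' Full local sensitivity matrix (all rates x all states)
#'
#' One [localSensitivity()] value per (rate constant, output state) pair at
#' the horizon; for the default model a 22 x 9 matrix.  The
#' \code{normalized} variant returns elasticities
#' \eqn{(k/x)\,\partial x/\partial k} (entries where \eqn{x(T) = 0} are set
#' to 0).
#'
#' @inheritParams localSensitivity
#' @param normalized return the dimensionless elasticity variant.
#' @return a [SensitivityResult-class].
#' @export
sensitivityMatrix <- function(model, horizon = 20, perturbation = 0.03,
                              normalized = FALSE, lambda_degradation = 0.5,
                              opts = solverOptions()) {
  k <- rateValues(model)
  sys <- buildRateSystem(model, lambda_degradation)
  out_states <- c(sys@state_ids,
                  if (nrow(sys@bookkept)) sys@bookkept$dead_id)
  # keep the model's own state order for columns
  out_states <- intersect(model@states$id, out_states)
  M <- matrix(NA_real_, length(k), length(out_states),
              dimnames = list(names(k), out_states))
  for (rn in names(k)) {
    k0 <- unname(k[rn])
    if (k0 > 0) {
      lo <- k0 * (1 - perturbation); hi <- k0 * (1 + perturbation)
    } else {
      lo <- 0; hi <- perturbation
    }
    x_hi <- .stateAtHorizon(setRateValues(model, stats::setNames(hi, rn)),
                            horizon, lambda_degradation, opts)
    x_lo <- .stateAtHorizon(setRateValues(model, stats::setNames(lo, rn)),
                            horizon, lambda_degradation, opts)
    M[rn, ] <- (x_hi[out_states] - x_lo[out_states]) / (hi - lo)
  }
  if (normalized) {
    x_base <- .stateAtHorizon(model, horizon, lambda_degradation, opts)
    for (rn in names(k)) {
      x0 <- x_base[out_states]
      el <- ifelse(x0 > 0, unname(k[rn]) * M[rn, ] / x0, 0)
      M[rn, ] <- el
    }
  }
  new("SensitivityResult", matrix = M, horizon = horizon,
      perturbation = perturbation, normalized = normalized)
}

#' Cluster a sensitivity matrix for heatmap display
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean
#' distance) on z-scored rows; columns are clustered the same way on the
#' transposed z-scored matrix.  Constant rows z-score to zero; an
#' all-constant matrix yields identity orderings with a warning.
#'
#' @param x a [SensitivityResult-class] or a numeric matrix.
#' @return list with \code{row_order}, \code{col_order} (1-based leaf
#'   orders), \code{matrix} (the z-scored matrix, original order) and the
#'   two \code{hclust} trees (\code{NULL} when degenerate or too small).
#' @export
clusterHeatmap <- function(x) {
  M <- if (is(x, "SensitivityResult")) x@matrix else as.matrix(x)
  if (any(!is.finite(M))) stop("matrix must be finite")
  zrow <- t(apply(M, 1, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  if (nrow(M) == 1) zrow <- matrix(zrow, nrow = 1,
                                   dimnames = dimnames(M))
  dimnames(zrow) <- dimnames(M)
  if (all(zrow == 0)) {
    warning("degenerate (constant) matrix: returning identity ordering")
    return(list(row_order = seq_len(nrow(M)), col_order = seq_len(ncol(M)),
                matrix = zrow, row_tree = NULL, col_tree = NULL))
  }
  order_of <- function(Z) {
    if (nrow(Z) < 2) return(list(order = seq_len(nrow(Z)), tree = NULL))
    hc <- stats::hclust(stats::dist(Z, method = "euclidean"),
                        method = "average")
    list(order = hc$order, tree = hc)
  }
  ro <- order_of(zrow)
  co <- order_of(t(zrow))
  list(row_order = ro$order, col_order = co$order, matrix = zrow,
       row_tree = ro$tree, col_tree = co$tree)
}

setMethod("show", "SensitivityResult", function(object) {
  cat(sprintf("SensitivityResult: %d rate(s) x %d state(s) at T = %g years (delta = %g%s)\n",
              nrow(object@matrix), ncol(object@matrix), object@horizon,
              object@perturbation,
              if (object@normalized) ", normalized" else ""))
  invisible(object)
})
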