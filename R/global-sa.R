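# Global sensitivity analysis: Latin hypercube sampling over the rate
# constants and time-resolved partial rank correlation coefficients (PRCC)
# against live-RGC density and stress (inflammation) buildup.

#' Default log-uniform sampling ranges for a model's rate constants
#'
#' One decade either side of each default value: \code{[k/10, 10 k]}.
#'
#' @param model a [NetworkModel-class] with strictly positive rates.
#' @return parameter x 2 matrix with columns \code{low}, \code{high}.
#' @export
defaultRanges <- function(model) {
  k <- rateValues(model)
  if (any(k <= 0))
    stop("default log-uniform ranges need strictly positive rates; ",
         "offending: ", paste(names(k)[k <= 0], collapse = ", "))
  cbind(low = k / 10, high = k * 10)
}

#' Draw a stratified Latin hypercube sample
#'
#' One sample per equal-probability stratum per parameter (on the log scale
#' for log-uniform ranges), via [lhs::randomLHS()] under a fixed seed.
#'
#' @param ranges parameter x 2 matrix (rownames = parameter names) of
#'   (low, high) bounds, e.g. [defaultRanges()].
#' @param n number of samples, >= 2.
#' @param seed integer RNG seed; the same seed reproduces the same design.
#' @param log_scale sample log-uniformly (default \code{TRUE}).
#' @return an [LHSDesign-class].
#' @export
lhsSample <- function(ranges, n, seed, log_scale = TRUE) {
  if (n < 2) stop("n must be >= 2")
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != 2 || any(ranges[, 1] >= ranges[, 2]))
    stop("ranges must be a parameter x 2 matrix with low < high")
  if (log_scale && any(ranges <= 0))
    stop("log-uniform sampling needs positive bounds")
  pn <- rownames(ranges)
  if (is.null(pn)) pn <- paste0("p", seq_len(nrow(ranges)))
  p <- nrow(ranges)
  u <- withr::with_seed(seed, lhs::randomLHS(n, p))
  samples <- matrix(NA_real_, n, p, dimnames = list(NULL, pn))
  for (j in seq_len(p)) {
    if (log_scale) {
      lo <- log(ranges[j, 1]); hi <- log(ranges[j, 2])
      samples[, j] <- exp(lo + u[, j] * (hi - lo))
    } else {
      samples[, j] <- ranges[j, 1] + u[, j] * (ranges[j, 2] - ranges[j, 1])
    }
  }
  new("LHSDesign", n = as.integer(n), parameter_names = pn,
      ranges = ranges, log_scale = log_scale, seed = as.integer(seed),
      samples = samples)
}

.rankAvg <- function(x) rank(x, ties.method = "average")

#' Partial rank correlation coefficients of a design against one output
#'
#' For parameter j: rank-transform all columns (average ranks for ties),
#' residualize the ranks of \eqn{x_j} and of the output on the ranks of the
#' other parameters by least squares, and take the Pearson correlation of
#' the two residual vectors.  Two-sided p-values use
#' \eqn{t = r\sqrt{(n - 2 - g)/(1 - r^2)}} on \eqn{n - 2 - g} degrees of
#' freedom, with \eqn{g} the number of co-adjusted parameters.
#'
#' @param samples n x p design matrix (columns named by parameter).
#' @param output numeric vector of length n.
#' @return data.frame with columns \code{parameter}, \code{prcc},
#'   \code{p_value}.
#' @export
prcc <- function(samples, output) {
  X <- as.matrix(samples)
  y <- as.numeric(output)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("output length must match the design")
  if (n <= p + 2) stop("need n > p + 2 samples for PRCC")
  if (stats::sd(y) == 0)
    stop("constant output: rank correlation undefined")
  const <- apply(X, 2, stats::sd) == 0
  if (any(const))
    stop("constant design column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  R <- apply(X, 2, .rankAvg)
  ry <- .rankAvg(y)
  g <- p - 1
  df <- n - 2 - g
  out <- data.frame(parameter = colnames(X), prcc = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    rx_res <- stats::lm.fit(Z, R[, j])$residuals
    ry_res <- stats::lm.fit(Z, ry)$residuals
    r <- suppressWarnings(stats::cor(rx_res, ry_res))
    if (!is.finite(r)) r <- 0
    r <- max(-1, min(1, r))
    out$prcc[j] <- r
    if (abs(r) >= 1) {
      out$p_value[j] <- 0
    } else {
      tstat <- r * sqrt(df / (1 - r^2))
      out$p_value[j] <- 2 * stats::pt(-abs(tstat), df)
    }
  }
  out
}

#' Time-resolved PRCC of a model's rates against RGC density and stress
#'
#' Simulates the model once per design row (rates replaced by the sampled
#' values), extracts the surviving-RGC and stress-pool series on the output
#' grid, and computes [prcc()] per output and time point.  Samples whose
#' simulation fails are excluded and counted.  Outputs that are constant
#' across samples at a time point (e.g. every state at t = 0) yield
#' \code{NA} coefficients and are never marked significant.
#'
#' @param model a [NetworkModel-class].
#' @param design an [LHSDesign-class] over (a subset of) the model's rates.
#' @param output_times output grid in years (default yearly 0..20).
#' @param lambda_degradation stress degradation for [buildRateSystem()].
#' @param opts a [SolverOptions-class]; its grid is replaced by
#'   \code{output_times}.
#' @param alpha significance threshold (default 0.01).
#' @return a [PRCCResult-class] with a parameter x output x time
#'   coefficient array (outputs \code{"Rs"} and \code{"Cs"}).
#' @export
timeResolvedPRCC <- function(model, design, output_times = 0:20,
                             lambda_degradation = 0.5,
                             opts = solverOptions(), alpha = 0.01) {
  stopifnot(is(design, "LHSDesign"))
  k_all <- rateValues(model)
  if (!all(design@parameter_names %in% names(k_all)))
    stop("design parameters not in model: ",
         paste(setdiff(design@parameter_names, names(k_all)),
               collapse = ", "))
  sys0 <- buildRateSystem(model, lambda_degradation)
  outputs <- c(sys0@bookkept$surviving_id[1], sys0@stress_id)
  outputs <- outputs[!is.na(outputs)]
  if (!length(outputs)) stop("model has neither RGC nor stress outputs")
  o <- new("SolverOptions", method = opts@method, rel_tol = opts@rel_tol,
           abs_tol = opts@abs_tol, max_step = opts@max_step,
           output_grid = as.numeric(output_times))
  nt <- length(output_times)
  n <- design@n
  sims <- array(NA_real_, c(n, length(outputs), nt))
  ok <- logical(n)
  for (i in seq_len(n)) {
    ki <- k_all
    ki[design@parameter_names] <- design@samples[i, ]
    res <- tryCatch({
      sys <- sys0
      sys@rate_values <- ki
      traj <- simulateTrajectory(sys, opts = o)
      traj@states[, outputs, drop = FALSE]
    }, error = function(e) NULL)
    if (!is.null(res)) {
      sims[i, , ] <- t(res)
      ok[i] <- TRUE
    }
  }
  n_ok <- sum(ok)
  if (n_ok <= ncol(design@samples) + 2)
    stop("too few successful simulations (", n_ok, ") for PRCC")
  X <- design@samples[ok, , drop = FALSE]
  p <- ncol(X)
  dn <- list(design@parameter_names, outputs, as.character(output_times))
  co <- array(NA_real_, c(p, length(outputs), nt), dimnames = dn)
  pv <- array(NA_real_, c(p, length(outputs), nt), dimnames = dn)
  for (oi in seq_along(outputs)) {
    for (ti in seq_len(nt)) {
      yv <- sims[ok, oi, ti]
      if (stats::sd(yv) == 0) next
      res <- prcc(X, yv)
      co[, oi, ti] <- res$prcc
      pv[, oi, ti] <- res$p_value
    }
  }
  sig <- !is.na(pv) & pv < alpha
  new("PRCCResult", coefficients = co, p_values = pv,
      n = as.integer(n_ok), n_failed = as.integer(n - n_ok),
      significant = sig, alpha = alpha)
}

setMethod("show", "LHSDesign", function(object) {
  cat(sprintf("LHSDesign: n = %d samples x %d parameter(s), %s scale, seed %d\n",
              object@n, length(object@parameter_names),
              if (object@log_scale) "log" else "linear", object@seed))
})

setMethod("show", "PRCCResult", function(object) {
  d <- dim(object@coefficients)
  cat(sprintf("PRCCResult: %d parameter(s) x %d output(s) x %d time point(s), n = %d (%d failed)\n",
              d[1], d[2], d[3], object@n, object@n_failed))
  cat(sprintf("  significant at p < %g: %d cell(s)\n", object@alpha,
              sum(object@significant)))
})
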