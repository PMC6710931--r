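#' Construct solver options
#'
#' @param method [deSolve::ode()] method; default \code{"ode45"}, an
#'   embedded adaptive Runge-Kutta pair with error control.
#' @param rel_tol,abs_tol error tolerances (defaults 1e-8, 1e-10).
#' @param max_step maximum step size in years (default unrestricted).
#' @param output_grid output times in years; default yearly 0..20.
#' @return a [SolverOptions-class].
#' @export
solverOptions <- function(method = "ode45", rel_tol = 1e-8,
                          abs_tol = 1e-10, max_step = Inf,
                          output_grid = 0:20) {
  new("SolverOptions", method = method, rel_tol = rel_tol,
      abs_tol = abs_tol, max_step = max_step,
      output_grid = as.numeric(output_grid))
}

#' Construct an intervention (rate scaling from an onset year)
#'
#' Models a treatment that multiplies selected rate constants by fixed
#' nonnegative factors from \code{onset} onwards (e.g. a microglial
#' activation inhibitor scaling \code{k12} and \code{k14} below 1).
#'
#' @param onset years >= 0.
#' @param multipliers named nonnegative factors keyed by rate name.
#' @return an [Intervention-class].
#' @export
intervention <- function(onset, multipliers) {
  new("Intervention", onset = as.numeric(onset),
      multipliers = multipliers)
}

.appliedRates <- function(system, interv) {
  k <- system@rate_values
  if (is.null(interv)) return(k)
  idx <- match(names(interv@multipliers), names(k))
  if (anyNA(idx))
    stop("intervention names unknown rate(s): ",
         paste(names(interv@multipliers)[is.na(idx)], collapse = ", "))
  k[idx] <- k[idx] * unname(interv@multipliers)
  k
}

.integrateSegment <- function(system, init, times, rates, opts) {
  if (length(times) == 1)
    return(matrix(init, nrow = 1, dimnames = list(NULL, names(init))))
  cs <- .compileSystem(system)
  kv <- unname(rates[names(system@rate_values)])
  rhs <- function(t, y, parms) list(.compiledDerivs(cs, y, parms))
  args <- list(y = unname(init), times = times, func = rhs, parms = kv,
               method = opts@method, rtol = opts@rel_tol,
               atol = opts@abs_tol)
  if (is.finite(opts@max_step)) args$hmax <- opts@max_step
  sol <- do.call(deSolve::ode, args)
  if (nrow(sol) < length(times)) {
    last_t <- sol[nrow(sol), 1]
    stop(sprintf("solver failed at t = %g years (last valid time)", last_t))
  }
  out <- sol[, -1, drop = FALSE]
  colnames(out) <- system@state_ids
  # Clip integrator undershoot; anything beyond tolerance is a real failure.
  low <- min(out)
  if (low < -opts@abs_tol * 10)
    stop(sprintf("state went negative beyond tolerance (min = %g)", low))
  out[out < 0] <- 0
  out
}

#' Integrate a rate system over the output grid
#'
#' Produces a [Trajectory-class] with the integrated dynamical states, the
#' conservation-derived dead-RGC series and the dead/surviving progression
#' ratio.  An [Intervention-class] is applied as piecewise-constant rate
#' scaling with an integration restart at the onset breakpoint, so the
#' discontinuity never falls inside an adaptive step.
#'
#' @param system a [RateSystem-class].
#' @param init named nonnegative initial values for the dynamical states;
#'   defaults to the model's initial values.
#' @param opts a [SolverOptions-class].
#' @param intervention an [Intervention-class] or \code{NULL}.
#' @return a [Trajectory-class].
#' @examples
#' traj <- simulateTrajectory(buildRateSystem(defaultModel()))
#' progressionRatio(traj, 0)  # 0.01 = Rd(0)/Rs(0)
#' @export
simulateTrajectory <- function(system, init = NULL, opts = solverOptions(),
                               intervention = NULL) {
  validObject(opts)
  if (is.null(init)) init <- system@init
  if (is.null(names(init))) names(init) <- system@state_ids
  init <- init[system@state_ids]
  if (anyNA(init)) stop("init must cover all dynamical states")
  if (any(init < 0)) stop("init must be nonnegative")
  grid <- opts@output_grid
  k0 <- system@rate_values

  if (is.null(intervention) || intervention@onset <= grid[1]) {
    rates <- .appliedRates(system, intervention)
    out <- .integrateSegment(system, init, grid, rates, opts)
  } else {
    onset <- intervention@onset
    t1 <- sort(unique(c(grid[grid <= onset], onset)))
    t2 <- sort(unique(c(onset, grid[grid > onset])))
    seg1 <- .integrateSegment(system, init, t1, k0, opts)
    init2 <- seg1[nrow(seg1), ]
    seg2 <- .integrateSegment(system, init2, t2,
                              .appliedRates(system, intervention), opts)
    keep1 <- t1 %in% grid
    keep2 <- t2 %in% grid & t2 > onset |
      (t2 %in% grid & t2 == onset & !(onset %in% t1[keep1]))
    out <- rbind(seg1[keep1, , drop = FALSE], seg2[keep2, , drop = FALSE])
  }

  bk <- system@bookkept
  if (nrow(bk) == 1) {
    dead <- bk$total - out[, bk$surviving_id]
    surv <- out[, bk$surviving_id]
    ratio <- ifelse(surv > 0, dead / surv, Inf)
  } else {
    dead <- rep(NA_real_, nrow(out))
    ratio <- rep(NA_real_, nrow(out))
  }
  new("Trajectory", times = grid, states = out,
      dead_rgc = unname(dead),
      dead_id = if (nrow(bk) == 1) bk$dead_id else NA_character_,
      progression_ratio = unname(ratio))
}

#' Dead/surviving RGC ratio at a time point
#'
#' The model's surrogate for the rate of glaucoma progression.  A depleted
#' surviving pool is signalled as an infinite-progression condition
#' (\code{Inf} with a warning), not an error.
#'
#' @param traj a [Trajectory-class].
#' @param t a time present in \code{traj@times}.
#' @return dimensionless ratio, non-decreasing in \code{t}.
#' @export
progressionRatio <- function(traj, t) {
  i <- which(abs(traj@times - t) < 1e-9)
  if (length(i) != 1)
    stop("t = ", t, " is not an output time of the trajectory")
  r <- traj@progression_ratio[i]
  if (is.infinite(r))
    warning("surviving RGC pool exhausted: infinite progression ratio")
  r
}

#' @describeIn Trajectory-class time x state matrix including the bookkept
#'   dead pool as column \code{Rd} (when present).
#' @param traj,object a \code{Trajectory}.
#' @export
trajectoryStates <- function(traj) {
  out <- traj@states
  if (!is.na(traj@dead_id)) {
    out <- cbind(out, traj@dead_rgc)
    colnames(out)[ncol(out)] <- traj@dead_id
  }
  out
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%g, %g] years, %d state(s)\n",
              length(object@times), min(object@times), max(object@times),
              ncol(object@states)))
  if (!all(is.na(object@progression_ratio)))
    cat(sprintf("  progression ratio: %.4g -> %.4g\n",
                object@progression_ratio[1],
                object@progression_ratio[length(object@times)]))
})
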