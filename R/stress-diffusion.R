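# 1-D reaction-diffusion of the cellular-stress field:
#   dC/dt = D d2C/dx2 + pi - lambda C
# on [0, L] with zero-flux (ghost-node) boundaries, solved by the method of
# lines with central second differences.  With the trapezoid quadrature
# weights (half-weight end nodes) the discrete Laplacian is exactly
# conservative, so with lambda = 0 the domain integral grows by exactly
# t * integral(pi).

#' Construct stress reaction-diffusion parameters
#'
#' @param production pi, stressor units per year; a scalar (uniform) or one
#'   value per node.
#' @param degradation lambda, per year.
#' @param diffusion D, length^2 per year.
#' @param domain_length length of the 1-D interval (default 1).
#' @param n_nodes number of grid nodes (default 101).
#' @return a [StressParams-class].
#' @export
stressParams <- function(production, degradation, diffusion,
                         domain_length = 1, n_nodes = 101L) {
  new("StressParams", production = as.numeric(production),
      degradation = as.numeric(degradation),
      diffusion = as.numeric(diffusion),
      domain_length = as.numeric(domain_length),
      n_nodes = as.integer(n_nodes))
}

.stressGrid <- function(params) {
  seq(0, params@domain_length, length.out = params@n_nodes)
}

.laplacianTimes <- function(C, dx) {
  n <- length(C)
  # ghost nodes: C[0] = C[2], C[n+1] = C[n-1] (zero flux)
  up <- c(C[2], C[seq_len(n - 1)])
  down <- c(C[-1], C[n - 1])
  (up - 2 * C + down) / dx^2
}

#' Solve the stress reaction-diffusion equation
#'
#' Method-of-lines solution of
#' \eqn{\partial C/\partial t = D\,\partial^2 C/\partial x^2 + \pi -
#' \lambda C} with central second differences and zero-flux ghost-node
#' boundaries.
#'
#' @param params a [StressParams-class].
#' @param init_field nonnegative initial concentrations, one per node (a
#'   scalar is recycled).
#' @param horizon final time in years.
#' @param output_times output times (default yearly \code{0:horizon}).
#' @param method \code{"adaptive"} (default; stiff-capable \code{lsoda})
#'   or \code{"explicit"} (fixed-step RK4; errors out when the step
#'   violates the diffusive CFL stability bound).
#' @param dt fixed step for the explicit method (years).
#' @param rel_tol,abs_tol adaptive-solver tolerances.
#' @return a [StressField-class].
#' @export
solveStressPDE <- function(params, init_field, horizon,
                           output_times = NULL,
                           method = c("adaptive", "explicit"),
                           dt = NULL, rel_tol = 1e-8, abs_tol = 1e-10) {
  method <- match.arg(method)
  validObject(params)
  n <- params@n_nodes
  if (length(init_field) == 1) init_field <- rep(init_field, n)
  if (length(init_field) != n)
    stop("init_field must have one value per node")
  if (any(init_field < 0)) stop("init_field must be nonnegative")
  if (is.null(output_times)) output_times <- seq(0, horizon, by = 1)
  grid <- .stressGrid(params)
  dx <- grid[2] - grid[1]
  prod <- if (length(params@production) == 1)
    rep(params@production, n) else params@production
  rhs <- function(t, C, parms) {
    list(params@diffusion * .laplacianTimes(C, dx) + prod -
           params@degradation * C)
  }
  if (method == "explicit") {
    if (is.null(dt)) dt <- min(diff(output_times)) / 10
    if (params@diffusion > 0 && dt > dx^2 / (2 * params@diffusion))
      stop("explicit step dt = ", dt, " violates the CFL stability bound ",
           "dx^2/(2D) = ", dx^2 / (2 * params@diffusion),
           "; reduce dt or use method = 'adaptive'")
    sol <- deSolve::ode(y = init_field, times = output_times, func = rhs,
                        parms = NULL, method = "rk4", hini = dt)
  } else {
    sol <- deSolve::ode(y = init_field, times = output_times, func = rhs,
                        parms = NULL, method = "lsoda", rtol = rel_tol,
                        atol = abs_tol)
  }
  vals <- sol[, -1, drop = FALSE]
  vals[vals < 0 & vals > -abs_tol * 10] <- 0
  if (any(vals < 0))
    stop("stress field went negative beyond tolerance")
  dimnames(vals) <- NULL
  new("StressField", times = output_times, grid = grid, values = vals)
}

#' Steady state of the stress equation
#'
#' Solves the linear steady problem
#' \eqn{0 = D\,\partial^2 C/\partial x^2 + \pi - \lambda C} with zero-flux
#' boundaries.  For uniform production this is \eqn{\pi/\lambda} at every
#' node.  Requires \eqn{\lambda > 0}; with no degradation and nonzero
#' production there is no steady state.
#'
#' @param params a [StressParams-class].
#' @return per-node steady concentrations.
#' @export
stressSteadyState <- function(params) {
  validObject(params)
  if (params@degradation <= 0)
    stop("no steady state: degradation (lambda) must be > 0")
  n <- params@n_nodes
  grid <- .stressGrid(params)
  dx <- grid[2] - grid[1]
  prod <- if (length(params@production) == 1)
    rep(params@production, n) else params@production
  # (lambda I - D L) c = pi, with the ghost-node Laplacian L
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    L[i, i] <- -2 / dx^2
    iu <- if (i == 1) 2 else i - 1
    id <- if (i == n) n - 1 else i + 1
    L[i, iu] <- L[i, iu] + 1 / dx^2
    L[i, id] <- L[i, id] + 1 / dx^2
  }
  A <- diag(params@degradation, n) - params@diffusion * L
  as.numeric(solve(A, prod))
}

#' Conservative domain total of a stress field
#'
#' Trapezoid-weighted integral of the concentration over the domain at each
#' output time; with zero degradation and zero-flux boundaries this grows
#' by exactly the integrated production.
#'
#' @param field a [StressField-class].
#' @return numeric vector, one total per time point.
#' @export
domainTotal <- function(field) {
  dx <- field@grid[2] - field@grid[1]
  w <- rep(dx, length(field@grid))
  w[c(1, length(w))] <- dx / 2
  as.numeric(field@values %*% w)
}

setMethod("show", "StressField", function(object) {
  cat(sprintf("StressField: %d time(s) x %d node(s) on [0, %g]\n",
              length(object@times), length(object@grid),
              max(object@grid)))
  cat(sprintf("  final mean concentration: %.6g\n",
              mean(object@values[nrow(object@values), ])))
})
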