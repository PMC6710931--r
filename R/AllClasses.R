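#' @import methods
NULL

LINEAGES <- c("rgc", "astroglia", "microglia", "mueller", "stress")
MODES <- c("surviving", "dead", "quiescent", "activated", "stress_pool")
ANNOTATIONS <- c("homeostatic", "pathogenic")
EFFICACY_TIERS <- c("very_high", "moderate", "low")
TERM_KINDS <- c("conversion", "catalyzed_conversion", "protective_hazard",
                "harmful_hazard", "stress_production")

#' NetworkModel: a declarative neuron-glia kinetic network
#'
#' Holds the cell states (paired quiescent/activated glia, surviving/dead
#' retinal ganglion cells, and a lumped stress pool), the directed pathways
#' with per-year rate constants, and an optional reference sensitivity table.
#'
#' @slot states data.frame with columns \code{id}, \code{display_name},
#'   \code{lineage}, \code{mode}, \code{initial_value}.
#' @slot pathways data.frame with columns \code{id}, \code{source},
#'   \code{target}, \code{rate_name}, \code{rate_value}, \code{annotation},
#'   \code{efficacy_tier}.
#' @slot reference_sensitivity numeric matrix of dimensionless reference
#'   sensitivity values with state ids as dimnames (possibly 0 x 0).
#' @slot metadata named list of free-form metadata.
#'
#' @seealso [loadModel()], [validateModel()], [defaultModel()]
#' @export
setClass("NetworkModel",
  representation(
    states = "data.frame",
    pathways = "data.frame",
    reference_sensitivity = "matrix",
    metadata = "list"
  ),
  prototype(
    states = data.frame(),
    pathways = data.frame(),
    reference_sensitivity = matrix(numeric(0), 0, 0),
    metadata = list()
  )
)

# Structural validity only: column presence and types. Domain invariants
# (pairings, uniqueness, nonnegativity) are reported by validateModel() so
# that deliberately broken models can be constructed and inspected.
setValidity("NetworkModel", function(object) {
  msg <- character(0)
  st_cols <- c("id", "display_name", "lineage", "mode", "initial_value")
  pw_cols <- c("id", "source", "target", "rate_name", "rate_value",
               "annotation", "efficacy_tier")
  if (nrow(object@states) > 0 && !all(st_cols %in% names(object@states)))
    msg <- c(msg, paste("states must have columns:",
                        paste(st_cols, collapse = ", ")))
  if (nrow(object@pathways) > 0 && !all(pw_cols %in% names(object@pathways)))
    msg <- c(msg, paste("pathways must have columns:",
                        paste(pw_cols, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ValidationReport: result of model validation
#'
#' @slot ok logical; \code{TRUE} iff no issue of severity \code{"error"}.
#' @slot issues data.frame with columns \code{severity} and \code{message}.
#' @export
setClass("ValidationReport",
  representation(ok = "logical", issues = "data.frame"),
  prototype(ok = TRUE,
            issues = data.frame(severity = character(0),
                                message = character(0)))
)

setValidity("ValidationReport", function(object) {
  has_err <- any(object@issues$severity == "error")
  if (identical(object@ok, !has_err)) TRUE
  else "'ok' must be TRUE iff there is no issue of severity 'error'"
})

#' RateSystem: reconstructed kinetic right-hand side
#'
#' The typed kinetic terms derived from a [NetworkModel-class]: one
#' first-order or catalyzed conversion, hazard contribution, or stress
#' production term per pathway, plus first-order stress degradation.  Dead
#' pools are bookkept by conservation rather than integrated, so the default
#' 9-state model yields 7 cell-population equations plus 1 stress equation.
#'
#' @slot state_ids ordered ids of the dynamical (integrated) states.
#' @slot terms data.frame of typed terms (one row per pathway):
#'   \code{pathway_id}, \code{rate_name}, \code{kind}, \code{catalyst},
#'   \code{substrate}, \code{product}, \code{normalization}.
#' @slot rate_values named per-year rate constants.
#' @slot lambda_degradation per-year first-order degradation of the stress
#'   pool.
#' @slot init named initial values of the dynamical states.
#' @slot bookkept data.frame of conservation-bookkept dead pools:
#'   \code{dead_id}, \code{surviving_id}, \code{total} (lineage total at
#'   t = 0).
#' @slot stress_id id of the stress pool (\code{NA} if absent) and
#' @slot stress_init its initial value (normalization scale).
#' @slot lineages named character vector mapping state id to lineage.
#' @export
setClass("RateSystem",
  representation(
    state_ids = "character",
    terms = "data.frame",
    rate_values = "numeric",
    lambda_degradation = "numeric",
    init = "numeric",
    bookkept = "data.frame",
    stress_id = "character",
    stress_init = "numeric",
    lineages = "character"
  )
)

setValidity("RateSystem", function(object) {
  msg <- character(0)
  if (length(object@lambda_degradation) != 1 || object@lambda_degradation < 0)
    msg <- c(msg, "lambda_degradation must be a single nonnegative number")
  if (!all(object@terms$kind %in% TERM_KINDS))
    msg <- c(msg, "unknown term kind")
  if (any(object@terms$normalization <= 0))
    msg <- c(msg, "term normalizations must be positive")
  if (!identical(names(object@init), object@state_ids))
    msg <- c(msg, "init must be named by state_ids in order")
  if (length(msg)) msg else TRUE
})

#' SolverOptions: adaptive integrator settings
#'
#' @slot method integration method passed to [deSolve::ode()]; the default
#'   \code{"ode45"} is an embedded adaptive Runge-Kutta pair.
#' @slot rel_tol,abs_tol relative/absolute error tolerances.
#' @slot max_step maximum step size in years (\code{Inf} = unrestricted).
#' @slot output_grid strictly increasing output times in years starting at 0.
#' @export
setClass("SolverOptions",
  representation(method = "character", rel_tol = "numeric",
                 abs_tol = "numeric", max_step = "numeric",
                 output_grid = "numeric")
)

setValidity("SolverOptions", function(object) {
  msg <- character(0)
  if (object@rel_tol <= 0 || object@abs_tol <= 0)
    msg <- c(msg, "tolerances must be > 0")
  g <- object@output_grid
  if (length(g) < 2 || g[1] != 0 || any(diff(g) <= 0))
    msg <- c(msg, "output_grid must be strictly increasing and start at 0")
  if (length(msg)) msg else TRUE
})

#' Intervention: piecewise-constant rate scaling from an onset year
#'
#' @slot onset years (>= 0) at which the multipliers take effect.
#' @slot multipliers named nonnegative factors applied to rate constants for
#'   t >= onset.
#' @export
setClass("Intervention",
  representation(onset = "numeric", multipliers = "numeric")
)

setValidity("Intervention", function(object) {
  msg <- character(0)
  if (length(object@onset) != 1 || object@onset < 0)
    msg <- c(msg, "onset must be a single year >= 0")
  if (length(object@multipliers) &&
      (is.null(names(object@multipliers)) || any(object@multipliers < 0)))
    msg <- c(msg, "multipliers must be named and nonnegative")
  if (length(msg)) msg else TRUE
})

#' Trajectory: integrated time course with derived RGC series
#'
#' @slot times output times in years.
#' @slot states time x dynamical-state matrix (columns named by state id).
#' @slot dead_rgc derived dead-RGC series (conservation bookkeeping).
#' @slot dead_id id of the bookkept dead pool (\code{NA} if none).
#' @slot progression_ratio dead/surviving RGC ratio per time point (the
#'   model's glaucoma-progression surrogate).
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix",
                 dead_rgc = "numeric", dead_id = "character",
                 progression_ratio = "numeric")
)

#' SensitivityResult: local sensitivity coefficients
#'
#' Matrix of coefficients \eqn{\Psi = \partial x(T) / \partial k} estimated
#' by central finite differences with a relative perturbation of each rate
#' constant.
#'
#' @slot matrix rate-constant x output-state matrix of coefficients.
#' @slot horizon evaluation horizon T in years.
#' @slot perturbation relative perturbation fraction (default 0.03).
#' @slot normalized logical; \code{TRUE} for the elasticity variant
#'   \eqn{(k/x)\,\partial x/\partial k}.
#' @export
setClass("SensitivityResult",
  representation(matrix = "matrix", horizon = "numeric",
                 perturbation = "numeric", normalized = "logical")
)

setValidity("SensitivityResult", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@matrix)))
    msg <- c(msg, "sensitivity entries must be finite")
  if (object@perturbation <= 0 || object@perturbation >= 0.5)
    msg <- c(msg, "perturbation must lie in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' LHSDesign: stratified Latin hypercube sample of rate constants
#'
#' @slot n number of samples (one per stratum per parameter).
#' @slot parameter_names sampled rate names.
#' @slot ranges parameter x 2 matrix of (low, high) bounds.
#' @slot log_scale logical; \code{TRUE} for log-uniform sampling.
#' @slot seed integer RNG seed used to draw the design.
#' @slot samples n x parameter matrix of sampled values.
#' @export
setClass("LHSDesign",
  representation(n = "integer", parameter_names = "character",
                 ranges = "matrix", log_scale = "logical",
                 seed = "integer", samples = "matrix")
)

setValidity("LHSDesign", function(object) {
  msg <- character(0)
  if (!all(object@ranges[, 1] < object@ranges[, 2]))
    msg <- c(msg, "each range must satisfy low < high")
  if (nrow(object@samples) != object@n ||
      ncol(object@samples) != length(object@parameter_names))
    msg <- c(msg, "samples must be n x length(parameter_names)")
  if (length(msg)) msg else TRUE
})

#' PRCCResult: time-resolved partial rank correlation coefficients
#'
#' @slot coefficients parameter x output x time array of PRCC values in
#'   [-1, 1] (\code{NA} where an output is constant at a time point).
#' @slot p_values same shape; two-sided p-values from the t approximation.
#' @slot n number of usable samples.
#' @slot n_failed number of samples excluded because simulation failed.
#' @slot significant logical mask \code{p < alpha} (\code{FALSE} where
#'   undefined).
#' @slot alpha significance threshold (default 0.01).
#' @export
setClass("PRCCResult",
  representation(coefficients = "array", p_values = "array", n = "integer",
                 n_failed = "integer", significant = "array",
                 alpha = "numeric")
)

setValidity("PRCCResult", function(object) {
  msg <- character(0)
  cc <- object@coefficients
  if (any(abs(cc[is.finite(cc)]) > 1 + 1e-12))
    msg <- c(msg, "coefficients must lie in [-1, 1]")
  pp <- object@p_values
  if (any(pp[is.finite(pp)] < 0 | pp[is.finite(pp)] > 1))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' StressParams: parameters of the stress reaction-diffusion equation
#'
#' The cellular-stress field obeys
#' \eqn{\partial C/\partial t = D \partial^2 C/\partial x^2 + \pi - \lambda C}
#' on a 1-D interval with zero-flux boundaries.
#'
#' @slot production pi: stressor units per year, scalar (uniform) or one
#'   value per node.
#' @slot degradation lambda: per-year first-order removal, >= 0.
#' @slot diffusion D: length^2 per year, >= 0.
#' @slot domain_length length of the 1-D domain (> 0).
#' @slot n_nodes number of grid nodes (>= 2).
#' @export
setClass("StressParams",
  representation(production = "numeric", degradation = "numeric",
                 diffusion = "numeric", domain_length = "numeric",
                 n_nodes = "integer")
)

setValidity("StressParams", function(object) {
  msg <- character(0)
  if (any(object@production < 0)) msg <- c(msg, "production must be >= 0")
  if (object@degradation < 0) msg <- c(msg, "degradation must be >= 0")
  if (object@diffusion < 0) msg <- c(msg, "diffusion must be >= 0")
  if (object@domain_length <= 0) msg <- c(msg, "domain_length must be > 0")
  if (object@n_nodes < 2L) msg <- c(msg, "n_nodes must be >= 2")
  np <- length(object@production)
  if (np != 1 && np != object@n_nodes)
    msg <- c(msg, "production must be scalar or one value per node")
  if (length(msg)) msg else TRUE
})

#' StressField: spatially resolved stress concentration
#'
#' @slot times output times in years.
#' @slot grid node positions.
#' @slot values time x node matrix of concentrations (>= 0).
#' @export
setClass("StressField",
  representation(times = "numeric", grid = "numeric", values = "matrix")
)

setValidity("StressField", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@times) ||
      ncol(object@values) != length(object@grid))
    msg <- c(msg, "values must be length(times) x length(grid)")
  if (length(msg)) msg else TRUE
})

#' ObservationSet: noisy simulated observations with recorded truth
#'
#' @slot times observation times in years.
#' @slot observed time x state matrix (dynamical states plus the bookkept
#'   dead pool), multiplicative-noise corrupted, clipped at 0.
#' @slot noise_sd relative noise standard deviation.
#' @slot seed RNG seed used to draw the noise.
#' @slot truth named generating rate values (for recovery scoring).
#' @export
setClass("ObservationSet",
  representation(times = "numeric", observed = "matrix",
                 noise_sd = "numeric", seed = "integer", truth = "numeric")
)
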