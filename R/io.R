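# Result serialization, config hashing, and run manifests.

#' Write a trajectory to CSV or JSON
#'
#' CSV uses the canonical header
#' \code{time_years,<states...>,<dead pool>,progression_ratio}.  JSON adds a
#' metadata block (seed, config hash, solver options) alongside the data.
#'
#' @param traj a [Trajectory-class].
#' @param file output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param metadata optional named list stored in the JSON variant.
#' @return invisibly \code{file}.
#' @export
writeTrajectory <- function(traj, file, format = c("csv", "json"),
                            metadata = list()) {
  format <- match.arg(format)
  df <- data.frame(time_years = traj@times,
                   trajectoryStates(traj),
                   progression_ratio = traj@progression_ratio,
                   check.names = FALSE)
  if (format == "csv") {
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(metadata = metadata, trajectory = df),
                         file, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(file)
}

#' Write a sensitivity matrix to CSV (rates as rows, states as columns)
#'
#' @param result a [SensitivityResult-class].
#' @param file output path.
#' @return invisibly \code{file}.
#' @export
writeSensitivity <- function(result, file) {
  df <- data.frame(rate_name = rownames(result@matrix), result@matrix,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a PRCC result in long format
#'
#' Columns: \code{parameter,output,time_years,prcc,p_value,significant}.
#'
#' @param result a [PRCCResult-class].
#' @param file output path.
#' @return invisibly \code{file}.
#' @export
writePRCC <- function(result, file) {
  dn <- dimnames(result@coefficients)
  grid <- expand.grid(parameter = dn[[1]], output = dn[[2]],
                      time_years = as.numeric(dn[[3]]),
                      stringsAsFactors = FALSE)
  grid$prcc <- as.vector(result@coefficients)
  grid$p_value <- as.vector(result@p_values)
  grid$significant <- as.vector(result@significant)
  utils::write.csv(grid, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write an LHS design matrix with its seed in a metadata header line
#'
#' @param design an [LHSDesign-class].
#' @param file output path.
#' @return invisibly \code{file}.
#' @export
writeDesign <- function(design, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d; n: %d; scale: %s", design@seed, design@n,
                     if (design@log_scale) "log" else "linear"), con)
  utils::write.csv(as.data.frame(design@samples), con, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Write a stress field in long format
#'
#' Columns: \code{time_years,x,concentration}.
#'
#' @param field a [StressField-class].
#' @param file output path.
#' @return invisibly \code{file}.
#' @export
writeStressField <- function(field, file) {
  df <- expand.grid(x = field@grid, time_years = field@times)
  df <- df[, c("time_years", "x")]
  df$concentration <- as.vector(t(field@values))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write / read an observation set (CSV + JSON sidecar)
#'
#' The CSV mirrors the trajectory format; the sidecar
#' (\code{<file>.meta.json}) records seed, noise_sd and the generating
#' truth.
#'
#' @param observations an [ObservationSet-class].
#' @param file CSV output path.
#' @return invisibly \code{file}.
#' @export
writeObservations <- function(observations, file) {
  df <- data.frame(time_years = observations@times, observations@observed,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = observations@seed,
                            noise_sd = observations@noise_sd,
                            truth = as.list(observations@truth)),
                       paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writeObservations
#' @param file CSV path written by \code{writeObservations}.
#' @export
readObservations <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  meta <- jsonlite::fromJSON(paste0(file, ".meta.json"))
  obs <- as.matrix(df[, -1, drop = FALSE])
  new("ObservationSet", times = df$time_years, observed = obs,
      noise_sd = as.numeric(meta$noise_sd), seed = as.integer(meta$seed),
      truth = unlist(meta$truth))
}

#' MD5 hash of a configuration text or file
#'
#' @param x configuration text (or a path to a file).
#' @return hex digest string.
#' @export
configHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (!grepl("\n", x) && file.exists(x))
    return(unname(tools::md5sum(x)))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(x, tmp)
  unname(tools::md5sum(tmp))
}

#' Build a run manifest for result provenance
#'
#' @param command the (sub)command being run.
#' @param seed integer seed in effect.
#' @param config_hash hash of the resolved configuration ([configHash()]).
#' @return named list with timestamps and package version.
#' @export
runManifest <- function(command, seed = NA_integer_, config_hash = NA) {
  list(command = command, seed = seed, config_hash = config_hash,
       started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version =
         as.character(utils::packageVersion("RGCglia")))
}

#' Resolve run settings from defaults, a config file, and overrides
#'
#' Precedence (lowest to highest): package defaults, values from the
#' optional YAML/JSON settings file, explicit overrides (e.g. parsed
#' command-line flags).
#'
#' @param overrides named list of explicit settings.
#' @param config_path optional path to a YAML/JSON settings file.
#' @param defaults named list of defaults (see source for the standard
#'   set: model path, horizon 20, lambda 0.5, seed 1, n 200,
#'   perturbation 0.03).
#' @return named list of fully resolved settings.
#' @export
resolveRunSettings <- function(overrides = list(), config_path = NULL,
                               defaults = list(
                                 model = system.file("extdata",
                                                     "glaucoma22.yaml",
                                                     package = "RGCglia"),
                                 horizon = 20, lambda = 0.5, seed = 1L,
                                 n = 200L, perturbation = 0.03)) {
  settings <- defaults
  if (!is.null(config_path)) {
    if (!file.exists(config_path))
      stop("settings file not found: ", config_path)
    fromfile <- if (grepl("\\.json$", config_path, ignore.case = TRUE))
      jsonlite::fromJSON(config_path, simplifyVector = TRUE)
    else yaml::yaml.load_file(config_path)
    for (nm in names(fromfile)) settings[[nm]] <- fromfile[[nm]]
  }
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) settings[[nm]] <- overrides[[nm]]
  settings
}
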