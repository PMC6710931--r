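#' Load a network model from a YAML or JSON configuration
#'
#' Parses a declarative model configuration into a [NetworkModel-class].
#' The configuration has top-level keys \code{states}, \code{pathways},
#' optional \code{reference_sensitivity} (keys \code{order} and \code{rows})
#' and optional \code{metadata}.  State and pathway order is preserved.
#' The parsed model is validated with [validateModel()]; any issue of
#' severity \code{"error"} aborts the load and names the offending record.
#'
#' @param x path to a configuration file, or a single string containing the
#'   configuration text itself.
#' @param format \code{"auto"} (default; decided by file extension or a
#'   leading \code{"\{"}), \code{"yaml"} or \code{"json"}.  YAML parsing
#'   accepts JSON input, so the distinction only matters for explicitness.
#' @return a validated [NetworkModel-class].
#' @examples
#' m <- defaultModel()
#' nrow(pathways(m))  # 22
#' @export
loadModel <- function(x, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  stopifnot(is.character(x), length(x) == 1)
  is_file <- !grepl("\n", x) && file.exists(x)
  txt <- if (is_file) paste(readLines(x, warn = FALSE), collapse = "\n") else x
  if (format == "auto") {
    format <- if (is_file && grepl("\\.json$", x, ignore.case = TRUE)) "json"
              else if (!is_file && grepl("^\\s*\\{", txt)) "json"
              else "yaml"
  }
  cfg <- tryCatch(
    if (format == "json") jsonlite::fromJSON(txt, simplifyVector = FALSE)
    else yaml::yaml.load(txt),
    error = function(e) stop("malformed model configuration: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(cfg) || is.null(cfg$states))
    stop("malformed model configuration: missing 'states'", call. = FALSE)

  pick <- function(rec, key, default = NA) {
    v <- rec[[key]]
    if (is.null(v)) default else v
  }
  states <- do.call(rbind, lapply(cfg$states, function(s) {
    data.frame(id = as.character(pick(s, "id")),
               display_name = as.character(pick(s, "display_name",
                                                pick(s, "id"))),
               lineage = as.character(pick(s, "lineage")),
               mode = as.character(pick(s, "mode")),
               initial_value = as.numeric(pick(s, "initial_value")),
               stringsAsFactors = FALSE)
  }))
  pathways <- if (length(cfg$pathways)) {
    do.call(rbind, lapply(cfg$pathways, function(p) {
      data.frame(id = as.integer(pick(p, "id")),
                 source = as.character(pick(p, "source")),
                 target = as.character(pick(p, "target")),
                 rate_name = as.character(pick(p, "rate_name")),
                 rate_value = as.numeric(pick(p, "rate_value")),
                 annotation = as.character(pick(p, "annotation")),
                 efficacy_tier = as.character(pick(p, "efficacy_tier")),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id = integer(0), source = character(0), target = character(0),
               rate_name = character(0), rate_value = numeric(0),
               annotation = character(0), efficacy_tier = character(0),
               stringsAsFactors = FALSE)
  }
  ref <- matrix(numeric(0), 0, 0)
  if (!is.null(cfg$reference_sensitivity)) {
    rs <- cfg$reference_sensitivity
    ord <- as.character(unlist(rs$order))
    rows <- rs$rows
    ref <- t(vapply(ord, function(s) as.numeric(unlist(rows[[s]])),
                    numeric(length(ord))))
    dimnames(ref) <- list(ord, ord)
  }
  metadata <- if (is.null(cfg$metadata)) list() else cfg$metadata

  model <- new("NetworkModel", states = states, pathways = pathways,
               reference_sensitivity = ref, metadata = metadata)
  rep <- validateModel(model)
  if (!rep@ok) {
    errs <- rep@issues$message[rep@issues$severity == "error"]
    stop("invalid model configuration:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  model
}

#' The packaged default 22-pathway glaucoma model
#'
#' Loads the packaged configuration: 8 cell species (4 lineage pairs) plus
#' one stress pool, 22 directed pathways with tiered per-year rate
#' constants, and the published reference sensitivity table.
#'
#' @return a [NetworkModel-class] with 9 states and 22 pathways.
#' @export
defaultModel <- function() {
  loadModel(system.file("extdata", "glaucoma22.yaml", package = "RGCglia"))
}

#' Serialize a network model back to configuration text
#'
#' Inverse of [loadModel()]: \code{loadModel(serializeModel(m))} reproduces
#' states, pathways and values exactly.
#'
#' @param model a [NetworkModel-class].
#' @param format \code{"yaml"} (default) or \code{"json"}.
#' @return a single configuration string.
#' @export
serializeModel <- function(model, format = c("yaml", "json")) {
  format <- match.arg(format)
  df_to_records <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  cfg <- list(metadata = model@metadata,
              states = df_to_records(model@states),
              pathways = df_to_records(model@pathways))
  if (length(model@reference_sensitivity)) {
    ref <- model@reference_sensitivity
    rows <- lapply(seq_len(nrow(ref)), function(i) unname(ref[i, ]))
    names(rows) <- rownames(ref)
    cfg$reference_sensitivity <- list(order = rownames(ref), rows = rows)
  }
  if (format == "json")
    as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  else
    yaml::as.yaml(cfg, precision = 15)
}

#' Validate a network model against its domain invariants
#'
#' Checks, without raising: id uniqueness; lineage/mode vocabulary; that
#' every non-stress lineage present is a complementary pair of exactly two
#' states and the stress lineage (if present) a single positive-valued pool;
#' nonnegative initial values; pathway endpoint existence and
#' \code{source != target}; rate-name uniqueness; nonnegative rate values;
#' annotation and efficacy-tier vocabulary; reference-sensitivity shape.
#'
#' @param model a [NetworkModel-class].
#' @return a [ValidationReport-class]; \code{ok} is \code{TRUE} iff no
#'   issue of severity \code{"error"} was found.
#' @export
validateModel <- function(model) {
  issues <- data.frame(severity = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  add <- function(severity, message) {
    issues <<- rbind(issues, data.frame(severity = severity,
                                        message = message,
                                        stringsAsFactors = FALSE))
  }
  st <- model@states
  pw <- model@pathways

  if (anyDuplicated(st$id))
    add("error", paste("duplicate state ids:",
                       paste(unique(st$id[duplicated(st$id)]),
                             collapse = ", ")))
  bad_lin <- setdiff(unique(st$lineage), LINEAGES)
  if (length(bad_lin))
    add("error", paste("unknown lineage:", paste(bad_lin, collapse = ", ")))
  bad_mode <- setdiff(unique(st$mode), MODES)
  if (length(bad_mode))
    add("error", paste("unknown mode:", paste(bad_mode, collapse = ", ")))
  if (any(st$initial_value < 0))
    add("error", paste("negative initial_value for state(s):",
                       paste(st$id[st$initial_value < 0], collapse = ", ")))

  for (lin in setdiff(intersect(unique(st$lineage), LINEAGES), "stress")) {
    members <- st[st$lineage == lin, ]
    if (nrow(members) != 2) {
      add("error", sprintf("lineage '%s' has %d state(s); expected a pair",
                           lin, nrow(members)))
    } else {
      pairs <- list(c("surviving", "dead"), c("quiescent", "activated"))
      ok <- any(vapply(pairs, function(p) setequal(members$mode, p),
                       logical(1)))
      if (!ok)
        add("error", sprintf(
          "lineage '%s' modes (%s) are not a complementary pair",
          lin, paste(members$mode, collapse = ", ")))
    }
  }
  stress <- st[st$lineage == "stress", ]
  if (nrow(stress) > 1)
    add("error", "more than one stress-pool state")
  if (nrow(stress) == 1) {
    if (stress$mode != "stress_pool")
      add("error", sprintf("stress state '%s' must have mode 'stress_pool'",
                           stress$id))
    if (stress$initial_value <= 0)
      add("error", sprintf(
        "stress pool '%s' initial_value must be > 0 (normalization scale)",
        stress$id))
  }

  if (nrow(pw)) {
    if (anyDuplicated(pw$rate_name))
      add("error", paste("duplicate rate_name:",
                         paste(unique(pw$rate_name[duplicated(pw$rate_name)]),
                               collapse = ", ")))
    if (anyDuplicated(pw$id))
      add("error", "duplicate pathway ids")
    for (i in seq_len(nrow(pw))) {
      p <- pw[i, ]
      if (!(p$source %in% st$id))
        add("error", sprintf("pathway %d: source '%s' is not a state",
                             p$id, p$source))
      if (!(p$target %in% st$id))
        add("error", sprintf("pathway %d: target '%s' is not a state",
                             p$id, p$target))
      if (identical(p$source, p$target))
        add("error", sprintf("pathway %d: source equals target ('%s')",
                             p$id, p$source))
      if (is.na(p$rate_value) || p$rate_value < 0)
        add("error", sprintf("pathway %d: rate_value must be >= 0", p$id))
      if (!(p$annotation %in% ANNOTATIONS))
        add("error", sprintf("pathway %d: unknown annotation '%s'",
                             p$id, p$annotation))
      if (!(p$efficacy_tier %in% EFFICACY_TIERS))
        add("error", sprintf("pathway %d: unknown efficacy_tier '%s'",
                             p$id, p$efficacy_tier))
    }
  }

  ref <- model@reference_sensitivity
  if (length(ref)) {
    if (nrow(ref) != ncol(ref))
      add("error", "reference_sensitivity must be square")
    if (!all(rownames(ref) %in% st$id))
      add("warning", "reference_sensitivity names unknown states")
  }

  new("ValidationReport", ok = !any(issues$severity == "error"),
      issues = issues)
}

#' Count homeostatic and pathogenic pathways
#'
#' @param model a [NetworkModel-class].
#' @return named integer vector \code{c(homeostatic =, pathogenic =)}; the
#'   two counts partition the pathway set.  The packaged default model
#'   yields 15 homeostatic and 7 pathogenic pathways.
#' @export
classifyCounts <- function(model) {
  ann <- model@pathways$annotation
  c(homeostatic = sum(ann == "homeostatic"),
    pathogenic = sum(ann == "pathogenic"))
}

#' Export the network topology as GraphML or DOT
#'
#' Nodes carry \code{display_name}, \code{lineage}, \code{mode} and
#' \code{initial_value}; edges carry \code{rate_name}, \code{rate_value},
#' \code{annotation} and \code{efficacy_tier}.
#'
#' @param model a [NetworkModel-class].
#' @param format \code{"graphml"} or \code{"dot"}.
#' @param file optional output path; if omitted the graph text is returned.
#' @return invisibly the output path if \code{file} is given, otherwise the
#'   graph text as a single string.
#' @export
exportGraph <- function(model, format = c("graphml", "dot"), file = NULL) {
  if (!is.character(format) || !all(format %in% c("graphml", "dot")))
    stop("unsupported graph format: ", paste(format, collapse = ", "))
  format <- match.arg(format)
  g <- modelGraph(model)
  out <- if (is.null(file)) tempfile(fileext = paste0(".", format)) else file
  igraph::write_graph(g, out, format = format)
  if (is.null(file)) {
    txt <- paste(readLines(out, warn = FALSE), collapse = "\n")
    unlink(out)
    txt
  } else invisible(out)
}

#' Build an igraph representation of the network
#'
#' @param model a [NetworkModel-class].
#' @return an [igraph::igraph] directed graph with state/pathway attributes.
#' @export
modelGraph <- function(model) {
  st <- model@states
  pw <- model@pathways
  vertices <- data.frame(name = st$id, display_name = st$display_name,
                         lineage = st$lineage, mode = st$mode,
                         initial_value = st$initial_value,
                         stringsAsFactors = FALSE)
  edges <- if (nrow(pw)) {
    data.frame(from = pw$source, to = pw$target, rate_name = pw$rate_name,
               rate_value = pw$rate_value, annotation = pw$annotation,
               efficacy_tier = pw$efficacy_tier, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0))
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' @describeIn NetworkModel-class states accessor.
#' @param model,object a \code{NetworkModel}.
#' @export
states <- function(model) model@states

#' @describeIn NetworkModel-class pathways accessor.
#' @export
pathways <- function(model) model@pathways

#' @describeIn NetworkModel-class named initial values in state order.
#' @export
initialValues <- function(model) {
  stats::setNames(model@states$initial_value, model@states$id)
}

#' @describeIn NetworkModel-class named rate constants.
#' @export
rateValues <- function(model) {
  stats::setNames(model@pathways$rate_value, model@pathways$rate_name)
}

#' Replace rate constants in a model
#'
#' @param model a [NetworkModel-class].
#' @param values named numeric vector of per-year rates; names must be
#'   existing \code{rate_name}s.
#' @return the modified model.
#' @export
setRateValues <- function(model, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  idx <- match(names(values), model@pathways$rate_name)
  if (anyNA(idx))
    stop("unknown rate name(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "))
  if (any(values < 0)) stop("rate values must be >= 0")
  model@pathways$rate_value[idx] <- unname(values)
  model
}

#' Look up the packaged reference sensitivity value
#'
#' Returns the entry of the model's dimensionless reference sensitivity
#' table for a (row state, column state) pair, e.g. the published tabulated
#' value of the sensitivity of one species with respect to another.
#'
#' @param model a [NetworkModel-class] carrying a reference table.
#' @param row_state,col_state state ids (e.g. \code{"Mb"}, \code{"Rd"}).
#' @return a single dimensionless value.
#' @export
referenceSensitivity <- function(model, row_state, col_state) {
  ref <- model@reference_sensitivity
  if (!length(ref)) stop("model carries no reference sensitivity table")
  if (!(row_state %in% rownames(ref)))
    stop("unknown row state: ", row_state)
  if (!(col_state %in% colnames(ref)))
    stop("unknown column state: ", col_state)
  ref[row_state, col_state]
}

setMethod("show", "NetworkModel", function(object) {
  cnt <- classifyCounts(object)
  cat(sprintf("NetworkModel: %d states, %d pathways (%d homeostatic, %d pathogenic)\n",
              nrow(object@states), nrow(object@pathways),
              cnt["homeostatic"], cnt["pathogenic"]))
  if (!is.null(object@metadata$name))
    cat("  name:", object@metadata$name, "\n")
  cat("  states:", paste(object@states$id, collapse = ", "), "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s (%d issue(s))\n",
              if (object@ok) "ok" else "NOT ok", nrow(object@issues)))
  if (nrow(object@issues))
    for (i in seq_len(nrow(object@issues)))
      cat(sprintf("  [%s] %s\n", object@issues$severity[i],
                  object@issues$message[i]))
})
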