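# Typed kinetic-term grammar
#
# Each directed pathway X -> Y with rate k maps to exactly one term.  With
# xhat = [X] / N(X), where N(X) is the total initial population of X's
# lineage (for the stress pool, its own initial value):
#   (a) Y is a surviving neuron pool     -> protective hazard  -k * xhat
#   (b) Y is a dead neuron pool          -> harmful hazard     +k * xhat
#   (c) Y is the stress pool             -> production  dC/dt += k * xhat * C(0)
#   (d) lineage(X) == lineage(Y)         -> first-order conversion  k * [X]
#   (e) otherwise -> catalyzed conversion of co(Y) (Y's complementary
#       state) into Y at rate k * xhat * [co(Y)]
# Every k stays in units of 1/year; lineage pair totals are conserved; all
# fluxes vanish at empty pools.  Surviving neurons die by one-hit kinetics,
# dRs/dt = -h * Rs with h = max(0, sum harmful - sum protective); the dead
# pool is bookkept by conservation, not integrated.

.lineageTotals <- function(model) {
  st <- model@states
  tot <- tapply(st$initial_value, st$lineage, sum)
  stress <- st$id[st$lineage == "stress"]
  if (length(stress) == 1)
    tot["stress"] <- st$initial_value[st$id == stress]
  tot
}

.complementOf <- function(model, id) {
  st <- model@states
  lin <- st$lineage[st$id == id]
  other <- st$id[st$lineage == lin & st$id != id]
  if (length(other) != 1)
    stop("state '", id, "' has no unique complementary state")
  other
}

#' Classify a pathway into its typed kinetic term
#'
#' Applies the term grammar (see [buildRateSystem()]) to a single edge.
#' Target-based rules (hazard contributions for edges into the surviving or
#' dead neuron pool, stress production for edges into the stress pool) take
#' precedence; then same-lineage edges become first-order conversions and
#' all remaining cross-lineage edges catalyzed conversions of the target's
#' complementary state.
#'
#' @param pathway a single-row data.frame from \code{pathways(model)} (or a
#'   pathway id).
#' @param model the [NetworkModel-class] the pathway belongs to.
#' @return one-row data.frame with columns \code{pathway_id},
#'   \code{rate_name}, \code{kind}, \code{catalyst}, \code{substrate},
#'   \code{product}, \code{normalization}.
#' @export
classifyEdgeTerm <- function(pathway, model) {
  if (is.numeric(pathway) || is.character(pathway)) {
    pw <- model@pathways
    row <- pw[pw$id == pathway | pw$rate_name == pathway, , drop = FALSE]
    if (nrow(row) != 1) stop("pathway not found in model: ", pathway)
    pathway <- row
  }
  st <- model@states
  src <- pathway$source
  tgt <- pathway$target
  if (!(src %in% st$id) || !(tgt %in% st$id))
    stop("pathway ", pathway$id, ": endpoint not in model")
  src_lin <- st$lineage[st$id == src]
  tgt_mode <- st$mode[st$id == tgt]
  tgt_lin <- st$lineage[st$id == tgt]
  totals <- .lineageTotals(model)
  norm <- unname(totals[src_lin])
  if (is.na(norm) || norm <= 0)
    stop("pathway ", pathway$id, ": normalization for lineage '", src_lin,
         "' is not positive")
  term <- function(kind, catalyst = NA_character_, substrate = NA_character_,
                   product = NA_character_, normalization = NA_real_) {
    data.frame(pathway_id = pathway$id, rate_name = pathway$rate_name,
               kind = kind, catalyst = catalyst, substrate = substrate,
               product = product, normalization = normalization,
               stringsAsFactors = FALSE)
  }
  if (tgt_mode == "surviving")
    return(term("protective_hazard", catalyst = src, normalization = norm))
  if (tgt_mode == "dead")
    return(term("harmful_hazard", catalyst = src, normalization = norm))
  if (tgt_mode == "stress_pool")
    return(term("stress_production", catalyst = src, normalization = norm))
  if (identical(src_lin, tgt_lin))
    return(term("conversion", substrate = src, product = tgt,
                normalization = norm))
  co <- .complementOf(model, tgt)
  if (st$mode[st$id == co] %in% c("dead", "surviving"))
    stop("pathway ", pathway$id, ": cannot catalyze conversion within the ",
         "neuron lineage (deaths go through the hazard)")
  term("catalyzed_conversion", catalyst = src, substrate = co, product = tgt,
       normalization = norm)
}

.dynamicalOrder <- function(model) {
  st <- model@states
  lins <- unique(st$lineage)
  lins <- c(setdiff(lins, "stress"), intersect("stress", lins))
  ids <- character(0)
  for (lin in lins) {
    members <- st[st$lineage == lin, ]
    first <- members$id[members$mode %in% c("surviving", "quiescent",
                                            "stress_pool")]
    second <- members$id[members$mode == "activated"]
    ids <- c(ids, first, second)
  }
  ids
}

#' Build the kinetic rate system for a model
#'
#' Classifies all pathways with [classifyEdgeTerm()] and assembles the
#' right-hand side: one equation per dynamical state (dead pools are
#' eliminated by conservation) plus first-order degradation of the stress
#' pool.  The packaged default model yields 7 cell-population equations and
#' 1 stress equation.
#'
#' @param model a valid [NetworkModel-class].
#' @param lambda_degradation per-year first-order stress degradation
#'   (default 0.5).
#' @return a [RateSystem-class].
#' @examples
#' sys <- buildRateSystem(defaultModel())
#' length(dynamicalStates(sys))  # 8 = 7 cell equations + 1 stress equation
#' @export
buildRateSystem <- function(model, lambda_degradation = 0.5) {
  stopifnot(is.numeric(lambda_degradation), length(lambda_degradation) == 1,
            lambda_degradation >= 0)
  rep <- validateModel(model)
  if (!rep@ok)
    stop("model fails validation:\n  ",
         paste(rep@issues$message[rep@issues$severity == "error"],
               collapse = "\n  "))
  st <- model@states
  pw <- model@pathways
  terms <- if (nrow(pw)) {
    do.call(rbind, lapply(seq_len(nrow(pw)), function(i)
      classifyEdgeTerm(pw[i, ], model)))
  } else {
    data.frame(pathway_id = integer(0), rate_name = character(0),
               kind = character(0), catalyst = character(0),
               substrate = character(0), product = character(0),
               normalization = numeric(0), stringsAsFactors = FALSE)
  }
  dead <- st[st$mode == "dead", ]
  bookkept <- if (nrow(dead)) {
    do.call(rbind, lapply(seq_len(nrow(dead)), function(i) {
      lin <- dead$lineage[i]
      surv <- st$id[st$lineage == lin & st$mode == "surviving"]
      data.frame(dead_id = dead$id[i], surviving_id = surv,
                 total = sum(st$initial_value[st$lineage == lin]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(dead_id = character(0), surviving_id = character(0),
               total = numeric(0), stringsAsFactors = FALSE)
  }
  stress <- st[st$lineage == "stress", ]
  dyn <- setdiff(.dynamicalOrder(model), dead$id)
  init <- stats::setNames(st$initial_value[match(dyn, st$id)], dyn)
  new("RateSystem",
      state_ids = dyn,
      terms = terms,
      rate_values = stats::setNames(pw$rate_value, pw$rate_name),
      lambda_degradation = lambda_degradation,
      init = init,
      bookkept = bookkept,
      stress_id = if (nrow(stress)) stress$id else NA_character_,
      stress_init = if (nrow(stress)) stress$initial_value else NA_real_,
      lineages = stats::setNames(st$lineage, st$id))
}

#' @describeIn RateSystem-class ordered ids of the integrated states.
#' @param system a \code{RateSystem}.
#' @export
dynamicalStates <- function(system) system@state_ids

#' @describeIn RateSystem-class the typed term table (one row per pathway).
#' @export
termTable <- function(system) system@terms

# Full state vector (dynamical + bookkept dead pools) from a dynamical one.
.fullState <- function(system, y) {
  full <- y[system@state_ids]
  bk <- system@bookkept
  if (nrow(bk)) {
    dead_vals <- bk$total - full[bk$surviving_id]
    names(dead_vals) <- bk$dead_id
    full <- c(full, dead_vals)
  }
  full
}

#' One-hit death hazard for a state vector
#'
#' \eqn{h = \max(0, \sum_{harmful} k\,\hat x - \sum_{protective} k\,\hat x)}
#' with \eqn{\hat x} the catalyst population divided by its lineage's
#' initial total.  Protective influences lower the hazard but never
#' resurrect cells: the hazard is clipped at zero.
#'
#' @param system a [RateSystem-class].
#' @param state_vector named nonnegative values covering every hazard
#'   catalyst (a full or dynamical state vector; bookkept dead pools are
#'   derived by conservation when missing).
#' @param rate_values optional named override of the system's rates.
#' @return hazard in 1/year, >= 0.
#' @export
hazardValue <- function(system, state_vector, rate_values = NULL) {
  k <- if (is.null(rate_values)) system@rate_values else rate_values
  tm <- system@terms
  hz <- tm[tm$kind %in% c("harmful_hazard", "protective_hazard"), ,
           drop = FALSE]
  if (!nrow(hz)) return(0)
  need <- unique(hz$catalyst)
  missing_ids <- setdiff(need, names(state_vector))
  if (length(missing_ids)) {
    bk <- system@bookkept
    derivable <- intersect(missing_ids, bk$dead_id)
    if (length(derivable)) {
      i <- match(derivable, bk$dead_id)
      add <- bk$total[i] - state_vector[bk$surviving_id[i]]
      names(add) <- derivable
      state_vector <- c(state_vector, add)
      missing_ids <- setdiff(missing_ids, derivable)
    }
    if (length(missing_ids))
      stop("state vector is missing: ", paste(missing_ids, collapse = ", "))
  }
  xhat <- state_vector[hz$catalyst] / hz$normalization
  contrib <- unname(k[hz$rate_name]) * unname(xhat)
  sgn <- ifelse(hz$kind == "harmful_hazard", 1, -1)
  max(0, sum(sgn * contrib))
}

#' Evaluate the time derivatives of the dynamical states
#'
#' @param system a [RateSystem-class].
#' @param t time in years (the system is autonomous; \code{t} is accepted
#'   for solver compatibility).
#' @param state_vector named nonnegative values of the dynamical states.
#' @param rate_values optional named override of the system's rates.
#' @return named derivative vector over \code{dynamicalStates(system)}.
#' @export
evaluateDerivatives <- function(system, t, state_vector, rate_values = NULL) {
  if (any(!is.finite(state_vector)))
    stop("non-finite state vector")
  k <- if (is.null(rate_values)) system@rate_values else rate_values
  y <- state_vector[system@state_ids]
  full <- .fullState(system, y)
  dy <- stats::setNames(numeric(length(y)), names(y))
  tm <- system@terms
  for (i in seq_len(nrow(tm))) {
    kind <- tm$kind[i]
    ki <- unname(k[tm$rate_name[i]])
    if (kind == "conversion") {
      flux <- ki * full[tm$substrate[i]]
      dy[tm$substrate[i]] <- dy[tm$substrate[i]] - flux
      dy[tm$product[i]] <- dy[tm$product[i]] + flux
    } else if (kind == "catalyzed_conversion") {
      xhat <- full[tm$catalyst[i]] / tm$normalization[i]
      flux <- ki * xhat * full[tm$substrate[i]]
      dy[tm$substrate[i]] <- dy[tm$substrate[i]] - flux
      dy[tm$product[i]] <- dy[tm$product[i]] + flux
    } else if (kind == "stress_production") {
      xhat <- full[tm$catalyst[i]] / tm$normalization[i]
      dy[system@stress_id] <- dy[system@stress_id] +
        ki * xhat * system@stress_init
    }
  }
  bk <- system@bookkept
  if (nrow(bk)) {
    h <- hazardValue(system, full, rate_values = k)
    for (i in seq_len(nrow(bk))) {
      surv <- bk$surviving_id[i]
      dy[surv] <- dy[surv] - h * full[surv]
    }
  }
  if (!is.na(system@stress_id))
    dy[system@stress_id] <- dy[system@stress_id] -
      system@lambda_degradation * full[system@stress_id]
  if (any(!is.finite(dy))) stop("non-finite derivative")
  dy
}

# Precompile a system into integer-indexed term vectors for the integrator
# hot path.  Semantics are identical to evaluateDerivatives(), which the
# test suite asserts at random states.
.compileSystem <- function(system) {
  dyn <- system@state_ids
  n <- length(dyn)
  bk <- system@bookkept
  full_ids <- c(dyn, bk$dead_id)
  fidx <- stats::setNames(seq_along(full_ids), full_ids)
  tm <- system@terms
  kn <- names(system@rate_values)
  kidx <- stats::setNames(seq_along(kn), kn)
  sel <- function(kind) tm[tm$kind == kind, , drop = FALSE]
  conv <- sel("conversion")
  cat_ <- sel("catalyzed_conversion")
  prod <- sel("stress_production")
  hz <- tm[tm$kind %in% c("harmful_hazard", "protective_hazard"), ,
           drop = FALSE]
  list(
    n = n,
    surv_idx = match(bk$surviving_id, dyn),
    totals = bk$total,
    conv_s = fidx[conv$substrate], conv_p = fidx[conv$product],
    conv_k = kidx[conv$rate_name],
    cat_c = fidx[cat_$catalyst], cat_s = fidx[cat_$substrate],
    cat_p = fidx[cat_$product], cat_k = kidx[cat_$rate_name],
    cat_n = cat_$normalization,
    prod_c = fidx[prod$catalyst], prod_k = kidx[prod$rate_name],
    prod_n = prod$normalization,
    hz_c = fidx[hz$catalyst], hz_k = kidx[hz$rate_name],
    hz_n = hz$normalization,
    hz_sign = ifelse(hz$kind == "harmful_hazard", 1, -1),
    stress_idx = if (is.na(system@stress_id)) 0L
                 else match(system@stress_id, dyn),
    stress_init = system@stress_init,
    lambda = system@lambda_degradation
  )
}

.compiledDerivs <- function(cs, y, k) {
  full <- c(y, cs$totals - y[cs$surv_idx])
  dy <- numeric(cs$n)
  for (i in seq_along(cs$conv_k)) {
    flux <- k[cs$conv_k[i]] * full[cs$conv_s[i]]
    dy[cs$conv_s[i]] <- dy[cs$conv_s[i]] - flux
    dy[cs$conv_p[i]] <- dy[cs$conv_p[i]] + flux
  }
  for (i in seq_along(cs$cat_k)) {
    flux <- k[cs$cat_k[i]] * (full[cs$cat_c[i]] / cs$cat_n[i]) *
      full[cs$cat_s[i]]
    dy[cs$cat_s[i]] <- dy[cs$cat_s[i]] - flux
    dy[cs$cat_p[i]] <- dy[cs$cat_p[i]] + flux
  }
  if (cs$stress_idx > 0L) {
    if (length(cs$prod_k))
      dy[cs$stress_idx] <- dy[cs$stress_idx] +
        sum(k[cs$prod_k] * (full[cs$prod_c] / cs$prod_n)) * cs$stress_init
    dy[cs$stress_idx] <- dy[cs$stress_idx] - cs$lambda * y[cs$stress_idx]
  }
  if (length(cs$surv_idx)) {
    h <- if (length(cs$hz_k))
      max(0, sum(cs$hz_sign * k[cs$hz_k] * (full[cs$hz_c] / cs$hz_n)))
    else 0
    dy[cs$surv_idx] <- dy[cs$surv_idx] - h * y[cs$surv_idx]
  }
  dy
}

#' Human-readable equation listing of a rate system
#'
#' One line per dynamical state with signed terms and rate names, plus the
#' conservation bookkeeping line for each dead pool.
#'
#' @param system a [RateSystem-class].
#' @return character vector of equation lines.
#' @export
equationText <- function(system) {
  tm <- system@terms
  pieces <- stats::setNames(vector("list", length(system@state_ids)),
                            system@state_ids)
  for (i in seq_len(nrow(tm))) {
    kind <- tm$kind[i]
    rn <- tm$rate_name[i]
    if (kind == "conversion") {
      expr <- sprintf("%s*[%s]", rn, tm$substrate[i])
      pieces[[tm$substrate[i]]] <- c(pieces[[tm$substrate[i]]],
                                     paste0("- ", expr))
      pieces[[tm$product[i]]] <- c(pieces[[tm$product[i]]],
                                   paste0("+ ", expr))
    } else if (kind == "catalyzed_conversion") {
      expr <- sprintf("%s*([%s]/%g)*[%s]", rn, tm$catalyst[i],
                      tm$normalization[i], tm$substrate[i])
      pieces[[tm$substrate[i]]] <- c(pieces[[tm$substrate[i]]],
                                     paste0("- ", expr))
      pieces[[tm$product[i]]] <- c(pieces[[tm$product[i]]],
                                   paste0("+ ", expr))
    } else if (kind == "stress_production") {
      expr <- sprintf("%s*([%s]/%g)*%g", rn, tm$catalyst[i],
                      tm$normalization[i], system@stress_init)
      pieces[[system@stress_id]] <- c(pieces[[system@stress_id]],
                                      paste0("+ ", expr))
    }
  }
  bk <- system@bookkept
  for (i in seq_len(nrow(bk)))
    pieces[[bk$surviving_id[i]]] <- c(pieces[[bk$surviving_id[i]]],
                                      sprintf("- h*[%s]",
                                              bk$surviving_id[i]))
  if (!is.na(system@stress_id))
    pieces[[system@stress_id]] <- c(pieces[[system@stress_id]],
                                    sprintf("- lambda*[%s]",
                                            system@stress_id))
  hz <- tm[tm$kind %in% c("harmful_hazard", "protective_hazard"), ,
           drop = FALSE]
  lines <- vapply(system@state_ids, function(s) {
    rhs <- if (length(pieces[[s]])) paste(pieces[[s]], collapse = " ")
           else "0"
    sprintf("d[%s]/dt = %s", s, rhs)
  }, character(1))
  if (nrow(hz)) {
    hterm <- paste(sprintf("%s %s*([%s]/%g)",
                           ifelse(hz$kind == "harmful_hazard", "+", "-"),
                           hz$rate_name, hz$catalyst, hz$normalization),
                   collapse = " ")
    lines <- c(lines, paste("h = max(0,", hterm, ")"))
  }
  for (i in seq_len(nrow(bk)))
    lines <- c(lines, sprintf("[%s] = %g - [%s]   (conservation)",
                              bk$dead_id[i], bk$total[i],
                              bk$surviving_id[i]))
  unname(lines)
}

setMethod("show", "RateSystem", function(object) {
  n_cell <- length(setdiff(object@state_ids, object@stress_id))
  cat(sprintf("RateSystem: %d cell-population equation(s) + %d stress equation(s), %d term(s)\n",
              n_cell, as.integer(!is.na(object@stress_id)),
              nrow(object@terms)))
  cat("  lambda (stress degradation):", object@lambda_degradation, "/yr\n")
  if (nrow(object@bookkept))
    cat("  bookkept dead pool(s):",
        paste(object@bookkept$dead_id, collapse = ", "), "\n")
})
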