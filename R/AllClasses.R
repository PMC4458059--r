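#' @import methods
NULL

#' MetabolicModel: a constraint-based stoichiometric model
#'
#' Container for a steady-state metabolic network: metabolite annotations,
#' reaction bounds, the stoichiometric matrix S (metabolites x reactions),
#' a biomass objective, and optional extra linear constraints coupling
#' reaction fluxes (used e.g. to cap a reaction at a fraction of substrate
#' uptake, or to tie glucose and oxygen uptake at a fixed ratio).
#'
#' Fluxes are in mmol/gDCW/h throughout. Exchange reactions involve exactly
#' one metabolite with coefficient -1; a negative exchange flux is uptake,
#' a positive one secretion.
#'
#' @slot mets data.frame with columns id, compartment, carbon_count, name
#' @slot rxns data.frame with columns id, lower_bound, upper_bound,
#'   is_exchange, knockable
#' @slot S numeric matrix, metabolites (rows) x reactions (columns),
#'   negative coefficients for substrates
#' @slot objective_id id of the biomass (objective) reaction
#' @slot couplings list of extra linear constraints, each a list with
#'   elements terms (named numeric over reaction ids), sense (one of
#'   "<=", "=", ">="), rhs (numeric)
#'
#' @export
setClass("MetabolicModel",
  representation(
    mets = "data.frame",
    rxns = "data.frame",
    S = "matrix",
    objective_id = "character",
    couplings = "list"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  m <- object@mets; r <- object@rxns; S <- object@S
  need_m <- c("id", "compartment", "carbon_count")
  need_r <- c("id", "lower_bound", "upper_bound", "is_exchange", "knockable")
  if (!all(need_m %in% names(m))) {
    msg <- c(msg, "mets must have columns id, compartment, carbon_count")
  }
  if (!all(need_r %in% names(r))) {
    msg <- c(msg, paste("rxns must have columns", paste(need_r, collapse = ", ")))
  }
  if (length(msg)) return(msg)
  if (anyDuplicated(m$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(r$id)) msg <- c(msg, "duplicate reaction ids")
  if (any(m$carbon_count < 0)) msg <- c(msg, "carbon_count must be >= 0")
  if (nrow(S) != nrow(m) || ncol(S) != nrow(r)) {
    msg <- c(msg, "S dimensions inconsistent with mets/rxns")
  } else {
    if (!identical(rownames(S), m$id)) msg <- c(msg, "rownames(S) != mets$id")
    if (!identical(colnames(S), r$id)) msg <- c(msg, "colnames(S) != rxns$id")
  }
  if (any(r$lower_bound > r$upper_bound)) {
    bad <- r$id[r$lower_bound > r$upper_bound]
    msg <- c(msg, paste("lower_bound > upper_bound for:", paste(bad, collapse = ", ")))
  }
  if (length(object@objective_id) != 1L || !(object@objective_id %in% r$id)) {
    msg <- c(msg, "objective_id must name exactly one existing reaction")
  }
  if (nrow(r) && nrow(S) == nrow(m) && ncol(S) == nrow(r)) {
    nz <- colSums(S != 0)
    if (any(nz == 0)) {
      msg <- c(msg, paste("empty stoichiometry for:",
                          paste(r$id[nz == 0], collapse = ", ")))
    }
    ex_bad <- r$is_exchange & nz != 1
    if (any(ex_bad)) {
      msg <- c(msg, paste("exchange reactions must have exactly one metabolite:",
                          paste(r$id[ex_bad], collapse = ", ")))
    }
  }
  for (cp in object@couplings) {
    if (!all(names(cp$terms) %in% r$id)) {
      msg <- c(msg, paste("coupling references unknown reactions:",
                          paste(setdiff(names(cp$terms), r$id), collapse = ", ")))
    }
    if (!cp$sense %in% c("<=", "=", ">=")) {
      msg <- c(msg, "coupling sense must be one of <=, =, >=")
    }
  }
  if (length(msg)) msg else TRUE
})

#' FluxSolution: result of one LP solve on a MetabolicModel
#'
#' @slot status "optimal", "infeasible" or "unbounded"
#' @slot objective_value optimal value of the objective flux (NA unless optimal)
#' @slot fluxes named numeric flux vector over reaction ids (length 0 unless
#'   optimal)
#'
#' @export
setClass("FluxSolution",
  representation(
    status = "character",
    objective_value = "numeric",
    fluxes = "numeric"
  )
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})

#' DesignResult: a knockout design with its validated phenotype
#'
#' Produced by [optknock()], [gdls()], [twoStepDesign()] and
#' [bruteForceDesign()]. `target_min`/`target_max` are the flux range of the
#' target exchange with growth fixed at its optimum; a design is
#' growth-coupled when even the pessimistic minimum is positive.
#'
#' @slot knockouts character vector of knocked-out reaction ids
#' @slot growth biomass flux at the mutant optimum
#' @slot target_min,target_max target exchange flux range at the growth
#'   optimum (flux variability analysis)
#' @slot coupled TRUE when target_min exceeds the coupling tolerance
#' @slot yield_fraction target_max divided by the wild-type theoretical
#'   maximum under the same condition (NA when not computed)
#' @slot trace data.frame of search iterations (stage, iteration, knockout
#'   set, score)
#' @slot status "ok" or a diagnostic string
#'
#' @export
setClass("DesignResult",
  representation(
    knockouts = "character",
    growth = "numeric",
    target_min = "numeric",
    target_max = "numeric",
    coupled = "logical",
    yield_fraction = "numeric",
    trace = "data.frame",
    status = "character"
  )
)

setValidity("DesignResult", function(object) {
  msg <- character()
  if (isTRUE(object@coupled) && !is.na(object@target_min) &&
      object@target_min <= 0)
    msg <- c(msg, "coupled implies target_min > 0")
  yf <- object@yield_fraction
  if (length(yf) == 1L && !is.na(yf) && (yf < -1e-9 || yf > 1 + 1e-9))
    msg <- c(msg, "yield_fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ThermoProfile: per-step Gibbs energy profile of a pathway
#'
#' @slot steps data.frame with one row per pathway step: reaction_id, dg0
#'   (kJ/mol), Q, dg (kJ/mol), rank (1 = furthest from equilibrium by |dg|)
#' @slot provenance data.frame mapping each participating species to the
#'   provenance of its concentration
#' @slot additivity list with the net-reaction additivity check (net_dg,
#'   sum_dg, cancelled: logical, max_abs_residual)
#' @slot temperature_K temperature used
#'
#' @export
setClass("ThermoProfile",
  representation(
    steps = "data.frame",
    provenance = "data.frame",
    additivity = "list",
    temperature_K = "numeric"
  )
)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@mets), "metabolites,",
      nrow(object@rxns), "reactions\n")
  cat("  objective:", object@objective_id, "\n")
  nex <- sum(object@rxns$is_exchange)
  cat("  exchanges:", nex, " knockable:", sum(object@rxns$knockable),
      " extra constraints:", length(object@couplings), "\n")
  invisible(object)
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution [", object@status, "]", sep = "")
  if (object@status == "optimal")
    cat(" objective =", format(object@objective_value, digits = 6))
  cat("\n")
  invisible(object)
})

setMethod("show", "DesignResult", function(object) {
  cat("DesignResult:", if (length(object@knockouts))
        paste(object@knockouts, collapse = ", ") else "(no knockouts)", "\n")
  cat(sprintf("  growth %.4f | target [%.4f, %.4f] | coupled: %s\n",
              object@growth, object@target_min, object@target_max,
              object@coupled))
  if (!is.na(object@yield_fraction))
    cat(sprintf("  yield fraction %.3f\n", object@yield_fraction))
  invisible(object)
})

setMethod("show", "ThermoProfile", function(object) {
  cat("ThermoProfile:", nrow(object@steps), "steps at",
      object@temperature_K, "K\n")
  print(object@steps[order(object@steps$rank),
                     c("reaction_id", "dg0", "Q", "dg", "rank")],
        row.names = FALSE, digits = 4)
  invisible(object)
})
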