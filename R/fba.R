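#' Flux balance analysis
#'
#' Solves the steady-state LP: optimize the flux through `objective`
#' subject to S v = 0, flux bounds, and any extra coupling constraints.
#'
#' @param model a [MetabolicModel-class]
#' @param objective reaction id to optimize; defaults to the model objective
#'   (biomass)
#' @param direction "max" or "min"
#' @return a [FluxSolution-class]; for optimal solutions the flux vector
#'   satisfies mass balance and bounds within 1e-6
#' @export
fba <- function(model, objective = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  validObject(model)
  if (is.null(objective)) objective <- model@objective_id
  oi <- .rxnIndex(model, objective)
  lp <- .modelLP(model)
  obj <- numeric(ncol(lp$A)); obj[oi] <- 1
  r <- lpSolveDense(obj, lp$A, lp$sense, lp$rhs, lp$lb, lp$ub,
                    maximize = direction == "max")
  if (r$status != "optimal")
    return(new("FluxSolution", status = r$status,
               objective_value = NA_real_, fluxes = numeric()))
  v <- r$x
  names(v) <- model@rxns$id
  mb <- max(abs(model@S %*% v))
  if (mb > .tf_feas_tol)
    stop("fba: mass-balance residual ", format(mb), " exceeds tolerance")
  new("FluxSolution", status = "optimal", objective_value = r$objval,
      fluxes = v)
}

#' Flux variability analysis
#'
#' With the model objective constrained to at least `fractionOfOptimum`
#' times its optimum, minimizes and maximizes each requested reaction flux.
#' At fraction 1 the biomass flux is pinned at its optimum before ranging,
#' which exposes alternate-optima ranges of other fluxes (e.g. a target
#' exchange that is only weakly coupled).
#'
#' @param model a [MetabolicModel-class]
#' @param reactions reaction ids to range over (default: all)
#' @param fractionOfOptimum number in \[0, 1\]
#' @return data.frame with columns id, min, max
#' @export
fva <- function(model, reactions = NULL, fractionOfOptimum = 1) {
  stopifnot(fractionOfOptimum >= 0, fractionOfOptimum <= 1)
  if (is.null(reactions)) reactions <- model@rxns$id
  idx <- .rxnIndex(model, reactions)
  sol <- fba(model)
  if (sol@status != "optimal") stop("fva: model is ", sol@status)
  lp <- .modelLP(model)
  n <- ncol(lp$A)
  if (fractionOfOptimum > 0) {
    row <- numeric(n); row[.rxnIndex(model, model@objective_id)] <- 1
    floor_v <- fractionOfOptimum * sol@objective_value
    # small absolute slack keeps the constrained polytope non-empty under
    # solver roundoff
    lp$A <- rbind(lp$A, row)
    lp$sense <- c(lp$sense, ">=")
    lp$rhs <- c(lp$rhs, floor_v - 1e-8 * max(1, abs(floor_v)))
  }
  out <- data.frame(id = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    obj <- numeric(n); obj[idx[k]] <- 1
    rmin <- lpSolveDense(obj, lp$A, lp$sense, lp$rhs, lp$lb, lp$ub, FALSE)
    rmax <- lpSolveDense(obj, lp$A, lp$sense, lp$rhs, lp$lb, lp$ub, TRUE)
    if (rmin$status != "optimal" || rmax$status != "optimal")
      stop("fva: subproblem not optimal for ", reactions[k])
    out$min[k] <- rmin$objval
    out$max[k] <- rmax$objval
  }
  out
}

#' Knock out reactions
#'
#' Returns a copy of the model with the given reactions' bounds set to
#' (0, 0). The input model is not modified. Only knockable reactions may be
#' removed; exchanges, the biomass objective and flagged maintenance
#' reactions refuse.
#'
#' @param model a [MetabolicModel-class]
#' @param reactions character vector of reaction ids (may be empty)
#' @return the knocked-out model
#' @export
applyKnockouts <- function(model, reactions) {
  if (!length(reactions)) return(model)
  idx <- .rxnIndex(model, reactions)
  bad <- !model@rxns$knockable[idx]
  if (any(bad))
    stop("reaction(s) not knockable: ",
         paste(reactions[bad], collapse = ", "))
  model@rxns$lower_bound[idx] <- 0
  model@rxns$upper_bound[idx] <- 0
  model
}

#' Add an exchange reaction for a metabolite
#'
#' Adds a single-metabolite export reaction `EX_<metabolite>` with the given
#' bounds (negative lower bound permits uptake). Errors if the exchange id
#' already exists; remove it first to replace.
#'
#' @param model a [MetabolicModel-class]
#' @param metabolite metabolite id
#' @param lb,ub flux bounds of the new exchange
#' @return the extended model
#' @export
addExchange <- function(model, metabolite, lb = 0, ub = .tf_cap) {
  .metIndex(model, metabolite)
  ex_id <- paste0("EX_", metabolite)
  if (ex_id %in% model@rxns$id)
    stop("exchange ", ex_id, " already present; drop it before replacing")
  model@rxns <- rbind(model@rxns,
    data.frame(id = ex_id, lower_bound = lb, upper_bound = ub,
               is_exchange = TRUE, knockable = FALSE, name = ex_id,
               stringsAsFactors = FALSE))
  S2 <- cbind(model@S, 0)
  colnames(S2) <- model@rxns$id
  S2[metabolite, ex_id] <- -1
  model@S <- S2
  validObject(model)
  model
}
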