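#' Construct a MetabolicModel
#'
#' Builds and validates a [MetabolicModel-class] from plain tables.
#' Reactions with missing/non-finite bounds get the default flux cap
#' (+/-1000 mmol/gDCW/h). Knockability defaults to FALSE for exchange
#' reactions, the objective reaction and any reaction flagged as ATP
#' maintenance; TRUE otherwise.
#'
#' @param mets data.frame with columns id, compartment and optionally
#'   carbon_count (default 0) and name
#' @param rxns data.frame with columns id, lower_bound, upper_bound and
#'   optionally is_exchange, knockable
#' @param stoich named list: for each reaction id, a named numeric vector of
#'   metabolite coefficients (substrates negative)
#' @param objective_id id of the biomass reaction
#' @param couplings optional list of linear couplings (see
#'   [MetabolicModel-class])
#' @param atpm_id optional id of the ATP maintenance reaction (made
#'   non-knockable)
#' @return a validated [MetabolicModel-class]
#' @export
metabolicModel <- function(mets, rxns, stoich, objective_id,
                           couplings = list(), atpm_id = NULL) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$carbon_count)) mets$carbon_count <- 0L
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(rxns$name)) rxns$name <- rxns$id
  rxns$lower_bound[!is.finite(rxns$lower_bound)] <- -.tf_cap
  rxns$upper_bound[!is.finite(rxns$upper_bound)] <- .tf_cap
  missing_r <- setdiff(rxns$id, names(stoich))
  if (length(missing_r))
    stop("no stoichiometry for reaction(s): ", paste(missing_r, collapse = ", "))
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  for (rid in rxns$id) {
    st <- stoich[[rid]]
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("reaction ", rid, " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    S[names(st), rid] <- st
  }
  if (is.null(rxns$is_exchange)) rxns$is_exchange <- colSums(S != 0) == 1L
  if (is.null(rxns$knockable)) {
    rxns$knockable <- !rxns$is_exchange & rxns$id != objective_id
    if (!is.null(atpm_id)) rxns$knockable[rxns$id == atpm_id] <- FALSE
  }
  mets <- mets[, c("id", "compartment", "carbon_count", "name")]
  rxns <- rxns[, c("id", "lower_bound", "upper_bound", "is_exchange",
                   "knockable", "name")]
  new("MetabolicModel", mets = mets, rxns = rxns, S = S,
      objective_id = objective_id, couplings = couplings)
}

.rxnIndex <- function(model, ids) {
  idx <- match(ids, model@rxns$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

.metIndex <- function(model, ids) {
  idx <- match(ids, model@mets$id)
  if (anyNA(idx))
    stop("unknown metabolite id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# LP pieces shared by fba/fva/design: stoichiometric equalities plus
# coupling rows, in lexicographic reaction order of the model as stored.
.modelLP <- function(model) {
  S <- model@S
  m <- nrow(S); n <- ncol(S)
  A <- S
  sense <- rep("=", m)
  rhs <- numeric(m)
  for (cp in model@couplings) {
    row <- numeric(n)
    row[.rxnIndex(model, names(cp$terms))] <- cp$terms
    A <- rbind(A, row)
    sense <- c(sense, cp$sense)
    rhs <- c(rhs, cp$rhs)
  }
  list(A = A, sense = sense, rhs = rhs,
       lb = pmax(model@rxns$lower_bound, -.tf_cap),
       ub = pmin(model@rxns$upper_bound, .tf_cap))
}
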