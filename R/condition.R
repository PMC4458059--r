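#' Simulation condition for strain design runs
#'
#' Encodes the boundary conditions used for design simulations: all uptake
#' fluxes closed except glucose and oxygen, both opened with a lower bound
#' of -10 mmol/gDCW/h, and glucose:oxygen uptake tied at a fixed ratio
#' (default 1:1) to mimic respiratory growth on glucose.
#'
#' @param substrate_exchange_id glucose exchange reaction id
#' @param oxygen_exchange_id oxygen exchange reaction id
#' @param uptake_lower_bound lower bound for both uptakes (<= 0),
#'   mmol/gDCW/h
#' @param glc_o2_ratio positive ratio enforced as the equality coupling
#'   v_glc = ratio * v_o2 (on the signed exchange fluxes); set
#'   `enforce_ratio = FALSE` to rely on bounds alone
#' @param enforce_ratio logical
#' @param other_uptakes_closed close every other exchange's uptake direction
#' @return a list of class "SimulationCondition"
#' @export
simulationCondition <- function(substrate_exchange_id = "EX_glc",
                                oxygen_exchange_id = "EX_o2",
                                uptake_lower_bound = -10,
                                glc_o2_ratio = 1,
                                enforce_ratio = TRUE,
                                other_uptakes_closed = TRUE) {
  stopifnot(uptake_lower_bound <= 0, glc_o2_ratio > 0)
  structure(list(substrate_exchange_id = substrate_exchange_id,
                 oxygen_exchange_id = oxygen_exchange_id,
                 uptake_lower_bound = uptake_lower_bound,
                 glc_o2_ratio = glc_o2_ratio,
                 enforce_ratio = enforce_ratio,
                 other_uptakes_closed = other_uptakes_closed),
            class = "SimulationCondition")
}

#' Apply a simulation condition to a model
#'
#' Sets every exchange lower bound to zero except the named substrate and
#' oxygen exchanges, which are opened at `uptake_lower_bound`; when ratio
#' enforcement is on, adds the coupling row
#' `v_substrate - ratio * v_oxygen = 0`. Idempotent: applying the same
#' condition twice gives the same model.
#'
#' @param model a [MetabolicModel-class]
#' @param condition a [simulationCondition()]
#' @return the conditioned model
#' @export
configureCondition <- function(model, condition = simulationCondition()) {
  stopifnot(inherits(condition, "SimulationCondition"))
  ids <- c(condition$substrate_exchange_id, condition$oxygen_exchange_id)
  idx <- .rxnIndex(model, ids)
  if (!all(model@rxns$is_exchange[idx]))
    stop("condition ids must be exchange reactions: ",
         paste(ids[!model@rxns$is_exchange[idx]], collapse = ", "))
  if (condition$other_uptakes_closed) {
    ex <- model@rxns$is_exchange & !(model@rxns$id %in% ids)
    model@rxns$lower_bound[ex] <- pmax(model@rxns$lower_bound[ex], 0)
  }
  model@rxns$lower_bound[idx] <- condition$uptake_lower_bound
  if (condition$enforce_ratio) {
    terms <- c(1, -condition$glc_o2_ratio)
    names(terms) <- ids
    tag <- "glc_o2_ratio"
    keep <- vapply(model@couplings,
                   function(cp) !identical(cp$tag, tag), logical(1))
    model@couplings <- c(model@couplings[keep],
                         list(list(terms = terms, sense = "=", rhs = 0,
                                   tag = tag)))
  }
  validObject(model)
  model
}

#' Wild-type flux-simulation adjustments
#'
#' Conditions a model the way the wild-type oxidative pentose phosphate
#' flux simulations were set up: (1) the cytosolic isocitrate dehydrogenase
#' (IDP2/ICDHy) is knocked out, reflecting its downregulation on glucose;
#' (2) a reversible 1:1 oxoadipate/alpha-ketoglutarate mitochondrial
#' antiporter is added; (3) the cytosolic acetaldehyde dehydrogenase
#' (ALD6/ALDD2y) is proportionally capped at 16 % of the glucose uptake
#' rate via the coupling row `v_ALDD2y + 0.16 * v_glc_exchange <= 0`
#' (uptake is negative, so -v_glc is the uptake rate).
#'
#' @param model a [MetabolicModel-class]
#' @param glucose_exchange_id glucose exchange id
#' @param mapping named character vector aliasing the canonical reaction and
#'   metabolite keys to this model's ids. Required keys: ICDHy, ALDD2y,
#'   oxoadipate_c, oxoadipate_m, akg_c, akg_m. Models using the canonical
#'   ids themselves need no mapping.
#' @param ald6_fraction cap fraction (default 0.16)
#' @return the adjusted model
#' @export
applyWildtypeAdjustments <- function(model, glucose_exchange_id,
                                     mapping = character(),
                                     ald6_fraction = 0.16) {
  keys <- c("ICDHy", "ALDD2y", "oxoadipate_c", "oxoadipate_m",
            "akg_c", "akg_m")
  map <- stats::setNames(keys, keys)
  map[names(mapping)] <- mapping
  rx_needed <- map[c("ICDHy", "ALDD2y")]
  missing_rx <- setdiff(rx_needed, model@rxns$id)
  mt_needed <- map[c("oxoadipate_c", "oxoadipate_m", "akg_c", "akg_m")]
  missing_mt <- setdiff(mt_needed, model@mets$id)
  if (length(missing_rx) || length(missing_mt)) {
    miss_keys <- names(map)[map %in% c(missing_rx, missing_mt)]
    stop("model lacks ids for adjustment key(s): ",
         paste(miss_keys, collapse = ", "),
         "; supply `mapping` entries for them")
  }
  .rxnIndex(model, glucose_exchange_id)
  # 1. ICDHy knocked out (direct bound closure; ICDHy need not be flagged
  #    knockable since this is a condition, not a design move)
  i <- .rxnIndex(model, map[["ICDHy"]])
  model@rxns$lower_bound[i] <- 0
  model@rxns$upper_bound[i] <- 0
  # 2. oxoadipate/alpha-ketoglutarate antiporter, reversible 1:1
  anti_id <- "OAA_AKG_ANTIPORT"
  if (!anti_id %in% model@rxns$id) {
    model@rxns <- rbind(model@rxns,
      data.frame(id = anti_id, lower_bound = -.tf_cap, upper_bound = .tf_cap,
                 is_exchange = FALSE, knockable = FALSE, name =
                   "oxoadipate/alpha-ketoglutarate mitochondrial antiporter",
                 stringsAsFactors = FALSE))
    S2 <- cbind(model@S, 0)
    colnames(S2) <- model@rxns$id
    S2[map[["oxoadipate_c"]], anti_id] <- 1
    S2[map[["oxoadipate_m"]], anti_id] <- -1
    S2[map[["akg_c"]], anti_id] <- -1
    S2[map[["akg_m"]], anti_id] <- 1
    model@S <- S2
  }
  # 3. ALD6 cap: v_ALDD2y <= fraction * (-v_glc)
  terms <- c(1, ald6_fraction)
  names(terms) <- c(map[["ALDD2y"]], glucose_exchange_id)
  tag <- "ald6_cap"
  keep <- vapply(model@couplings,
                 function(cp) !identical(cp$tag, tag), logical(1))
  model@couplings <- c(model@couplings[keep],
                       list(list(terms = terms, sense = "<=", rhs = 0,
                                 tag = tag)))
  validObject(model)
  model
}

#' Add a production target exchange
#'
#' Adds an irreversible export reaction for a cytosolic metabolite (the
#' "artificial exchange flux" used as the outer design objective) and
#' returns both the model and the new reaction id.
#'
#' @param model a [MetabolicModel-class]
#' @param metabolite cytosolic metabolite id
#' @param cytosol_compartment compartment code treated as cytosol
#'   (default "c")
#' @param cap upper bound of the export
#' @return list with elements `model` and `target_id`
#' @export
addTarget <- function(model, metabolite, cytosol_compartment = "c",
                      cap = .tf_cap) {
  i <- .metIndex(model, metabolite)
  if (model@mets$compartment[i] != cytosol_compartment)
    stop("target metabolite ", metabolite, " is not cytosolic (compartment ",
         model@mets$compartment[i], ")")
  model <- addExchange(model, metabolite, lb = 0, ub = cap)
  list(model = model, target_id = paste0("EX_", metabolite))
}
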