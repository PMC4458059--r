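# Reaction-quotient Gibbs energy profiling of the tyrosine pathway.
#
# Standard reaction energies (dG0, kJ/mol; computed externally, e.g. by the
# component contribution method at pH 6.5, 25 C) are combined with resolved
# metabolite concentrations through dG = dG0 + R*T*ln Q, with Q the product
# of participant concentrations (mol/L, standard state 1 M) raised to their
# stoichiometric coefficients, products over reactants.

.tf_R_kJ <- 8.314e-3  # gas constant, kJ/mol/K

#' Construct a pathway step for thermodynamic profiling
#'
#' @param id reaction identifier
#' @param stoichiometry named numeric vector of species coefficients
#'   (reactants negative, products positive), or NULL when `equation` given
#' @param dg0 standard reaction Gibbs energy, kJ/mol
#' @param equation optional equation string, e.g.
#'   `"PEP + E4P <=> DAHP + Pi"`; coefficients as numeric prefixes
#' @return a list of class "ThermoReaction"
#' @export
thermoReaction <- function(id, stoichiometry = NULL, dg0 = NA_real_,
                           equation = NULL) {
  if (is.null(stoichiometry)) {
    if (is.null(equation)) stop("give either stoichiometry or equation")
    stoichiometry <- parseReactionEquation(equation)
  }
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0))
    stop("reaction ", id, " needs at least one reactant and one product")
  structure(list(id = id, stoichiometry = stoichiometry, dg0 = dg0),
            class = "ThermoReaction")
}

#' Parse a reaction equation string
#'
#' @param equation e.g. `"A + 2 B <=> C"`; separators `<=>`, `<->` or `=`
#' @return named numeric stoichiometry vector (reactants negative)
#' @export
parseReactionEquation <- function(equation) {
  sides <- strsplit(equation, "<=>|<->|(?<![<>])=(?![<>])", perl = TRUE)[[1]]
  if (length(sides) != 2) stop("equation must have two sides: ", equation)
  parseSide <- function(s, sign) {
    terms <- trimws(strsplit(s, "\\+")[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (tm in terms) {
      mm <- regmatches(tm, regexec("^([0-9.]+)\\s+(.+)$", tm))[[1]]
      if (length(mm) == 3) {
        out[mm[3]] <- sign * as.numeric(mm[2])
      } else {
        out[tm] <- sign * 1
      }
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], 1)
  both <- intersect(names(lhs), names(rhs))
  st <- c(lhs, rhs[setdiff(names(rhs), both)])
  st[both] <- lhs[both] + rhs[both]
  st[st != 0]
}

#' Literature cofactor concentrations
#'
#' Cytosolic cofactor concentrations used for the pathway profile, in
#' mol/L: NADPH 151.1 mM, NADP 20.37 mM, NADH 174.8 mM, NAD 862.9 mM, and
#' ATP 4.25, ADP 0.93, Pi 6.6 — the latter three carried in molar units
#' exactly as reported by their source even though molar magnitudes are
#' physiologically surprising; override entries via the `...` argument when
#' a corrected set is preferred.
#'
#' @param ... named overrides in mol/L
#' @return named numeric vector, mol/L
#' @export
cofactorConcentrations <- function(...) {
  x <- c(NADPH = 0.1511, NADP = 0.02037, NADH = 0.1748, NAD = 0.8629,
         ATP = 4.25, ADP = 0.93, Pi = 6.6)
  over <- c(...)
  x[names(over)] <- over
  x
}

#' Resolve pathway species concentrations
#'
#' Builds a concentration table (mol/L) for a set of pathway species under
#' explicit provenance rules: species measured intracellularly enter via
#' their specific concentration (umol/g DCW) converted through the
#' cytosolic volume; species only measured extracellularly use the
#' extracellular concentration (mM) as a cytosolic proxy; cofactors come
#' from the literature table; everything else defaults to 1 mM. Each
#' species carries exactly one provenance tag.
#'
#' @param species character vector of species ids to resolve
#' @param measured_intra named vector, umol/g DCW
#' @param measured_extra named vector, mM
#' @param cofactors named vector, mol/L (default [cofactorConcentrations()])
#' @param rules named character vector mapping species to a provenance
#'   class among "measured_intracellular", "extracellular_proxy",
#'   "literature_cofactor", "default"; unlisted species default
#' @param constants cell constants for the intracellular conversion
#'   (see [cellConstants()])
#' @return data.frame with columns species, conc_M, provenance
#' @export
resolveConcentrations <- function(species,
                                  measured_intra = numeric(),
                                  measured_extra = numeric(),
                                  cofactors = cofactorConcentrations(),
                                  rules = character(),
                                  constants = cellConstants()) {
  prov <- rep("default", length(species))
  names(prov) <- species
  known <- intersect(names(rules), species)
  bad <- setdiff(rules[known],
                 c("measured_intracellular", "extracellular_proxy",
                   "literature_cofactor", "default"))
  if (length(bad)) stop("unknown provenance class(es): ",
                        paste(unique(bad), collapse = ", "))
  prov[known] <- rules[known]
  conc <- numeric(length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    conc[i] <- switch(prov[i],
      measured_intracellular = {
        if (!sp %in% names(measured_intra))
          stop("species ", sp, " tagged measured_intracellular but no ",
               "intracellular measurement supplied")
        cytosolicConcentration(measured_intra[[sp]], constants) / 1000
      },
      extracellular_proxy = {
        if (!sp %in% names(measured_extra))
          stop("species ", sp, " tagged extracellular_proxy but no ",
               "extracellular measurement supplied")
        measured_extra[[sp]] / 1000
      },
      literature_cofactor = {
        if (!sp %in% names(cofactors))
          stop("species ", sp, " tagged literature_cofactor but absent ",
               "from the cofactor table")
        cofactors[[sp]]
      },
      default = 1e-3)
  }
  if (any(conc <= 0)) stop("non-positive concentration for: ",
                           paste(species[conc <= 0], collapse = ", "))
  data.frame(species = species, conc_M = conc, provenance = prov,
             row.names = NULL, stringsAsFactors = FALSE)
}

.concLookup <- function(conc) {
  if (is.data.frame(conc)) stats::setNames(conc$conc_M, conc$species)
  else conc
}

#' Reaction quotient
#'
#' Q = product of product concentrations raised to their coefficients over
#' product of reactant concentrations raised to theirs, all in mol/L.
#' Species on the ignore list (water, protons by default; their treatment
#' is inside the transformed dG0) are skipped.
#'
#' @param reaction a [thermoReaction()]
#' @param conc concentration table from [resolveConcentrations()] or a
#'   named vector in mol/L
#' @param ignore species excluded from Q
#' @return dimensionless Q
#' @export
reactionQuotient <- function(reaction, conc,
                             ignore = c("h2o", "H2O", "h", "H")) {
  cv <- .concLookup(conc)
  st <- reaction$stoichiometry
  st <- st[!names(st) %in% ignore]
  miss <- setdiff(names(st), names(cv))
  if (length(miss))
    stop("no concentration for species: ", paste(miss, collapse = ", "))
  x <- cv[names(st)]
  if (any(!is.finite(x) | x <= 0))
    stop("non-positive concentration for: ",
         paste(names(st)[!is.finite(x) | x <= 0], collapse = ", "))
  exp(sum(st * log(x)))
}

#' Gibbs energy of a pathway step at given concentrations
#'
#' dG = dG0 + R*T*ln Q with R = 8.314 J/mol/K.
#'
#' @inheritParams reactionQuotient
#' @param temperature_K temperature (default 298.15 K, i.e. 25 C)
#' @return kJ/mol
#' @export
deltaG <- function(reaction, conc, temperature_K = 298.15,
                   ignore = c("h2o", "H2O", "h", "H")) {
  if (is.na(reaction$dg0)) stop("reaction ", reaction$id, " has no dg0")
  Q <- reactionQuotient(reaction, conc, ignore)
  reaction$dg0 + .tf_R_kJ * temperature_K * log(Q)
}

#' Gibbs energy profile of a pathway
#'
#' Computes Q and dG for every step, ranks steps by |dG| (rank 1 =
#' furthest from equilibrium, hence the step most plausibly under active
#' regulation), and performs an additivity audit: when intermediates cancel
#' along the chain, the sum of step dG values equals the dG of the net
#' reaction.
#'
#' @param pathway list of [thermoReaction()] in pathway order
#' @param conc concentration table or named vector (mol/L)
#' @param temperature_K temperature
#' @param ignore species excluded from Q
#' @return a [ThermoProfile-class]
#' @export
pathwayProfile <- function(pathway, conc, temperature_K = 298.15,
                           ignore = c("h2o", "H2O", "h", "H")) {
  if (!length(pathway)) stop("empty pathway")
  cv <- .concLookup(conc)
  steps <- do.call(rbind, lapply(pathway, function(rx) {
    Q <- reactionQuotient(rx, cv, ignore)
    data.frame(reaction_id = rx$id, dg0 = rx$dg0, Q = Q,
               dg = rx$dg0 + .tf_R_kJ * temperature_K * log(Q),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(steps$reaction_id))
    stop("pathway contains duplicate step ids")
  steps$rank <- rank(-abs(steps$dg), ties.method = "first")
  # net reaction and additivity audit
  net <- numeric(0)
  for (rx in pathway) {
    st <- rx$stoichiometry
    for (spn in names(st)) {
      cur <- if (spn %in% names(net)) net[[spn]] else 0
      net[spn] <- cur + st[[spn]]
    }
  }
  net <- net[abs(net) > 1e-12]
  net_rx <- list(id = "net", stoichiometry = net,
                 dg0 = sum(steps$dg0))
  class(net_rx) <- "ThermoReaction"
  cancelled <- any(net < 0) && any(net > 0)
  net_dg <- if (cancelled)
    deltaG(net_rx, cv, temperature_K, ignore) else NA_real_
  additivity <- list(sum_dg = sum(steps$dg), net_dg = net_dg,
                     cancelled = cancelled,
                     residual = if (cancelled) sum(steps$dg) - net_dg
                                else NA_real_)
  used <- unique(unlist(lapply(pathway,
                               function(rx) names(rx$stoichiometry))))
  used <- setdiff(used, ignore)
  provenance <- if (is.data.frame(conc)) {
    conc[conc$species %in% used, c("species", "provenance")]
  } else {
    data.frame(species = used, provenance = "supplied",
               stringsAsFactors = FALSE)
  }
  new("ThermoProfile", steps = steps, provenance = provenance,
      additivity = additivity, temperature_K = temperature_K)
}

#' Read a pathway specification TSV
#'
#' Expects columns `reaction_id`, `equation`, `dg0_kj_mol`.
#'
#' @param path TSV path
#' @return list of [thermoReaction()]
#' @export
readPathway <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "equation", "dg0_kj_mol")
  if (!all(need %in% names(df)))
    stop("pathway TSV needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    thermoReaction(df$reaction_id[i], equation = df$equation[i],
                   dg0 = df$dg0_kj_mol[i]))
}

#' Write a ThermoProfile as TSV
#'
#' @param profile a [ThermoProfile-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeProfile <- function(profile, path) {
  utils::write.table(profile@steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
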