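#' Read a metabolic model
#'
#' Two formats are supported. The package's own JSON dialect (schema below)
#' is the native round-trip format used for toy fixtures; SBML Level 3 with
#' the `fbc` package (the format genome-scale reconstructions such as iMM904
#' are distributed in) is supported read-only.
#'
#' JSON schema: an object with `metabolites` (array of \{id, compartment,
#' carbon_count, name\}), `reactions` (array of \{id, stoichiometry:
#' \{metabolite: coefficient\}, lower_bound, upper_bound, is_exchange,
#' knockable\}), `objective` (reaction id) and optional `couplings` (array
#' of \{terms: \{reaction: coefficient\}, sense, rhs\}).
#'
#' @param path file path
#' @param format "json" or "sbml"; default guessed from the extension
#' @return a validated [MetabolicModel-class]
#' @export
readModel <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") .readModelJSON(path) else .readModelSBML(path)
}

.readModelJSON <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON model file '", path,
                                           "': ", conditionMessage(e)))
  for (key in c("metabolites", "reactions", "objective"))
    if (is.null(doc[[key]]))
      stop("model JSON missing required element '", key, "'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id) || is.null(m$compartment))
      stop("metabolite entry missing id/compartment")
    data.frame(id = m$id, compartment = m$compartment,
               carbon_count = if (is.null(m$carbon_count)) 0L
                              else as.integer(m$carbon_count),
               name = if (is.null(m$name)) m$id else m$name,
               stringsAsFactors = FALSE)
  }))
  stoich <- list()
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoichiometry))
      stop("reaction entry missing id/stoichiometry")
    data.frame(id = r$id,
               lower_bound = if (is.null(r$lower_bound)) -.tf_cap
                             else as.numeric(r$lower_bound),
               upper_bound = if (is.null(r$upper_bound)) .tf_cap
                             else as.numeric(r$upper_bound),
               is_exchange = isTRUE(r$is_exchange),
               knockable = isTRUE(r$knockable),
               stringsAsFactors = FALSE)
  }))
  for (r in doc$reactions)
    stoich[[r$id]] <- unlist(r$stoichiometry)
  couplings <- lapply(doc$couplings %||% list(), function(cp)
    list(terms = unlist(cp$terms), sense = cp$sense, rhs = as.numeric(cp$rhs)))
  m <- metabolicModel(mets, rxns, stoich, objective_id = doc$objective,
                      couplings = couplings)
  # JSON round-trips carry knockable explicitly; keep them verbatim
  m@rxns$knockable <- vapply(doc$reactions, function(r) isTRUE(r$knockable),
                             logical(1))
  validObject(m)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic model to the JSON dialect
#'
#' Lossless inverse of [readModel()] for the JSON format: all bounds,
#' flags, couplings and the objective are preserved bit-exactly.
#'
#' @param model a [MetabolicModel-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeModel <- function(model, path) {
  validObject(model)
  mets <- lapply(seq_len(nrow(model@mets)), function(i)
    list(id = model@mets$id[i], compartment = model@mets$compartment[i],
         carbon_count = model@mets$carbon_count[i],
         name = model@mets$name[i]))
  rxns <- lapply(seq_len(nrow(model@rxns)), function(i) {
    rid <- model@rxns$id[i]
    coef <- model@S[, rid]
    coef <- coef[coef != 0]
    list(id = rid, stoichiometry = as.list(coef),
         lower_bound = model@rxns$lower_bound[i],
         upper_bound = model@rxns$upper_bound[i],
         is_exchange = model@rxns$is_exchange[i],
         knockable = model@rxns$knockable[i])
  })
  doc <- list(metabolites = mets, reactions = rxns,
              objective = model@objective_id,
              couplings = lapply(model@couplings, function(cp)
                list(terms = as.list(cp$terms), sense = cp$sense,
                     rhs = cp$rhs)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Minimal SBML L3 + fbc reader: species, reactions with speciesReference
# stoichiometries, fbc flux bounds via parameters, fbc active objective.
.readModelSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  find <- function(x, xp) xml2::xml_find_all(x, xp, ns)
  attr1 <- function(nodes, a) xml2::xml_attr(nodes, a)

  params <- find(doc, ".//s:listOfParameters/s:parameter")
  pval <- as.numeric(attr1(params, "value"))
  names(pval) <- attr1(params, "id")

  sp <- find(doc, ".//s:listOfSpecies/s:species")
  if (!length(sp)) stop("SBML file has no species")
  boundary <- attr1(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(id = attr1(sp, "id"),
                     compartment = attr1(sp, "compartment"),
                     carbon_count = 0L,
                     name = ifelse(is.na(attr1(sp, "name")),
                                   attr1(sp, "id"), attr1(sp, "name")),
                     stringsAsFactors = FALSE)
  # carbon counts from fbc chemical formulas where present
  formula <- xml2::xml_attr(sp, "fbc:chemicalFormula",
                            xml2::xml_ns(doc))
  nc <- suppressWarnings(ifelse(is.na(formula), 0L,
    vapply(formula, function(f) {
      mm <- regmatches(f, regexec("C([0-9]*)([A-Z]|$)", f))[[1]]
      if (length(mm) < 2 || !nzchar(mm[1])) return(0L)
      if (!nzchar(mm[2])) 1L else as.integer(mm[2])
    }, integer(1))))
  mets$carbon_count <- as.integer(nc)
  mets <- mets[!boundary, , drop = FALSE]

  rnodes <- find(doc, ".//s:listOfReactions/s:reaction")
  if (!length(rnodes)) stop("SBML file has no reactions")
  stoich <- list(); rows <- list()
  for (rn in rnodes) {
    rid <- xml2::xml_attr(rn, "id")
    reac <- find(rn, "./s:listOfReactants/s:speciesReference")
    prod <- find(rn, "./s:listOfProducts/s:speciesReference")
    co <- c(-as.numeric(ifelse(is.na(attr1(reac, "stoichiometry")), 1,
                               attr1(reac, "stoichiometry"))),
            as.numeric(ifelse(is.na(attr1(prod, "stoichiometry")), 1,
                              attr1(prod, "stoichiometry"))))
    names(co) <- c(attr1(reac, "species"), attr1(prod, "species"))
    co <- co[names(co) %in% mets$id]
    co <- tapply(co, names(co), sum)    # merge duplicated species refs
    if (!length(co)) stop("SBML reaction ", rid,
                          " has no non-boundary species")
    stoich[[rid]] <- co
    lbp <- xml2::xml_attr(rn, "fbc:lowerFluxBound", xml2::xml_ns(doc))
    ubp <- xml2::xml_attr(rn, "fbc:upperFluxBound", xml2::xml_ns(doc))
    rev <- xml2::xml_attr(rn, "reversible") %in% "true"
    lbv <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]]
           else if (rev) -.tf_cap else 0
    ubv <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else .tf_cap
    rows[[rid]] <- data.frame(id = rid, lower_bound = lbv, upper_bound = ubv,
                              stringsAsFactors = FALSE)
  }
  rxns <- do.call(rbind, rows)
  objn <- find(doc, ".//*[local-name()='fluxObjective']")
  if (!length(objn)) stop("SBML file declares no flux objective")
  obj_id <- xml2::xml_attr(objn[[1]], "reaction")
  if (is.na(obj_id))
    obj_id <- xml2::xml_attr(objn[[1]], "fbc:reaction", xml2::xml_ns(doc))
  if (is.na(obj_id) || !obj_id %in% rxns$id)
    stop("SBML objective reaction not found")
  metabolicModel(mets, rxns, stoich, objective_id = obj_id)
}

#' Write a flux solution as TSV
#'
#' @param solution a [FluxSolution-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeFluxes <- function(solution, path) {
  stopifnot(is(solution, "FluxSolution"))
  df <- data.frame(reaction_id = names(solution@fluxes),
                   flux = unname(solution@fluxes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
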