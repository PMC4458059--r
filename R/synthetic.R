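# Synthetic inputs with known ground truth: toy metabolic models whose
# growth-coupled optima are verified by exhaustive search at generation
# time, a "deceptive" landscape that defeats single-stage local search but
# yields to the two-step intermediate-target bootstrap, and simulated
# fermentation time courses (logistic growth, exponential-rise product
# curves, multiplicative log-normal noise).

#' Specification for the toy growth-coupling model
#'
#' The generated network mirrors, at miniature scale, the structural
#' features a genome-scale yeast model brings to strain design: glucose and
#' oxygen exchanges, a glycolysis-like trunk producing pyruvate, NADH and
#' ATP, an oxidative-PPP-like branch co-producing a pathway precursor and
#' NADPH (the ZWF1 analog), a transhydrogenase-like NADPH sink, respiratory
#' and fermentative NADH reoxidation, a linear three-step shikimate-like
#' pathway to the target ("tyr"), a precursor overflow valve, biomass and
#' ATP maintenance.
#'
#' @param n_branch_reactions number of parallel fermentation branches
#' @param include_shikimate_chain include the target pathway (without it
#'   the model has no target path and generation fails its self-check)
#' @param include_cofactor_cycle include the transhydrogenase-like NADPH
#'   sink; without it the NADPH pool is rigidly tied to growth and the
#'   coupled optimum changes
#' @param coupled_optimum declared optimum: list(knockouts, target_flux);
#'   NULL accepts the brute-force result as ground truth
#' @param seed integer seed (the topology is deterministic; the seed is
#'   recorded in the ground truth)
#' @return list of class "ToyModelSpec"
#' @export
toyModelSpec <- function(n_branch_reactions = 1,
                         include_shikimate_chain = TRUE,
                         include_cofactor_cycle = TRUE,
                         coupled_optimum = if (n_branch_reactions == 1 &&
                                               include_shikimate_chain &&
                                               include_cofactor_cycle)
                           list(knockouts = "FERM", target_flux = 95 / 26)
                         else NULL,
                         seed = 1L) {
  stopifnot(n_branch_reactions >= 1)
  structure(list(n_branch_reactions = n_branch_reactions,
                 include_shikimate_chain = include_shikimate_chain,
                 include_cofactor_cycle = include_cofactor_cycle,
                 coupled_optimum = coupled_optimum, seed = seed),
            class = "ToyModelSpec")
}

.toyMets <- function(ids, compartment, carbon) {
  data.frame(id = ids, compartment = compartment, carbon_count = carbon,
             name = ids, stringsAsFactors = FALSE)
}

.toyRxn <- function(id, lb = 0, ub = .tf_cap, is_exchange = FALSE,
                    knockable = NA) {
  data.frame(id = id, lower_bound = lb, upper_bound = ub,
             is_exchange = is_exchange, knockable = knockable,
             stringsAsFactors = FALSE)
}

#' Generate the toy growth-coupling model
#'
#' Builds the network described in [toyModelSpec()] and self-verifies
#' before returning: the target exchange is added, every knockout set of
#' size <= 2 is enumerated with [bruteForceDesign()], and the result must
#' match the declared coupled optimum (when one is declared). A model that
#' fails its self-check is never returned. The emitted model does NOT
#' contain the target exchange; add it with [addTarget()] (metabolite
#' "tyr").
#'
#' @param spec a [toyModelSpec()]
#' @return a [MetabolicModel-class]; attribute "ground_truth" carries the
#'   verified optimum
#' @export
makeToyCouplingModel <- function(spec = toyModelSpec()) {
  stopifnot(inherits(spec, "ToyModelSpec"))
  mets <- rbind(
    .toyMets(c("glc_e", "glc"), c("e", "c"), c(6L, 6L)),
    .toyMets(c("o2_e", "o2"), c("e", "c"), c(0L, 0L)),
    .toyMets(c("pyr", "nadh", "nadph", "atp"), "c", c(3L, 0L, 0L, 0L)),
    .toyMets(c("pre", "shk1", "shk2", "tyr"), "c", c(4L, 7L, 7L, 9L)),
    .toyMets(c("etoh", "etoh_e"), c("c", "e"), c(2L, 2L)))
  rxns <- rbind(
    .toyRxn("EX_glc", -10, 0, TRUE, FALSE),
    .toyRxn("T_glc"),
    .toyRxn("EX_o2", -10, 0, TRUE, FALSE),
    .toyRxn("T_o2"),
    .toyRxn("GLYC"),
    .toyRxn("ZWF"),
    .toyRxn("RESP"),
    .toyRxn("NADHOX"),
    .toyRxn("T_etoh"),
    .toyRxn("EX_etoh", 0, .tf_cap, TRUE, FALSE),
    .toyRxn("EX_pre", 0, .tf_cap, TRUE, FALSE),
    .toyRxn("BIOMASS", 0, .tf_cap, FALSE, FALSE),
    .toyRxn("ATPM", 0, .tf_cap, FALSE, FALSE))
  stoich <- list(
    EX_glc = c(glc_e = -1),
    T_glc = c(glc_e = -1, glc = 1),
    EX_o2 = c(o2_e = -1),
    T_o2 = c(o2_e = -1, o2 = 1),
    GLYC = c(glc = -1, pyr = 2, nadh = 2, atp = 2),
    ZWF = c(glc = -1, pre = 1, nadph = 2),
    RESP = c(pyr = -1, o2 = -1, atp = 2),
    NADHOX = c(nadh = -1, o2 = -0.5, atp = 1.5),
    T_etoh = c(etoh = -1, etoh_e = 1),
    EX_etoh = c(etoh_e = -1),
    EX_pre = c(pre = -1),
    BIOMASS = c(pyr = -1, nadph = -1, atp = -8),
    ATPM = c(atp = -1))
  for (b in seq_len(spec$n_branch_reactions)) {
    id <- if (b == 1) "FERM" else paste0("FERM", b)
    rxns <- rbind(rxns, .toyRxn(id))
    stoich[[id]] <- c(pyr = -1, nadh = -1, etoh = 1)
  }
  if (spec$include_cofactor_cycle) {
    rxns <- rbind(rxns, .toyRxn("THD"))
    stoich$THD <- c(nadph = -1, nadh = 1)
  }
  if (spec$include_shikimate_chain) {
    rxns <- rbind(rxns, .toyRxn("SHK1"), .toyRxn("SHK2"), .toyRxn("SHK3"))
    stoich$SHK1 <- c(pre = -1, pyr = -1, shk1 = 1)
    stoich$SHK2 <- c(shk1 = -1, nadh = -1, shk2 = 1)
    stoich$SHK3 <- c(shk2 = -1, tyr = 1)
  }
  rxns$knockable[is.na(rxns$knockable)] <- TRUE
  model <- metabolicModel(mets, rxns, stoich, objective_id = "BIOMASS",
                          atpm_id = "ATPM")
  # self-check: the declared coupled optimum must be reproduced by
  # exhaustive enumeration on the target-extended model
  if (!spec$include_shikimate_chain)
    stop("toy model generation failed self-check: no target pathway, ",
         "the target metabolite is unreachable")
  tg <- addTarget(model, "tyr")
  pr <- designProblem(tg$model, tg$target_id, max_knockouts = 2)
  bf <- bruteForceDesign(pr)
  if (!isTRUE(bf@coupled))
    stop("toy model generation failed self-check: no coupled design ",
         "within 2 knockouts")
  if (!is.null(spec$coupled_optimum)) {
    want <- spec$coupled_optimum
    if (!setequal(bf@knockouts, want$knockouts) ||
        abs(bf@target_min - want$target_flux) > 1e-5)
      stop("toy model generation failed self-check: brute force found {",
           paste(bf@knockouts, collapse = ","), "} at ",
           format(bf@target_min), " instead of the declared {",
           paste(want$knockouts, collapse = ","), "} at ",
           format(want$target_flux))
  }
  attr(model, "ground_truth") <- list(
    knockouts = bf@knockouts, target_flux = bf@target_min,
    growth = bf@growth, seed = spec$seed)
  model
}

#' Generate the deceptive design landscape
#'
#' A network on which single-stage GDLS from the wild type fails while the
#' two-step intermediate-target bootstrap succeeds. A ZWF1-like reaction
#' co-produces NADPH (required for growth) and the pathway precursor m1, so
#' m1 production is growth-proportional; the route onward costs ATP, and
#' three independent overflow valves (at m1, at the intermediate "int", and
#' at the final product "tyr2") must ALL be closed before the final product
#' is growth-coupled. No knockout set of size <= 2 couples tyr2, so local
#' search with neighborhood 2 cannot leave the wild type; the intermediate,
#' however, is coupled by closing just the two upstream valves, and that
#' solution lies in the final target's basin.
#'
#' Generation self-verifies all three properties (single-stage failure,
#' two-step success, existence of a coupled set by brute force) and fails
#' loudly otherwise.
#'
#' @param seed integer seed recorded in the ground truth
#' @param verify run the (slower) generation-time verification
#' @return a [MetabolicModel-class] with attribute "ground_truth";
#'   intermediate metabolite "int", final metabolite "tyr2"
#' @export
makeDeceptiveModel <- function(seed = 1L, verify = TRUE) {
  mets <- rbind(
    .toyMets(c("glc_e", "glc"), c("e", "c"), c(6L, 6L)),
    .toyMets(c("o2_e", "o2"), c("e", "c"), c(0L, 0L)),
    .toyMets(c("pyr", "nadh", "nadph", "atp"), "c", c(3L, 0L, 0L, 0L)),
    .toyMets(c("m1", "int", "tyr2"), "c", c(4L, 7L, 9L)),
    .toyMets(c("etoh", "w1", "w2", "w3"), "c", c(2L, 4L, 7L, 9L)))
  rxns <- rbind(
    .toyRxn("EX_glc", -10, 0, TRUE, FALSE),
    .toyRxn("T_glc"),
    .toyRxn("EX_o2", -10, 0, TRUE, FALSE),
    .toyRxn("T_o2"),
    .toyRxn("GLYC"),
    .toyRxn("ZWF2"),
    .toyRxn("FERM"),
    .toyRxn("RESP"),
    .toyRxn("NADHOX"),
    .toyRxn("S1"),
    .toyRxn("S2"),
    .toyRxn("V1"),
    .toyRxn("V2"),
    .toyRxn("V3"),
    .toyRxn("EX_etoh", 0, .tf_cap, TRUE, FALSE),
    .toyRxn("EX_w1", 0, .tf_cap, TRUE, FALSE),
    .toyRxn("EX_w2", 0, .tf_cap, TRUE, FALSE),
    .toyRxn("EX_w3", 0, .tf_cap, TRUE, FALSE),
    .toyRxn("BIOMASS", 0, .tf_cap, FALSE, FALSE),
    .toyRxn("ATPM", 0, .tf_cap, FALSE, FALSE))
  stoich <- list(
    EX_glc = c(glc_e = -1),
    T_glc = c(glc_e = -1, glc = 1),
    EX_o2 = c(o2_e = -1),
    T_o2 = c(o2_e = -1, o2 = 1),
    GLYC = c(glc = -1, pyr = 2, nadh = 2, atp = 2),
    ZWF2 = c(glc = -1, m1 = 1, nadph = 2),
    FERM = c(pyr = -1, nadh = -1, etoh = 1),
    RESP = c(pyr = -1, o2 = -1, atp = 2),
    NADHOX = c(nadh = -1, o2 = -0.5, atp = 1.5),
    S1 = c(m1 = -1, atp = -1, int = 1),
    S2 = c(int = -1, nadph = -1, tyr2 = 1),
    V1 = c(m1 = -1, w1 = 1),
    V2 = c(int = -1, w2 = 1),
    V3 = c(tyr2 = -1, w3 = 1),
    EX_etoh = c(etoh = -1),
    EX_w1 = c(w1 = -1),
    EX_w2 = c(w2 = -1),
    EX_w3 = c(w3 = -1),
    BIOMASS = c(pyr = -1, nadph = -1, atp = -8),
    ATPM = c(atp = -1))
  rxns$knockable[is.na(rxns$knockable)] <- TRUE
  model <- metabolicModel(mets, rxns, stoich, objective_id = "BIOMASS",
                          atpm_id = "ATPM")
  gt <- list(intermediate = "int", final = "tyr2",
             coupled_set = c("V1", "V2", "V3"), seed = seed)
  if (verify) {
    tg <- addTarget(model, "tyr2")
    single <- gdls(designProblem(tg$model, tg$target_id,
                                 max_knockouts = 10, neighborhood_size = 2))
    if (single@target_min > .tf_couple_tol || length(single@knockouts))
      stop("deceptive model generation failed self-check: single-stage ",
           "local search escaped the wild type")
    two <- twoStepDesign(model, "int", "tyr2", max_knockouts = 10,
                         neighborhood_size = 2)
    if (!isTRUE(two@coupled))
      stop("deceptive model generation failed self-check: two-step search ",
           "found no coupled design")
    bf <- bruteForceDesign(designProblem(tg$model, tg$target_id,
                                         max_knockouts = 3))
    if (!isTRUE(bf@coupled))
      stop("deceptive model generation failed self-check: no coupled set ",
           "within 3 knockouts exists")
    gt$coupled_set <- bf@knockouts
    gt$coupled_flux <- bf@target_min
    gt$two_step_flux <- two@target_min
  }
  attr(model, "ground_truth") <- gt
  model
}

#' Specification for a simulated fermentation time course
#'
#' @param mu maximum specific growth rate, 1/h
#' @param carrying_capacity stationary biomass, g DCW/L
#' @param yield_xs growth yield, g DCW/g glucose
#' @param glucose0 initial glucose, g/L
#' @param x0 inoculation biomass, g DCW/L
#' @param metabolites named list of c(A, k): exponential-rise parameters
#'   per species column (units: umol/g DCW for `__intra` columns, mM for
#'   `__extra`)
#' @param titers named list of c(a, b, t0): sigmoidal titer parameters per
#'   species column
#' @param noise_sigma relative (log-normal) noise sd; 0 for noiseless
#' @param n_replicates biological replicates
#' @param times sampling times, h
#' @param seed mandatory integer seed
#' @return list of class "FermentationSpec"
#' @export
fermentationSpec <- function(mu = 0.16, carrying_capacity = 0.08,
                             yield_xs = 0.004, glucose0 = 20,
                             x0 = carrying_capacity / 400,
                             metabolites = list(
                               TYR__intra = c(A = 520, k = 0.08),
                               SHIK__intra = c(A = 60, k = 0.10)),
                             titers = list(COU__extra = c(a = 0.12, b = 6,
                                                          t0 = 24)),
                             noise_sigma = 0.05, n_replicates = 3,
                             times = c(0, 2, 4, 6, 8, 12, 16, 20, 24, 30,
                                       36, 42, 48, 60, 72, 84, 96),
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for simulated time courses")
  stopifnot(mu > 0, carrying_capacity > 0, yield_xs > 0, glucose0 > 0,
            x0 > 0, noise_sigma >= 0, n_replicates >= 1)
  structure(list(mu = mu, carrying_capacity = carrying_capacity,
                 yield_xs = yield_xs, glucose0 = glucose0, x0 = x0,
                 metabolites = metabolites, titers = titers,
                 noise_sigma = noise_sigma, n_replicates = n_replicates,
                 times = times, seed = as.integer(seed)),
            class = "FermentationSpec")
}

#' Simulate a fermentation time course
#'
#' Biomass follows logistic growth X(t) = K X0 e^(mu t) / (K + X0
#' (e^(mu t) - 1)); glucose is depleted as (X - X0)/Y_XS; each metabolite
#' follows A (1 - e^(-k t)) and each titer a 3-parameter sigmoid; all
#' measured columns (including OD) receive multiplicative log-normal noise
#' exp(N(0, sigma^2)), which keeps concentrations positive. Replicates are
#' independent noise draws. The embedded ground truth (the spec itself) is
#' attached as attribute "ground_truth".
#'
#' @param spec a [fermentationSpec()] (seed mandatory)
#' @param constants a [cellConstants()] for the OD conversion
#' @return data.frame with columns time_h, replicate, od600, glucose_gL and
#'   one column per configured species
#' @export
simulateTimecourse <- function(spec, constants = cellConstants()) {
  stopifnot(inherits(spec, "FermentationSpec"))
  set.seed(spec$seed)
  t <- spec$times
  K <- spec$carrying_capacity; X0 <- spec$x0; mu <- spec$mu
  X <- K * X0 * exp(mu * t) / (K + X0 * (exp(mu * t) - 1))
  glc <- pmax(spec$glucose0 - (X - X0) / spec$yield_xs, 0)
  noise <- function(n) if (spec$noise_sigma == 0) rep(1, n)
                       else exp(stats::rnorm(n, 0, spec$noise_sigma))
  out <- list()
  for (r in seq_len(spec$n_replicates)) {
    df <- data.frame(time_h = t, replicate = r,
                     od600 = X / (constants$dcw_per_od) * noise(length(t)),
                     glucose_gL = glc * noise(length(t)))
    for (sp in names(spec$metabolites)) {
      p <- spec$metabolites[[sp]]
      df[[sp]] <- p[["A"]] * (1 - exp(-p[["k"]] * t)) * noise(length(t))
    }
    for (sp in names(spec$titers)) {
      p <- spec$titers[[sp]]
      df[[sp]] <- p[["a"]] / (1 + exp(-(t - p[["t0"]]) / p[["b"]])) *
        noise(length(t))
    }
    out[[r]] <- df
  }
  res <- do.call(rbind, out)
  attr(res, "ground_truth") <- spec
  res
}
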