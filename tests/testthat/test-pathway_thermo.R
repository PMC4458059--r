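test_that("reaction quotients follow the products-over-reactants convention", {
  conc <- c(A = 0.001, B = 0.001, C = 0.02)
  rx <- thermoReaction("iso", c(A = -1, B = 1))
  expect_equal(reactionQuotient(rx, conc), 1)      # [A]=[B] -> Q=1
  rx2 <- thermoReaction("dimer", c(A = -2, B = 1))
  expect_equal(reactionQuotient(rx2, conc), 0.001 / 0.001^2)  # = 1000
  # cofactor ratio at the literature values: Q = 151.1/20.37
  rx3 <- thermoReaction("redox", c(A = -1, NADP = -1, B = 1, NADPH = 1))
  tab <- resolveConcentrations(c("A", "B", "NADP", "NADPH"),
                               rules = c(NADP = "literature_cofactor",
                                         NADPH = "literature_cofactor"))
  expect_equal(reactionQuotient(rx3, tab), 151.1 / 20.37, tolerance = 1e-9)
  expect_equal(reactionQuotient(rx3, tab), 7.418, tolerance = 1e-3)
})

test_that("quotients reject missing and non-positive concentrations and skip water", {
  rx <- thermoReaction("r", c(A = -1, B = 1, h2o = 1))
  expect_error(reactionQuotient(rx, c(A = 0.001)), "B")
  expect_error(reactionQuotient(rx, c(A = 0, B = 0.001)), "A")
  # water excluded by the ignore list
  expect_equal(reactionQuotient(rx, c(A = 0.001, B = 0.001)), 1)
})

test_that("deltaG follows dG0 + RT ln Q", {
  rx <- thermoReaction("r", c(A = -1, B = 1), dg0 = 0)
  expect_equal(deltaG(rx, c(A = 1e-3, B = 1e-3)), 0)          # Q=1
  expect_equal(deltaG(rx, c(A = 1e-3, B = 1e-2)),             # Q=10
               8.314e-3 * 298.15 * log(10), tolerance = 1e-12)
  expect_equal(8.314 * 298.15 * log(10) / 1000, 5.708, tolerance = 1e-3)
  rx2 <- thermoReaction("r2", c(A = -1, B = 1), dg0 = -20)
  expect_equal(deltaG(rx2, c(A = 1e-3, B = 1e-3 * exp(10))),
               -20 + 8.314e-3 * 298.15 * 10, tolerance = 1e-9)
  expect_equal(-20 + 8.314e-3 * 298.15 * 10, 4.79, tolerance = 1e-2)
  # strictly increasing in Q at fixed dG0
  qs <- 10^seq(-3, 3, by = 0.5)
  dgs <- vapply(qs, function(q)
    deltaG(rx, c(A = 1e-3, B = 1e-3 * q)), numeric(1))
  expect_true(all(diff(dgs) > 0))
})

test_that("concentration resolution applies the provenance rules", {
  tab <- resolveConcentrations(
    species = c("PEP", "TYR", "CHOR", "DAHP", "3DHQ", "NADPH", "NAD"),
    measured_intra = c(PEP = 10, TYR = 520),
    measured_extra = c(CHOR = 0.8),
    rules = c(PEP = "measured_intracellular",
              TYR = "measured_intracellular",
              CHOR = "extracellular_proxy",
              NADPH = "literature_cofactor",
              NAD = "literature_cofactor"))
  look <- setNames(tab$conc_M, tab$species)
  prov <- setNames(tab$provenance, tab$species)
  # 520 umol/g DCW over 2.7 mL/g -> 192.6 mM -> 0.1926 M
  expect_equal(look[["TYR"]], 0.1926, tolerance = 1e-3)
  expect_equal(look[["CHOR"]], 0.0008)          # extracellular proxy, mM -> M
  expect_equal(look[["DAHP"]], 1e-3)            # unmeasured -> 1 mM default
  expect_equal(look[["3DHQ"]], 1e-3)
  expect_equal(look[["NADPH"]], 0.1511)
  expect_identical(unname(prov[c("DAHP", "3DHQ")]), rep("default", 2))
  expect_identical(unname(prov[["TYR"]]), "measured_intracellular")
  # measured provenance without a measurement is an error
  expect_error(resolveConcentrations("X",
    rules = c(X = "measured_intracellular")), "no intracellular")
  expect_error(resolveConcentrations("X",
    rules = c(X = "weird_class")), "provenance")
})

test_that("cofactor table carries the printed values and supports overrides", {
  cf <- cofactorConcentrations()
  expect_equal(unname(cf[c("NADPH", "NADP", "NADH", "NAD")]),
               c(151.1, 20.37, 174.8, 862.9) / 1000)
  expect_equal(unname(cf[c("ATP", "ADP", "Pi")]), c(4.25, 0.93, 6.6))
  cf2 <- cofactorConcentrations(ATP = 4.25e-3)
  expect_equal(cf2[["ATP"]], 4.25e-3)
})

test_that("pathway profiles are additive over chains and rank by |dG|", {
  conc <- c(A = 5e-3, B = 2e-4, C = 8e-2, D = 1e-3)
  s1 <- thermoReaction("s1", c(A = -1, B = 1), dg0 = -12)
  s2 <- thermoReaction("s2", c(B = -1, C = 1), dg0 = 3)
  s3 <- thermoReaction("s3", c(C = -1, D = 1), dg0 = -30)
  prof <- pathwayProfile(list(s1, s2, s3), conc)
  steps <- profileSteps(prof)
  net <- thermoReaction("net", c(A = -1, D = 1), dg0 = -12 + 3 - 30)
  expect_equal(prof@additivity$sum_dg, deltaG(net, conc), tolerance = 1e-9)
  expect_true(prof@additivity$cancelled)
  expect_lt(abs(prof@additivity$residual), 1e-9)
  # a step handed Q >> 1 ranks first by |dG|
  far <- thermoReaction("far", c(A = -1, B = 1), dg0 = -60)
  prof2 <- pathwayProfile(list(far, s2), conc)
  expect_equal(profileSteps(prof2)$rank[1], 1L)
  expect_identical(profileSteps(prof2)$reaction_id[
    profileSteps(prof2)$rank == 1L], "far")
})

test_that("a shikimate-like profile puts the committed step furthest from equilibrium", {
  # concentrations mimicking the measured pattern: abundant precursors,
  # depleted early intermediates, accumulating end product
  tab <- resolveConcentrations(
    species = c("PEP", "E4P", "DAHP", "DHQ", "DHS", "SHIK", "NADPH", "NADP"),
    measured_intra = c(PEP = 12, E4P = 3, DHS = 0.5, SHIK = 8),
    rules = c(PEP = "measured_intracellular",
              E4P = "measured_intracellular",
              DHS = "measured_intracellular",
              SHIK = "measured_intracellular",
              NADPH = "literature_cofactor",
              NADP = "literature_cofactor"))
  pw <- list(
    thermoReaction("DAHP_synthase", c(PEP = -1, E4P = -1, DAHP = 1),
                   dg0 = -46),
    thermoReaction("DHQ_synthase", c(DAHP = -1, DHQ = 1), dg0 = -37),
    thermoReaction("DHQ_dehydratase", c(DHQ = -1, DHS = 1), dg0 = 4),
    thermoReaction("SHIK_dehydrogenase",
                   c(DHS = -1, NADPH = -1, SHIK = 1, NADP = 1), dg0 = -5))
  prof <- pathwayProfile(pw, tab)
  steps <- profileSteps(prof)
  expect_lte(steps$rank[steps$reaction_id == "DAHP_synthase"], 2L)
  # every species carries exactly one provenance tag
  expect_equal(anyDuplicated(prof@provenance$species), 0L)
  expect_setequal(prof@provenance$species,
                  c("PEP", "E4P", "DAHP", "DHQ", "DHS", "SHIK",
                    "NADPH", "NADP"))
})

test_that("scaling all concentrations leaves Q unchanged for balanced reactions", {
  rx <- thermoReaction("bal", c(A = -1, B = -1, C = 1, D = 1))
  base <- c(A = 1e-3, B = 5e-3, C = 2e-2, D = 7e-4)
  q0 <- reactionQuotient(rx, base)
  for (f in c(0.1, 3, 100)) {
    expect_equal(reactionQuotient(rx, base * f), q0, tolerance = 1e-12)
  }
  # unbalanced reaction scales with the factor
  rx2 <- thermoReaction("unbal", c(A = -2, C = 1))
  expect_equal(reactionQuotient(rx2, base * 10),
               reactionQuotient(rx2, base) / 10, tolerance = 1e-12)
})

test_that("equation parsing and pathway TSV round trip", {
  st <- parseReactionEquation("PEP + E4P <=> DAHP + Pi")
  expect_equal(st, c(PEP = -1, E4P = -1, DAHP = 1, Pi = 1))
  st2 <- parseReactionEquation("2 A + B <-> 3 C")
  expect_equal(st2, c(A = -2, B = -1, C = 3))
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(reaction_id = c("r1", "r2"),
                         equation = c("A + NADP <=> B + NADPH", "B = C"),
                         dg0_kj_mol = c(-4.2, 1.1)),
              p, sep = "\t", row.names = FALSE, quote = FALSE)
  pw <- readPathway(p)
  expect_length(pw, 2)
  expect_equal(pw[[1]]$dg0, -4.2)
  expect_equal(pw[[2]]$stoichiometry, c(B = -1, C = 1))
  prof <- pathwayProfile(pw, c(A = 1e-3, B = 1e-3, C = 1e-3,
                               NADP = 0.02037, NADPH = 0.1511))
  out <- withr::local_tempfile(fileext = ".tsv")
  writeProfile(prof, out)
  back <- read.delim(out)
  expect_equal(back$dg, profileSteps(prof)$dg, tolerance = 1e-9)
})
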