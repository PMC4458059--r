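test_that("JSON model round-trip is lossless and the toy fixture has the expected shape", {
  m <- makeToyCouplingModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeModel(m, path)
  m2 <- readModel(path)
  expect_equal(length(reactionIds(m2)), 18L)
  expect_identical(objectiveReaction(m2), "BIOMASS")
  expect_identical(sort(reactionIds(m2)), sort(reactionIds(m)))
  expect_identical(sort(metaboliteIds(m2)), sort(metaboliteIds(m)))
  expect_equal(sMatrix(m2)[metaboliteIds(m), reactionIds(m)], sMatrix(m))
  expect_equal(fluxBounds(m2)[match(reactionIds(m), reactionIds(m2)), ],
               fluxBounds(m), ignore_attr = TRUE)
  expect_identical(m2@rxns$knockable[match(reactionIds(m), reactionIds(m2))],
                   m@rxns$knockable)
})

test_that("malformed models are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": [], "reactions": []}', p)
  expect_error(readModel(p), "objective")
  writeLines("{not json", p)
  expect_error(readModel(p), "malformed")
  # reaction referencing an undeclared metabolite
  expect_error(
    metabolicModel(
      mets = data.frame(id = "A", compartment = "c", carbon_count = 1L),
      rxns = data.frame(id = "R", lower_bound = 0, upper_bound = 10),
      stoich = list(R = c(A = -1, GHOST = 1)),
      objective_id = "R"),
    "undeclared metabolite")
  expect_error(
    metabolicModel(
      mets = data.frame(id = "A", compartment = "c", carbon_count = 1L),
      rxns = data.frame(id = "R", lower_bound = 0, upper_bound = 10),
      stoich = list(R = c(A = -1)),
      objective_id = "NOPE"),
    "objective")
})

test_that("fba solves hand-checkable LPs and respects mass balance", {
  chain <- chainModel()
  sol <- fba(chain)
  expect_flux_sane(chain, sol)
  expect_equal(sol@objective_value, 10)        # limited by the uptake bound

  closed <- chainModel(uptake_lb = 0)
  expect_equal(fba(closed)@objective_value, 0) # no input, no growth

  toy <- makeToyCouplingModel()
  wt <- fba(toy)
  expect_flux_sane(toy, wt)
  # hand-solved LP: O2-limited respiro-fermentative optimum
  expect_equal(wt@objective_value, 5, tolerance = 1e-5)

  expect_equal(fba(chain, direction = "min")@objective_value, 0)
  expect_gte(fba(chain, direction = "max")@objective_value,
             fba(chain, direction = "min")@objective_value)
})

test_that("infeasible constraint sets report status without fluxes", {
  m <- chainModel()
  m@couplings <- list(list(terms = c(BIOMASS = 1), sense = ">=", rhs = 50))
  sol <- fba(m)
  expect_identical(solutionStatus(sol), "infeasible")
  expect_length(fluxes(sol), 0)
})

test_that("fva exposes alternate optima and honours fraction_of_optimum", {
  chain <- chainModel()
  r <- fva(chain, c("R1", "BIOMASS"))
  expect_equal(r$min, r$max, tolerance = 1e-6)  # single path: no freedom

  br <- branchModel()
  r2 <- fva(br, c("R1", "R2"), fractionOfOptimum = 1)
  # two equivalent branches split 10 units arbitrarily
  expect_equal(r2$min, c(0, 0), tolerance = 1e-6)
  expect_equal(r2$max, c(10, 10), tolerance = 1e-6)

  r0 <- fva(chain, "R1", fractionOfOptimum = 0)
  expect_equal(r0$min, 0, tolerance = 1e-6)
  expect_equal(r0$max, 10, tolerance = 1e-6)
  # fva interval at fraction 1 contains the fba flux
  v <- fluxes(fba(br))
  r3 <- fva(br, "R1")
  expect_gte(v[["R1"]], r3$min - 1e-6)
  expect_lte(v[["R1"]], r3$max + 1e-6)
})

test_that("knockouts close bounds, never help growth, and validate inputs", {
  toy <- makeToyCouplingModel()
  expect_identical(applyKnockouts(toy, character()), toy)
  base <- fba(toy)@objective_value
  # lethal: remove the only glucose transporter
  expect_equal(fba(applyKnockouts(toy, "T_glc"))@objective_value, 0,
               tolerance = 1e-6)
  # monotone under constraint addition
  for (ko in list("FERM", "RESP", c("FERM", "NADHOX"))) {
    expect_lte(fba(applyKnockouts(toy, ko))@objective_value, base + 1e-6)
  }
  expect_error(applyKnockouts(toy, "NOT_A_RXN"), "NOT_A_RXN")
  expect_error(applyKnockouts(toy, "EX_glc"), "not knockable")
  expect_error(applyKnockouts(toy, "BIOMASS"), "not knockable")
  expect_error(applyKnockouts(toy, "ATPM"), "not knockable")
  # input model untouched
  ko <- applyKnockouts(toy, "FERM")
  expect_equal(fluxBounds(toy)[fluxBounds(toy)$id == "FERM", "upper_bound"],
               1000)
})

test_that("addExchange creates a deterministic export and refuses duplicates", {
  toy <- makeToyCouplingModel()
  m2 <- addExchange(toy, "tyr", 0, 1000)
  expect_equal(length(reactionIds(m2)), length(reactionIds(toy)) + 1L)
  expect_true("EX_tyr" %in% reactionIds(m2))
  expect_equal(unname(sMatrix(m2)["tyr", "EX_tyr"]), -1)
  # hand LP: theoretical maximum export 20/3 (glc split 1:2 between the
  # trunk and the precursor branch, transhydrogenase burning the NADPH)
  expect_equal(fba(m2, "EX_tyr")@objective_value, 20 / 3, tolerance = 1e-5)
  expect_error(addExchange(m2, "tyr"), "already present")
})

test_that("SBML L3/fbc models read with bounds, objective and carbon counts", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeSbmlFixture(p)
  m <- readModel(p)
  expect_identical(objectiveReaction(m), "GROWTH")
  expect_setequal(reactionIds(m), c("EX_A", "TA", "R1", "GROWTH"))
  b <- fluxBounds(m)
  expect_equal(b$lower_bound[b$id == "EX_A"], -10)
  expect_equal(m@mets$carbon_count[m@mets$id == "A_c"], 6L)
  expect_equal(m@mets$carbon_count[m@mets$id == "B_c"], 3L)
  sol <- fba(m)
  expect_flux_sane(m, sol)
  expect_equal(sol@objective_value, 20)   # 10 uptake, 1 -> 2 conversion
})

test_that("flux solutions export as TSV", {
  chain <- chainModel()
  p <- withr::local_tempfile(fileext = ".tsv")
  writeFluxes(fba(chain), p)
  df <- read.delim(p)
  expect_setequal(df$reaction_id, reactionIds(chain))
  expect_equal(df$flux[df$reaction_id == "BIOMASS"], 10, tolerance = 1e-6)
})
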