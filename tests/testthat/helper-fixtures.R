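# Fixtures built in code. All are tiny networks with hand-solvable LPs.

# linear chain: EX_A (uptake up to 10) -> A -> B -> biomass drain
chainModel <- function(uptake_lb = -10) {
  metabolicModel(
    mets = data.frame(id = c("A", "B"), compartment = "c",
                      carbon_count = c(1L, 1L)),
    rxns = data.frame(
      id = c("EX_A", "R1", "BIOMASS"),
      lower_bound = c(uptake_lb, 0, 0),
      upper_bound = c(0, 1000, 1000),
      is_exchange = c(TRUE, FALSE, FALSE),
      knockable = c(FALSE, TRUE, FALSE)),
    stoich = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                  BIOMASS = c(B = -1)),
    objective_id = "BIOMASS")
}

# two equivalent parallel branches A -> B (R1 | R2), then biomass
branchModel <- function() {
  metabolicModel(
    mets = data.frame(id = c("A", "B"), compartment = "c",
                      carbon_count = 1L),
    rxns = data.frame(
      id = c("EX_A", "R1", "R2", "BIOMASS"),
      lower_bound = c(-10, 0, 0, 0), upper_bound = c(0, 1000, 1000, 1000),
      is_exchange = c(TRUE, FALSE, FALSE, FALSE),
      knockable = c(FALSE, TRUE, TRUE, FALSE)),
    stoich = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                  R2 = c(A = -1, B = 1), BIOMASS = c(B = -1)),
    objective_id = "BIOMASS")
}

# fixture for the wild-type adjustments: carries ICDHy/ALDD2y analogs and
# the four antiporter metabolites across cytosol and mitochondrion
adjustmentModel <- function(icdhy_id = "ICDHy", aldd_id = "ALDD2y") {
  rid <- c("EX_glc", "T_glc", "GLY2", aldd_id, "EX_ac", "EX_acald",
           icdhy_id, "EX_akg", "MITO_USE", "EX_oxa_sink", "BIOMASS")
  metabolicModel(
    mets = data.frame(
      id = c("glc_e", "glc", "acald", "ac", "akg_c", "akg_m",
             "oxoadipate_c", "oxoadipate_m"),
      compartment = c("e", "c", "c", "c", "c", "m", "c", "m"),
      carbon_count = c(6L, 6L, 2L, 2L, 5L, 5L, 6L, 6L)),
    rxns = data.frame(
      id = rid,
      lower_bound = c(-10, 0, 0, 0, 0, 0, -1000, 0, 0, 0, 0),
      upper_bound = c(0, rep(1000, 10)),
      is_exchange = rid %in% c("EX_glc", "EX_ac", "EX_acald", "EX_akg",
                               "EX_oxa_sink"),
      knockable = !(rid %in% c("EX_glc", "EX_ac", "EX_acald", "EX_akg",
                               "EX_oxa_sink", "BIOMASS"))),
    stoich = stats::setNames(list(
      c(glc_e = -1),
      c(glc_e = -1, glc = 1),
      c(glc = -1, acald = 1, akg_c = 1),
      c(acald = -1, ac = 1),
      c(ac = -1),
      c(acald = -1),
      c(akg_c = -1, oxoadipate_c = 1),
      c(akg_c = -1),
      c(oxoadipate_m = -1, akg_m = 1),
      c(akg_m = -1),
      c(glc = -1)), rid),
    objective_id = "BIOMASS")
}

toyWithTarget <- function() {
  m <- makeToyCouplingModel()
  addTarget(m, "tyr")
}

# a tiny SBML L3 + fbc document, written to a temp file
writeSbmlFixture <- function(path) {
  xml <- paste0(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_sbml" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_e" compartment="e" constant="false"
               boundaryCondition="false" hasOnlySubstanceUnits="false"
               fbc:chemicalFormula="C6H12O6"/>
      <species id="A_c" compartment="c" constant="false"
               boundaryCondition="false" hasOnlySubstanceUnits="false"
               fbc:chemicalFormula="C6H12O6"/>
      <species id="B_c" compartment="c" constant="false"
               boundaryCondition="false" hasOnlySubstanceUnits="false"
               fbc:chemicalFormula="C3H4O3"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="lb_0" value="0" constant="true"/>
      <parameter id="ub_1000" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="TA" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="GROWTH" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>')
  writeLines(xml, path)
  path
}

expect_flux_sane <- function(model, sol, tol = 1e-5) {
  expect_identical(solutionStatus(sol), "optimal")
  v <- fluxes(sol)
  expect_lt(max(abs(sMatrix(model) %*% v)), tol)
  b <- fluxBounds(model)
  expect_true(all(v >= b$lower_bound - tol & v <= b$upper_bound + tol))
}
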