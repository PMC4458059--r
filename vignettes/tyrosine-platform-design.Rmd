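---
title: "Growth-coupled strain design and fermentation analytics for a yeast tyrosine platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled strain design and fermentation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyroflux)
```

## Scope and models

`tyroflux` implements the computational workflow around engineering
*Saccharomyces cerevisiae* for L-tyrosine overproduction: picking reaction
knockouts on a constraint-based metabolic model so that tyrosine export
becomes *necessary* for optimal growth, profiling how far each
shikimate-pathway step sits from thermodynamic equilibrium given measured
metabolite concentrations, and the bookkeeping calculations that turn raw
fermentation time courses (OD, glucose, targeted metabolomics) into growth
rates, yields, specific-carbon totals and cytosolic concentrations.

### Constraint-based core

A metabolic network with stoichiometric matrix $S$ is assumed at steady
state, $S v = 0$, with fluxes $v$ (mmol/gDCW/h) bounded by
$l \le v \le u$. Flux balance analysis (FBA) maximizes the biomass flux by
linear programming; flux variability analysis (FVA) pins the biomass flux
at its optimum and ranges each other flux, exposing alternate optima.
Unbounded reactions receive the conventional $\pm 1000$ mmol/gDCW/h cap.
Mass balance and bound feasibility are asserted to $10^{-6}$ on every
optimal solution; test comparisons allow $10^{-5}$ so conclusions do not
depend on solver round-off.

The LP engine is a bounded-variable two-phase primal simplex written for
this package (dense tableau, Harris-style two-pass ratio test, Bland
fallback against degenerate cycling, periodic refactorisation). Mixed
integer programs are solved by branch-and-bound on the binary knockout
indicators with depth-first search and incumbent pruning. Variables fixed
at a single value (knocked-out reactions) are never allowed to enter the
basis, which removes the dominant source of degenerate cycling in knockout
enumeration.

### Design conditions

Strain-design runs start from a conditioned model: every exchange's uptake
is closed except glucose and oxygen, both opened at $-10$ mmol/gDCW/h, and
glucose and oxygen uptake tied 1:1. The ratio is enforced as an equality
*coupling row* ($v_{glc} = v_{O_2}$ on the signed exchange fluxes) rather
than as fixed bounds, so that uptake can scale below its bound while the
ratio is preserved; the bounds-only form remains available by turning
ratio enforcement off. The wild-type pentose-phosphate simulations
additionally (1) close the cytosolic isocitrate dehydrogenase, (2) add a
reversible 1:1 oxoadipate/$\alpha$-ketoglutarate mitochondrial antiporter,
and (3) cap the cytosolic acetaldehyde dehydrogenase at 16 % of the
glucose uptake rate through the row
$v_{ALDD2y} + 0.16\,v_{EX_{glc}} \le 0$. Reaction ids differ between
models, so these adjustments take an id-mapping table.

### OptKnock

OptKnock is the bilevel program: an outer player removes up to $K$
reactions to maximize the target exchange flux, while the inner player
(the cell) maximizes biomass over the remaining network. With binary
indicators $y_j$ ($y_j = 0$: knocked out) entering the inner bounds
$l_j y_j \le v_j \le u_j y_j$, the inner LP is collapsed through strong
duality: primal feasibility, dual feasibility, and the equality of primal
and dual inner objectives are imposed simultaneously, with the bilinear
dual-bound products $\alpha_j y_j$, $\beta_j y_j$ linearised by big-M
constraints ($M = 1000$, matching the flux cap). Big-M formulations can
leak — a too-small $M$ silently cuts optima — so every MILP solution is
re-validated by fresh LP solves (FBA + FVA on the knocked-out model); a
mismatch beyond $10^{-4}$ raises an error rather than returning a wrong
design. Ties between equal-scoring sets are broken toward fewer knockouts
(a secondary MILP maximizing $\sum y_j$ at fixed target flux); the
exhaustive oracle additionally orders ties lexicographically.

### Growth coupling, pessimistic and optimistic

A knockout set is *growth-coupled* when the minimum target flux over all
growth-optimal flux states is positive: export is then not merely
possible but necessary. Because alternate optima are common (the package's
own partial-design tests reproduce a target range $[0, >0]$ when one
knockout of a coupled set is dropped — the situation seen when the ZWF1
deletion is left out of a design), GDLS acceptance uses the *pessimistic*
score (FVA minimum at the growth optimum) by default; the optimistic
maximum is available via `score = "optimistic"`. The OptKnock outer
objective is inherently optimistic; its results report both bounds.

### GDLS and the two-step bootstrap

GDLS (genetic design by local search) iterates: from the incumbent
knockout set, solve a restricted OptKnock MILP over the neighborhood of
sets within symmetric difference $M$ (additions and removals both
counted — our reading of "neighborhood size", recorded here) and total
size $\le K$; accept strict improvements; stop when no neighbor improves.
The defaults are $M = 2$, $K = 10$, the settings used for the
tyrosine-platform designs this package targets. Because the
restricted MILP maximizes the optimistic score while acceptance is
pessimistic, proposals are screened by an exact FVA solve and excluded by
integer cuts until the MILP bound itself drops to the incumbent score;
this loop is finite and keeps the search sound for the pessimistic
criterion. Visited incumbents are excluded by integer cuts, which is also
the oscillation guard.

Local search can be *deceived*: when several independent escape valves
must all close before the product is coupled, no small neighborhood step
improves the (pessimistic) score and the search never leaves the wild
type. The two-step bootstrap runs GDLS first with an upstream intermediate
(chorismate, for tyrosine) as target — couplable with fewer knockouts —
and uses that solution as the initial condition for a second GDLS run on
the final target, closing the stage-1 auxiliary exchange. The package's
deceptive fixture reproduces exactly this landscape and is verified at
generation time by exhaustive search.

## Synthetic fixtures and what they do (and do not) show

`makeToyCouplingModel()` emits an 18-reaction network with the structural
features the design algorithms exercise on a genome-scale model: substrate
and oxygen exchanges, a glycolysis-like trunk (2 pyruvate + 2 NADH +
2 ATP per glucose), an oxidative-PPP-like branch co-producing the pathway
precursor and 2 NADPH (the ZWF1 analog), a transhydrogenase-like NADPH
sink, respiration and fermentation, a three-step shikimate-like chain to
the target, a precursor overflow valve, biomass (1 pyruvate + 1 NADPH +
8 ATP) and ATP maintenance. The coefficients were chosen once so the
wild-type optimum is a clean respiro-fermentative state (growth 5 at
10 glucose + 10 O$_2$) and the fermentation-branch knockout growth-couples
the target; all reference values in the tests (growth $125/26$, coupled
flux $95/26$, theoretical maximum $20/3$, yield fraction $57/104$) were
derived by hand from the balance equations before being frozen. Every
generated model self-verifies: the declared optimum must be reproduced by
`bruteForceDesign()` or generation fails.

`makeDeceptiveModel()` implements the three-valve landscape described
above; its self-check runs single-stage GDLS (must stay at the wild
type), the two-step bootstrap (must couple), and exhaustive search (a
coupled 3-knockout set must exist).

`simulateTimecourse()` emulates the statistical shape of batch
fermentation data: logistic biomass, glucose depletion through a fixed yield,
exponential-rise (`A(1-e^{-kt})`) product curves, sigmoidal titers, and
multiplicative log-normal noise (concentrations stay positive), in
replicate. Defaults follow the reported magnitudes: $\mu = 0.16$/h, yield
0.004 g DCW/g glucose, intracellular tyrosine plateau 520 µmol/g DCW.
What these fixtures do *not* emulate: regulation (feedback inhibition,
the Crabtree effect), diauxie and re-assimilation phases, measurement
drop-outs, or replicate-level batch effects — passing tests show the
estimators are correct on data satisfying their assumptions, not that
real fermentations satisfy them.

## Thermodynamic profiling

Each pathway step combines an externally supplied standard energy
$\Delta G^0_\gamma$ (kJ/mol, component-contribution values at pH 6.5,
25 °C are the intended source) with the reaction quotient
$Q = \prod [\mathrm{products}]^{c} / \prod [\mathrm{reactants}]^{a}$ in
mol/L via $\Delta G_\gamma = \Delta G^0_\gamma + RT\ln Q$,
$R = 8.314$ J/mol/K. Water and protons are excluded from $Q$ through a
configurable ignore list since their treatment lives inside the
transformed $\Delta G^0$. Concentrations resolve by provenance rules:
measured intracellular species convert from µmol/g DCW through the
cytosolic volume; species only measured extracellularly use the
extracellular concentration as cytosolic proxy; cofactors come from a
literature table (NADPH 151.1, NADP 20.37, NADH 174.8, NAD 862.9 mM; ATP
4.25, ADP 0.93, Pi 6.6 *molar as printed in their source* — surprising
units, deliberately not silently corrected, overridable); everything else
defaults to 1 mM exactly. Steps are ranked by $|\Delta G_\gamma|$; the
step furthest from equilibrium is the most plausible point of active
regulation. An additivity audit checks that step energies sum to the net
reaction's energy whenever intermediates cancel (identity to $10^{-9}$).

## Time-course calculations

* OD600 converts to biomass at 2.01 mg DCW/mL/OD.
* A 60 pg cell and 160 µm³ volume give $1.7\times10^{10}$ cells/g DCW and
  2.7 mL cytosol/g DCW (two significant figures). Concentration
  conversions use the *stated rounded* 2.7 mL/g by default so worked
  examples match published numbers (520 µmol/g → 192 mM; 351 → 129 mM at
  1 %); the unrounded 2.67 is available from `deriveCellConstants()`.
* $\mu_{max}$: log-linear least squares over the exponential window. The
  window is auto-selected as the contiguous stretch of ≥ 4 points with
  positive slope maximizing $R^2$ ("exponential growth phase" is rarely
  defined operationally; this rule is explicit and deterministic).
  On logistic data the estimate carries a small negative bias from the
  bend (≪ 1 % at the default inoculum ratio); recovery tolerances in the
  tests account for it.
* Growth yield: maximum g DCW formed per g glucose consumed since
  inoculation.
* Specific-carbon totals: per-time-point sums over a downstream metabolite
  set (molecule-count mode by default — the published totals are
  inconsistent with carbon-atom weighting, so `carbon_mol` is optional),
  fitted with the 2-parameter exponential rise and read off at 48 h, with
  the fit's delta-method standard error.
* Titers: 3-parameter sigmoid $a/(1+e^{-(t-t_0)/b})$, plateau = final
  titer. Non-increasing series are rejected rather than fitted.
* Specific rates: slope of amount vs. the biomass-time integral
  $\int X\,dt$ (the standard estimator when only units are specified).

## Numerical choices and limitations

* Feasibility/mass-balance tolerance $10^{-6}$; design coupling threshold
  $10^{-6}$ on the pessimistic flux; MILP/LP validation $10^{-4}$;
  branch-and-bound integer tolerance $10^{-6}$.
* All candidate sets and tie-breaks are ordered lexicographically, so
  results are reproducible across platforms.
* Problem sizes: toy fixtures stay ≤ 30 reactions so exhaustive
  enumeration over ≤ 3 knockouts runs in seconds and can serve as the
  oracle for the MILP path; the recovery studies use 30 simulation seeds
  at 5 % noise.
* The simplex/branch-and-bound stack is dense and aimed at these desk
  scales; genome-scale models load through the SBML reader and solve, but
  OptKnock on thousands of reactions is outside the intended envelope.
* Gene-protein-reaction rules, loop-law corrections, dynamic FBA,
  ionic-strength corrections to $\Delta G^0$ and uncertainty propagation
  are out of scope.

## A worked design run

```{r design, eval = FALSE}
toy <- makeToyCouplingModel()
tg <- addTarget(toy, "tyr")
res <- optknock(designProblem(tg$model, tg$target_id, max_knockouts = 2))
res
theoreticalYieldFraction(tg$model, knockouts(res), tg$target_id)
```

The run reports the coupled knockout (the fermentation branch), growth
$125/26 \approx 4.81$, a pessimistic = optimistic target flux
$95/26 \approx 3.65$ (the design is fully coupled, the range collapses),
and a yield fraction $\approx 0.55$ of the theoretical maximum.
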