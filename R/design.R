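# Growth-coupled knockout design: OptKnock bilevel MILP via LP strong
# duality, GDLS bounded local search, the two-step intermediate-target
# bootstrap, and an exhaustive oracle for small instances.

.tf_bigM <- 1000        # big-M on dual variables and dual-bound products
.tf_couple_tol <- 1e-6  # target_min above this counts as growth-coupled
.tf_validate_tol <- 1e-4

#' Define a knockout design problem
#'
#' @param model a conditioned [MetabolicModel-class] that already contains
#'   the target exchange
#' @param target_id the target exchange reaction id (outer objective)
#' @param max_knockouts maximum number of simultaneous knockouts (K)
#' @param candidate_set reaction ids eligible for knockout; defaults to all
#'   knockable reactions (exchanges, biomass and maintenance excluded),
#'   sorted lexicographically
#' @param neighborhood_size GDLS neighborhood size M: the maximum symmetric
#'   difference between successive incumbent knockout sets
#' @param initial_knockouts starting incumbent for GDLS
#' @param min_growth_fraction require mutant growth >= this fraction of the
#'   wild-type optimum (0 = no floor)
#' @param score "pessimistic" scores designs by the minimum target flux at
#'   the growth optimum (the growth-coupling criterion); "optimistic" by the
#'   maximum
#' @return a list of class "DesignProblem"
#' @export
designProblem <- function(model, target_id, max_knockouts = 4,
                          candidate_set = NULL, neighborhood_size = 2,
                          initial_knockouts = character(),
                          min_growth_fraction = 0,
                          score = c("pessimistic", "optimistic")) {
  score <- match.arg(score)
  .rxnIndex(model, target_id)
  if (is.null(candidate_set))
    candidate_set <- sort(model@rxns$id[model@rxns$knockable])
  else {
    idx <- .rxnIndex(model, candidate_set)
    if (any(!model@rxns$knockable[idx]))
      stop("candidate_set contains non-knockable reactions: ",
           paste(candidate_set[!model@rxns$knockable[idx]], collapse = ", "))
    candidate_set <- sort(candidate_set)
  }
  stopifnot(max_knockouts >= 0, neighborhood_size >= 1,
            min_growth_fraction >= 0, min_growth_fraction <= 1)
  if (max_knockouts > length(candidate_set))
    stop("max_knockouts exceeds the candidate set size")
  if (!all(initial_knockouts %in% candidate_set))
    stop("initial_knockouts must be a subset of candidate_set")
  structure(list(model = model, target_id = target_id,
                 max_knockouts = max_knockouts,
                 candidate_set = candidate_set,
                 neighborhood_size = neighborhood_size,
                 initial_knockouts = sort(unique(initial_knockouts)),
                 min_growth_fraction = min_growth_fraction,
                 score = score),
            class = "DesignProblem")
}

#' Assess growth coupling of a knockout set
#'
#' Applies the knockouts, maximizes growth, then fixes growth at its
#' optimum and ranges the target exchange flux (flux variability). The
#' design is growth-coupled when the pessimistic minimum target flux is
#' positive: export of the target is then necessary in every growth-optimal
#' flux state. Lethal sets report growth 0 and coupled = FALSE without
#' erroring.
#'
#' @param model a [MetabolicModel-class] containing the target exchange
#' @param knockouts character vector of reaction ids
#' @param target_id target exchange id
#' @return list(growth, target_min, target_max, coupled)
#' @export
assessCoupling <- function(model, knockouts, target_id) {
  m2 <- applyKnockouts(model, knockouts)
  sol <- fba(m2)
  if (sol@status != "optimal")
    return(list(growth = 0, target_min = 0, target_max = 0, coupled = FALSE))
  rng <- fva(m2, target_id, fractionOfOptimum = 1)
  growth <- sol@objective_value
  if (growth <= .tf_couple_tol)
    return(list(growth = 0, target_min = 0, target_max = max(0, rng$max),
                coupled = FALSE))
  list(growth = growth,
       target_min = rng$min, target_max = rng$max,
       coupled = rng$min > .tf_couple_tol)
}

#' Theoretical yield fraction of a design
#'
#' Ratio of the mutant's maximum target flux at its growth optimum to the
#' wild-type's absolute maximum target flux under the same condition
#' (growth unconstrained). Lies in \[0, 1\]; 1 means the design reaches the
#' network's theoretical maximum.
#'
#' @inheritParams assessCoupling
#' @return a number in \[0, 1\]
#' @export
theoreticalYieldFraction <- function(model, knockouts, target_id) {
  wt_max <- fba(model, objective = target_id, direction = "max")
  if (wt_max@status != "optimal" || wt_max@objective_value <= .tf_couple_tol)
    stop("theoretical maximum target flux is zero; target unreachable ",
         "from the substrate under this condition")
  ac <- assessCoupling(model, knockouts, target_id)
  min(1, max(0, ac$target_max / wt_max@objective_value))
}

# coupling rows in <= form (equalities split in two)
.couplingLE <- function(model) {
  n <- nrow(model@rxns)
  G <- matrix(0, 0, n); g <- numeric()
  for (cp in model@couplings) {
    row <- numeric(n)
    row[.rxnIndex(model, names(cp$terms))] <- cp$terms
    if (cp$sense %in% c("<=", "=")) { G <- rbind(G, row); g <- c(g, cp$rhs) }
    if (cp$sense %in% c(">=", "=")) { G <- rbind(G, -row); g <- c(g, -cp$rhs) }
  }
  list(G = G, g = g)
}

# Single-level OptKnock MILP: outer max target flux, inner biomass optimum
# enforced through LP strong duality with big-M linearised dual-bound
# products. `extra_y` rows (named lists with coef over candidates, sense,
# rhs) restrict the binary knockout indicators (y = 0 means knocked out).
.optknockMILP <- function(model, target_id, candidates, max_knockouts,
                          min_growth = 0, extra_y = list(),
                          maximize_y = FALSE, target_floor = NULL) {
  n <- nrow(model@rxns); m <- nrow(model@mets)
  lb <- pmax(model@rxns$lower_bound, -.tf_cap)
  ub <- pmin(model@rxns$upper_bound, .tf_cap)
  ci <- .rxnIndex(model, candidates); nc <- length(ci)
  ti <- .rxnIndex(model, target_id)
  bi <- .rxnIndex(model, model@objective_id)
  cle <- .couplingLE(model); G <- cle$G; g <- cle$g; ng <- length(g)
  M <- .tf_bigM

  # variable layout
  iv <- seq_len(n)
  il <- n + seq_len(m)
  ig <- n + m + seq_len(ng)
  ia <- n + m + ng + seq_len(n)
  ib <- n + m + ng + n + seq_len(n)
  iay <- n + m + ng + 2 * n + seq_len(nc)
  iby <- n + m + ng + 2 * n + nc + seq_len(nc)
  iy <- n + m + ng + 2 * n + 2 * nc + seq_len(nc)
  ntot <- n + m + ng + 2 * n + 2 * nc + nc

  vlb <- numeric(ntot); vub <- numeric(ntot)
  vlb[iv] <- lb; vub[iv] <- ub
  vlb[iv][match(ci, iv)] <- pmin(lb[ci], 0)   # candidate fluxes may be shut
  vub[iv][match(ci, iv)] <- pmax(ub[ci], 0)
  vlb[il] <- -M; vub[il] <- M
  if (ng) { vlb[ig] <- 0; vub[ig] <- M }
  vlb[ia] <- 0; vub[ia] <- M
  vlb[ib] <- 0; vub[ib] <- M
  vlb[iay] <- 0; vub[iay] <- M
  vlb[iby] <- 0; vub[iby] <- M
  vlb[iy] <- 0; vub[iy] <- 1

  rows <- list(); senses <- character(); rhs <- numeric()
  addRow <- function(ix, co, sense, b) {
    r <- numeric(ntot); r[ix] <- co
    rows[[length(rows) + 1L]] <<- r
    senses[length(senses) + 1L] <<- sense
    rhs[length(rhs) + 1L] <<- b
  }

  # primal: S v = 0 ; G v <= g
  for (k in seq_len(m)) {
    nz <- which(model@S[k, ] != 0)
    addRow(iv[nz], model@S[k, nz], "=", 0)
  }
  if (ng) for (k in seq_len(ng)) {
    nz <- which(G[k, ] != 0)
    addRow(iv[nz], G[k, nz], "<=", g[k])
  }
  # candidate flux gating: v_j <= u_j y_j ; v_j >= l_j y_j
  for (q in seq_len(nc)) {
    j <- ci[q]
    addRow(c(iv[j], iy[q]), c(1, -ub[j]), "<=", 0)
    addRow(c(iv[j], iy[q]), c(1, -lb[j]), ">=", 0)
  }
  # dual feasibility: S' lambda + G' mu + alpha - beta = e_biomass
  for (j in seq_len(n)) {
    nzS <- which(model@S[, j] != 0)
    ix <- c(il[nzS], ia[j], ib[j])
    co <- c(model@S[nzS, j], 1, -1)
    if (ng) {
      nzG <- which(G[, j] != 0)
      if (length(nzG)) { ix <- c(ix, ig[nzG]); co <- c(co, G[nzG, j]) }
    }
    addRow(ix, co, "=", as.numeric(j == bi))
  }
  # strong duality: c'v = g'mu + sum_{j not cand}(alpha_j u_j - beta_j l_j)
  #                        + sum_{j cand}(u_j aY_j - l_j bY_j)
  noncand <- setdiff(seq_len(n), ci)
  ix <- c(iv[bi], if (ng) ig, ia[noncand], ib[noncand], iay, iby)
  co <- c(1, if (ng) -g, -ub[noncand], lb[noncand], -ub[ci], lb[ci])
  addRow(ix, co, "=", 0)
  # linearisation of aY = alpha*y and bY = beta*y for candidates
  for (q in seq_len(nc)) {
    j <- ci[q]
    addRow(c(iay[q], ia[j]), c(1, -1), "<=", 0)
    addRow(c(iay[q], iy[q]), c(1, -M), "<=", 0)
    addRow(c(iay[q], ia[j], iy[q]), c(1, -1, -M), ">=", -M)
    addRow(c(iby[q], ib[j]), c(1, -1), "<=", 0)
    addRow(c(iby[q], iy[q]), c(1, -M), "<=", 0)
    addRow(c(iby[q], ib[j], iy[q]), c(1, -1, -M), ">=", -M)
  }
  # knockout budget
  addRow(iy, rep(1, nc), ">=", nc - max_knockouts)
  if (min_growth > 0) addRow(iv[bi], 1, ">=", min_growth)
  if (!is.null(target_floor)) addRow(iv[ti], 1, ">=", target_floor)
  for (ey in extra_y) {
    co <- ey$coef[candidates]
    nz <- which(co != 0)
    addRow(iy[nz], co[nz], ey$sense, ey$rhs)
  }

  obj <- numeric(ntot)
  if (maximize_y) obj[iy] <- 1 else obj[iv[ti]] <- 1
  A <- do.call(rbind, rows)
  r <- milpSolveDense(obj, A, senses, rhs, vlb, vub, maximize = TRUE,
                      binary_idx = iy)
  if (r$status != "optimal")
    return(list(status = r$status, objval = NA_real_, knockouts = character()))
  y <- round(r$x[iy])
  list(status = "optimal", objval = r$objval,
       knockouts = candidates[y == 0],
       target_flux = r$x[iv[ti]], growth = r$x[iv[bi]])
}

.newDesignResult <- function(knockouts, ac, trace, yield = NA_real_,
                             status = "ok") {
  new("DesignResult", knockouts = sort(knockouts), growth = ac$growth,
      target_min = ac$target_min, target_max = ac$target_max,
      coupled = ac$coupled, yield_fraction = yield, trace = trace,
      status = status)
}

.traceRow <- function(stage, iteration, knockouts, score) {
  data.frame(stage = stage, iteration = iteration,
             knockouts = paste(sort(knockouts), collapse = "+"),
             score = score, stringsAsFactors = FALSE)
}

#' OptKnock: bilevel knockout design via strong duality
#'
#' Finds the knockout set (at most `max_knockouts` reactions from the
#' candidate set) maximizing the target exchange flux while the inner
#' problem — the cell — maximizes biomass. The bilevel program is collapsed
#' to a single MILP through LP strong duality of the inner problem with
#' binary knockout indicators and big-M linearised dual-bound products.
#' Every solution is re-validated with independent LP solves on the
#' knocked-out model; a mismatch beyond 1e-4 (a big-M pathology) raises a
#' hard error rather than returning a wrong design. Among equally scoring
#' sets, fewer knockouts are preferred.
#'
#' @param problem a [designProblem()]
#' @return a [DesignResult-class]
#' @export
optknock <- function(problem) {
  stopifnot(inherits(problem, "DesignProblem"))
  model <- problem$model
  if (!length(problem$candidate_set)) stop("empty candidate set")
  min_growth <- 0
  if (problem$min_growth_fraction > 0) {
    wt <- fba(model)
    if (wt@status != "optimal") stop("wild-type model is ", wt@status)
    min_growth <- problem$min_growth_fraction * wt@objective_value
  }
  r <- .optknockMILP(model, problem$target_id, problem$candidate_set,
                     problem$max_knockouts, min_growth = min_growth)
  if (r$status != "optimal")
    stop("OptKnock MILP is ", r$status)
  # tie-break: among sets achieving the optimum, keep as many reactions as
  # possible (fewest knockouts)
  r2 <- .optknockMILP(model, problem$target_id, problem$candidate_set,
                      problem$max_knockouts, min_growth = min_growth,
                      maximize_y = TRUE, target_floor = r$objval - 1e-7)
  if (r2$status == "optimal") r <- r2
  ac <- assessCoupling(model, r$knockouts, problem$target_id)
  milp_score <- if (length(r$target_flux)) r$target_flux else r$objval
  if (abs(ac$target_max - milp_score) > .tf_validate_tol)
    stop(sprintf(paste0("OptKnock validation failed: MILP target %.6f vs ",
                        "LP-validated maximum %.6f (big-M leakage?)"),
                 milp_score, ac$target_max))
  tr <- .traceRow("optknock", 1L, r$knockouts, ac$target_max)
  .newDesignResult(r$knockouts, ac, tr)
}

#' GDLS: genetic design through local search
#'
#' Iterative bounded local search for growth-coupled designs. From the
#' incumbent knockout set, a restricted OptKnock MILP over the neighborhood
#' (knockout sets within symmetric difference `neighborhood_size` of the
#' incumbent, total size at most `max_knockouts`) proposes candidates;
#' a proposal is accepted when it strictly improves the incumbent score.
#' With pessimistic scoring (the default; growth coupling is a statement
#' about the worst case over alternate optima) proposals whose optimistic
#' MILP score exceeds the incumbent are screened by an exact flux
#' variability solve, and integer cuts exclude rejected sets until the MILP
#' bound itself drops below the incumbent. Visited incumbents are excluded
#' by integer cuts, which guards against oscillation. The search starts
#' from `initial_knockouts` (wild type when empty).
#'
#' @param problem a [designProblem()]
#' @return a [DesignResult-class] with the full search trace
#' @export
gdls <- function(problem) {
  stopifnot(inherits(problem, "DesignProblem"))
  model <- problem$model
  candidates <- problem$candidate_set
  start_sol <- fba(applyKnockouts(model, problem$initial_knockouts))
  if (start_sol@status != "optimal")
    stop("GDLS: infeasible at start (", start_sol@status, ")")
  min_growth <- 0
  if (problem$min_growth_fraction > 0) {
    wt <- fba(model)
    min_growth <- problem$min_growth_fraction * wt@objective_value
  }
  scoreOf <- function(ac)
    if (problem$score == "pessimistic") ac$target_min else ac$target_max

  inc <- problem$initial_knockouts
  inc_ac <- assessCoupling(model, inc, problem$target_id)
  inc_score <- scoreOf(inc_ac)
  trace <- .traceRow("gdls", 0L, inc, inc_score)
  cutFor <- function(set) {
    # exclude exactly `set`: sum_{j in set} y_j + sum_{j notin set} (1-y_j) >= 1
    co <- stats::setNames(rep(-1, length(candidates)), candidates)
    co[set] <- 1
    list(coef = co, sense = ">=", rhs = 1 - (length(candidates) - length(set)))
  }
  nbhdRows <- function(set) {
    # sym. difference to `set`: sum_{set} y + sum_{not set} (1-y) <= nbhd
    co <- stats::setNames(rep(-1, length(candidates)), candidates)
    co[set] <- 1
    list(list(coef = co, sense = "<=",
              rhs = problem$neighborhood_size -
                    (length(candidates) - length(set))))
  }
  visited_cuts <- list(cutFor(inc))
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > 100L) { trace$status <- NULL; break }
    local_cuts <- list()
    accepted <- NULL
    repeat {
      r <- .optknockMILP(model, problem$target_id, candidates,
                         problem$max_knockouts, min_growth = min_growth,
                         extra_y = c(nbhdRows(inc), visited_cuts, local_cuts))
      if (r$status != "optimal" || r$objval <= inc_score + .tf_couple_tol)
        break
      ac <- assessCoupling(model, r$knockouts, problem$target_id)
      if (abs(ac$target_max - r$target_flux) > .tf_validate_tol)
        stop("GDLS validation failed: MILP/LP mismatch ",
             format(abs(ac$target_max - r$target_flux)))
      if (scoreOf(ac) > inc_score + .tf_couple_tol) {
        accepted <- list(set = r$knockouts, ac = ac)
        break
      }
      local_cuts <- c(local_cuts, list(cutFor(r$knockouts)))
    }
    if (is.null(accepted)) break
    inc <- sort(accepted$set)
    inc_ac <- accepted$ac
    inc_score <- scoreOf(inc_ac)
    trace <- rbind(trace, .traceRow("gdls", it, inc, inc_score))
    visited_cuts <- c(visited_cuts, list(cutFor(inc)))
  }
  .newDesignResult(inc, inc_ac, trace)
}

#' Two-step design via an intermediate target
#'
#' Local search for deeply buried growth couplings: GDLS is first run with
#' an intermediate pathway metabolite (e.g. chorismate) as the production
#' target, and the resulting knockout set seeds a second GDLS run with the
#' final metabolite (e.g. tyrosine) as the target. The stage-1 auxiliary
#' exchange is closed during stage 2. When intermediate and final coincide
#' this reduces to plain [gdls()].
#'
#' @param model a conditioned [MetabolicModel-class] (without target
#'   exchanges)
#' @param intermediate_metabolite,final_metabolite cytosolic metabolite ids
#' @param max_knockouts,neighborhood_size,min_growth_fraction,score passed
#'   to [designProblem()]
#' @param candidate_set optional candidate reactions (defaults to all
#'   knockable)
#' @return a [DesignResult-class]; the trace contains both stages
#' @export
twoStepDesign <- function(model, intermediate_metabolite, final_metabolite,
                          max_knockouts = 10, neighborhood_size = 2,
                          min_growth_fraction = 0, candidate_set = NULL,
                          score = c("pessimistic", "optimistic")) {
  score <- match.arg(score)
  if (identical(intermediate_metabolite, final_metabolite)) {
    tg <- addTarget(model, final_metabolite)
    pr <- designProblem(tg$model, tg$target_id, max_knockouts,
                        candidate_set, neighborhood_size,
                        min_growth_fraction = min_growth_fraction,
                        score = score)
    return(gdls(pr))
  }
  tg1 <- addTarget(model, intermediate_metabolite)
  pr1 <- designProblem(tg1$model, tg1$target_id, max_knockouts,
                       candidate_set, neighborhood_size,
                       min_growth_fraction = min_growth_fraction,
                       score = score)
  stage1 <- tryCatch(gdls(pr1), error = function(e) e)
  if (inherits(stage1, "error"))
    stop("two-step design: stage 1 (intermediate ", intermediate_metabolite,
         ") failed: ", conditionMessage(stage1))
  tr1 <- stage1@trace
  tr1$stage <- "stage1"

  m2 <- tg1$model
  i <- .rxnIndex(m2, tg1$target_id)    # close the auxiliary exchange
  m2@rxns$lower_bound[i] <- 0
  m2@rxns$upper_bound[i] <- 0
  tg2 <- addTarget(m2, final_metabolite)
  pr2 <- designProblem(tg2$model, tg2$target_id, max_knockouts,
                       candidate_set, neighborhood_size,
                       initial_knockouts = stage1@knockouts,
                       min_growth_fraction = min_growth_fraction,
                       score = score)
  stage2 <- gdls(pr2)
  tr2 <- stage2@trace
  tr2$stage <- "stage2"
  stage2@trace <- rbind(tr1, tr2)
  stage2
}

#' Exhaustive knockout design (test oracle)
#'
#' Evaluates every knockout subset of the candidate set up to
#' `max_knockouts` with [assessCoupling()] scoring and returns the optimum.
#' Ties are broken deterministically: fewest knockouts first, then the
#' lexicographically smallest id tuple. Refuses instances with more than
#' `enumeration_cap` subsets.
#'
#' @param problem a [designProblem()]
#' @param enumeration_cap maximum number of subsets to enumerate
#' @return a [DesignResult-class]
#' @export
bruteForceDesign <- function(problem, enumeration_cap = 1e5) {
  stopifnot(inherits(problem, "DesignProblem"))
  cand <- problem$candidate_set
  K <- problem$max_knockouts
  total <- sum(choose(length(cand), 0:K))
  if (total > enumeration_cap)
    stop("enumeration of ", format(total), " subsets exceeds the cap; ",
         "use a smaller instance")
  model <- problem$model
  min_growth <- 0
  if (problem$min_growth_fraction > 0) {
    wt <- fba(model)
    min_growth <- problem$min_growth_fraction * wt@objective_value
  }
  scoreOf <- function(ac)
    if (problem$score == "pessimistic") ac$target_min else ac$target_max
  best <- NULL
  trace <- NULL
  nEval <- 0L
  for (k in 0:K) {
    sets <- if (k == 0) list(character()) else
      utils::combn(cand, k, simplify = FALSE)
    for (set in sets) {
      nEval <- nEval + 1L
      ac <- assessCoupling(model, set, problem$target_id)
      if (min_growth > 0 && ac$growth < min_growth - 1e-9) next
      sc <- scoreOf(ac)
      better <- is.null(best) || sc > best$score + 1e-9 ||
        (abs(sc - best$score) <= 1e-9 &&
           (length(set) < length(best$set) ||
            (length(set) == length(best$set) &&
             paste(set, collapse = "\r") < paste(best$set, collapse = "\r"))))
      if (better) {
        best <- list(set = set, score = sc, ac = ac)
        trace <- rbind(trace, .traceRow("brute_force", nEval, set, sc))
      }
    }
  }
  if (is.null(best)) {
    ac0 <- assessCoupling(model, character(), problem$target_id)
    best <- list(set = character(), score = scoreOf(ac0), ac = ac0)
    trace <- .traceRow("brute_force", 0L, character(), best$score)
  }
  .newDesignResult(best$set, best$ac, trace)
}
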