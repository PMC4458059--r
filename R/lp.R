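# Bounded-variable two-phase primal simplex, dense tableau.
#
# Solves  min/max  c'x  s.t.  A x {<=,=,>=} b,  l <= x <= u.
# Every structural variable must carry at least one finite bound (flux
# variables are capped upstream at +/- .tf_cap). Written for the small dense
# systems that arise from toy networks and the OptKnock duality MILP; favours
# numerical robustness (Bland fallback, periodic refactorisation) over speed.

.tf_cap <- 1000           # default flux cap, mmol/gDCW/h (COBRA convention)
.tf_feas_tol <- 1e-6      # mass-balance / bound feasibility reported to users
.tf_pivot_tol <- 1e-9
.tf_dj_tol <- 1e-9

lpSolveDense <- function(obj, A, sense, rhs, lb, ub, maximize = TRUE) {
  n <- length(obj)
  m <- length(rhs)
  stopifnot(length(lb) == n, length(ub) == n,
            is.matrix(A), nrow(A) == m || m == 0L, length(sense) == m)
  if (m == 0L) {
    # pure box problem
    x <- ifelse((if (maximize) obj else -obj) > 0, ub, lb)
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objval = sum(obj * x), x = x))
  }
  # slacks: one per row, A x + s = b
  slb <- numeric(m); sub <- numeric(m)
  slb[sense == "<="] <- 0;    sub[sense == "<="] <- Inf
  slb[sense == ">="] <- -Inf; sub[sense == ">="] <- 0
  slb[sense == "="] <- 0;     sub[sense == "="] <- 0
  Afull <- cbind(A, diag(m))
  l <- c(lb, slb); u <- c(ub, sub)
  cmin <- c(if (maximize) -obj else obj, numeric(m))
  ntot <- n + m

  # initial nonbasic values at a finite bound
  x0 <- ifelse(is.finite(l), l, u)
  if (any(!is.finite(x0)))
    stop("lpSolveDense: every variable needs at least one finite bound")
  resid <- rhs - as.vector(Afull %*% x0)
  # artificials giving an identity basis
  art_sign <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(Afull, diag(art_sign, m))
  l <- c(l, numeric(m)); u <- c(u, rep(Inf, m))
  cmin <- c(cmin, numeric(m))
  nall <- ntot + m

  st <- list(
    A = Afull, l = l, u = u,
    basis = (ntot + 1L):nall,
    # at_upper flag for nonbasic variables
    at_upper = !is.finite(l)[seq_len(nall)],
    x = c(x0, abs(resid)),
    Tab = diag(art_sign, m) %*% Afull,   # Binv %*% A with Binv = diag(art_sign)
    rhs = rhs
  )
  st$at_upper[st$basis] <- FALSE

  phase1_c <- c(numeric(ntot), rep(1, m))
  r1 <- .simplexRun(st, phase1_c)
  if (r1$status != "optimal")
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  p1 <- sum(phase1_c * r1$st$x)
  if (p1 > 1e-7)
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  st <- r1$st
  # freeze artificials at zero
  st$u[(ntot + 1L):nall] <- 0
  st$x[(ntot + 1L):nall][st$x[(ntot + 1L):nall] < .tf_pivot_tol] <- 0

  r2 <- .simplexRun(st, cmin)
  if (r2$status == "unbounded")
    return(list(status = "unbounded", objval = NA_real_, x = NULL))
  x <- r2$st$x[seq_len(n)]
  # clip roundoff against the original bounds
  x <- pmin(pmax(x, lb), ub)
  objval <- sum(obj * x)
  list(status = "optimal", objval = objval, x = x)
}

# one simplex phase: minimise cvec'x from state st
.simplexRun <- function(st, cvec) {
  m <- length(st$basis)
  nall <- ncol(st$A)
  it <- 0L
  max_it <- 200L * (m + nall)
  refac_every <- 100L
  since_refac <- 0L
  repeat {
    it <- it + 1L
    if (it > max_it) stop("simplex: iteration limit reached")
    bland <- it > 20L * (m + 5L)

    yB <- cvec[st$basis] %*% st$Tab        # 1 x nall (= c_B' Binv A)
    dj <- cvec - as.vector(yB)
    dj[st$basis] <- 0
    nonbas <- rep(TRUE, nall); nonbas[st$basis] <- FALSE
    movable <- st$u > st$l            # fixed variables never enter
    cand_lo <- nonbas & movable & !st$at_upper & dj < -.tf_dj_tol
    cand_hi <- nonbas & movable & st$at_upper & dj > .tf_dj_tol
    cand <- which(cand_lo | cand_hi)
    if (!length(cand)) {
      return(list(status = "optimal", st = st))
    }
    j <- if (bland) cand[1L] else cand[which.max(abs(dj[cand]))]
    up_dir <- !st$at_upper[j]              # entering increases if at lower
    w <- st$Tab[, j]
    # basic values move by -w*t (up) or +w*t (down)
    d <- if (up_dir) -w else w
    xB <- st$x[st$basis]
    lB <- st$l[st$basis]; uB <- st$u[st$basis]
    flip <- st$u[j] - st$l[j]              # bound-flip distance
    # Harris-style two-pass ratio test: find the limiting step with a small
    # feasibility relaxation, then pick the largest pivot among rows whose
    # exact ratio is within it (avoids near-singular bases)
    ratio <- rep(Inf, m)
    pos <- d > .tf_pivot_tol
    neg <- d < -.tf_pivot_tol
    ratio[pos] <- (uB[pos] - xB[pos]) / d[pos]
    ratio[neg] <- (xB[neg] - lB[neg]) / (-d[neg])
    relax <- rep(Inf, m)
    relax[pos] <- (uB[pos] - xB[pos] + 1e-9) / d[pos]
    relax[neg] <- (xB[neg] - lB[neg] + 1e-9) / (-d[neg])
    tlim <- min(relax, flip)
    if (!is.finite(tlim)) {
      return(list(status = "unbounded", st = st))
    }
    leave <- 0L
    elig <- which(is.finite(ratio) & ratio <= tlim)
    if (length(elig)) {
      if (bland) {
        # Bland anti-cycling: smallest basic-variable index among the rows
        # attaining the exact minimum ratio
        rmin <- min(ratio[elig])
        cands <- elig[ratio[elig] <= rmin + 1e-12]
        leave <- cands[which.min(st$basis[cands])]
      } else {
        leave <- elig[which.max(abs(d[elig]))]
      }
      tmax <- ratio[leave]
    } else {
      tmax <- flip
    }
    tmax <- max(tmax, 0)
    st$x[st$basis] <- xB + d * tmax
    if (leave == 0L) {
      # bound flip: j jumps to its other bound
      st$x[j] <- if (up_dir) st$u[j] else st$l[j]
      st$at_upper[j] <- up_dir
      next
    }
    # pivot: j enters, basis[leave] leaves at the bound it hit
    jout <- st$basis[leave]
    xout <- st$x[jout]
    hit_upper <- abs(xout - st$u[jout]) < abs(xout - st$l[jout])
    st$x[jout] <- if (hit_upper) st$u[jout] else st$l[jout]
    st$at_upper[jout] <- hit_upper
    st$x[j] <- (if (up_dir) st$x[j] + tmax else st$x[j] - tmax)
    st$basis[leave] <- j
    piv <- st$Tab[leave, j]
    if (abs(piv) < .tf_pivot_tol) {
      st <- .refactor(st)
      next
    }
    prow <- st$Tab[leave, ] / piv
    colj <- st$Tab[, j]
    st$Tab <- st$Tab - outer(colj, prow)
    st$Tab[leave, ] <- prow
    since_refac <- since_refac + 1L
    if (since_refac >= refac_every) {
      st <- .refactor(st)
      since_refac <- 0L
    }
  }
}

.refactor <- function(st) {
  B <- st$A[, st$basis, drop = FALSE]
  Binv <- tryCatch(solve(B), error = function(e) .singularStop())
  st$Tab <- Binv %*% st$A
  # recompute basic values from nonbasic bounds for consistency
  nonbas <- setdiff(seq_len(ncol(st$A)), st$basis)
  xN <- st$x[nonbas]
  st$x[st$basis] <- as.vector(Binv %*% (st$rhs - st$A[, nonbas, drop = FALSE] %*% xN))
  st
}

.singularStop <- function() stop("simplex: singular basis encountered")
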