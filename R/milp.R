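# Branch-and-bound MILP on top of the dense simplex. Binary variables only
# (knockout indicators); depth-first with best-incumbent pruning and
# most-fractional branching. Deterministic: ties broken by variable index.

.tf_int_tol <- 1e-6

milpSolveDense <- function(obj, A, sense, rhs, lb, ub, maximize = TRUE,
                           binary_idx = integer(), node_limit = 100000L) {
  if (!length(binary_idx)) {
    r <- lpSolveDense(obj, A, sense, rhs, lb, ub, maximize)
    return(list(status = r$status, objval = r$objval, x = r$x, nodes = 1L))
  }
  best <- list(objval = if (maximize) -Inf else Inf, x = NULL)
  sgn <- if (maximize) 1 else -1
  nodes <- 0L
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) stop("milpSolveDense: node limit exceeded")
    r <- lpSolveDense(obj, A, sense, rhs, nd$lb, nd$ub, maximize)
    if (r$status != "optimal") next
    # bound pruning (relaxation can only be better than any integral child)
    if (!is.null(best$x) && sgn * r$objval <= sgn * best$objval + 1e-9) next
    xb <- r$x[binary_idx]
    frac <- abs(xb - round(xb))
    if (all(frac <= .tf_int_tol)) {
      cand_obj <- r$objval
      if (is.null(best$x) || sgn * cand_obj > sgn * best$objval + 1e-9) {
        x <- r$x
        x[binary_idx] <- round(xb)
        best <- list(objval = cand_obj, x = x)
      }
      next
    }
    j <- binary_idx[which.max(frac)]
    lo <- nd; hi <- nd
    lo$ub[j] <- 0
    hi$lb[j] <- 1
    # explore the "active" (y=1) child first: biological default is keeping
    # reactions, so incumbents appear early and prune well
    stack[[length(stack) + 1L]] <- lo
    stack[[length(stack) + 1L]] <- hi
  }
  if (is.null(best$x))
    return(list(status = "infeasible", objval = NA_real_, x = NULL,
                nodes = nodes))
  list(status = "optimal", objval = best$objval, x = best$x, nodes = nodes)
}
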