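# Dense two-phase primal simplex with Bland's rule.
#
# Solves   max (or min)  obj' x   s.t.  A_eq x = b_eq,  0 <= x <= ub
# where ub entries may be Inf.  Finite upper bounds are handled as slack
# rows.  Bland's pivoting rule guarantees termination on the heavily
# degenerate flux-balance programs (all equality right-hand sides zero)
# that this package solves.  Sizes here are small (at most a few hundred
# variables), so a dense tableau is adequate.

simplex_core <- function(tab, basis, cost, tol = 1e-9, max_iter = 100000L) {
  m <- nrow(tab)
  ncols <- ncol(tab) - 1L
  iter <- 0L
  repeat {
    cb <- cost[basis]
    rc <- cost[seq_len(ncols)] -
      as.vector(cb %*% tab[, seq_len(ncols), drop = FALSE])
    entering <- which(rc < -tol)
    if (!length(entering)) {
      return(list(status = "optimal", tab = tab, basis = basis))
    }
    j <- min(entering)                       # Bland: smallest index enters
    col <- tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- tab[pos, ncols + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    r <- cand[which.min(basis[cand])]        # Bland: smallest basis index leaves
    tab[r, ] <- tab[r, ] / tab[r, j]
    upd <- setdiff(seq_len(m), r)
    tab[upd, ] <- tab[upd, , drop = FALSE] - outer(tab[upd, j], tab[r, ])
    basis[r] <- j
    iter <- iter + 1L
    if (iter > max_iter) return(list(status = "maxiter"))
  }
}

lp_solve <- function(obj, A_eq, b_eq, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(A_eq) == n, length(ub) == n)
  fin <- which(is.finite(ub))
  k <- length(fin)
  A <- rbind(cbind(A_eq, matrix(0, nrow(A_eq), k)),
             cbind(diag(n)[fin, , drop = FALSE],
                   if (k) diag(k) else matrix(0, 0, 0)))
  b <- c(b_eq, ub[fin])
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  m <- nrow(A)
  nv <- n + k
  # phase 1: artificial basis
  tab <- cbind(A, diag(m), b)
  basis <- nv + seq_len(m)
  cost1 <- c(rep(0, nv), rep(1, m))
  p1 <- simplex_core(tab, basis, cost1, tol = tol)
  if (!identical(p1$status, "optimal")) return(list(status = p1$status))
  phase1_value <- sum(cost1[p1$basis] * p1$tab[, ncol(p1$tab)])
  if (phase1_value > 1e-7) return(list(status = "infeasible"))
  tab <- p1$tab
  basis <- p1$basis
  # drive surviving artificials out of the basis; drop redundant rows
  art <- which(basis > nv)
  drop_rows <- integer(0)
  for (r in art) {
    piv <- which(abs(tab[r, seq_len(nv)]) > tol)
    if (length(piv)) {
      j <- min(piv)
      tab[r, ] <- tab[r, ] / tab[r, j]
      upd <- setdiff(seq_len(nrow(tab)), r)
      tab[upd, ] <- tab[upd, , drop = FALSE] - outer(tab[upd, j], tab[r, ])
      basis[r] <- j
    } else {
      drop_rows <- c(drop_rows, r)
    }
  }
  if (length(drop_rows)) {
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  tab <- tab[, c(seq_len(nv), ncol(tab)), drop = FALSE]
  cost2 <- c(if (maximize) -obj else obj, rep(0, k))
  p2 <- simplex_core(tab, basis, cost2, tol = tol)
  if (!identical(p2$status, "optimal")) return(list(status = p2$status))
  rhs <- p2$tab[, ncol(p2$tab)]
  x_full <- numeric(nv)
  x_full[p2$basis] <- rhs
  value <- sum(obj * x_full[seq_len(n)])
  list(status = "optimal", x = x_full[seq_len(n)], value = value)
}
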