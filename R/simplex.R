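# Dense two-phase primal simplex for small linear programs
#
#   minimize    c' x
#   subject to  G x <= h,  x >= 0
#
# No LP solver ships with the supported environment, and the Dantzig
# decorrelation step needs one; problem sizes here are tiny (a few hundred
# variables at most), so a textbook tableau implementation with Bland's
# anti-cycling rule is adequate and exact up to floating point.

solve_lp <- function(cvec, G, h, tol = 1e-9, max_iter = 100000L) {
  G <- as.matrix(G)
  m <- nrow(G); nv <- ncol(G)
  stopifnot(length(cvec) == nv, length(h) == m)

  # equality form: G x + s = h with slack s; rows with negative rhs are
  # negated (flipping the slack sign) and given artificial variables
  A <- cbind(G, diag(m))
  b <- h
  neg <- which(b < 0)
  if (length(neg) > 0L) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  art_rows <- neg
  n_art <- length(art_rows)
  n_tot <- nv + m + n_art
  if (n_art > 0L) {
    Art <- matrix(0, m, n_art)
    Art[cbind(art_rows, seq_len(n_art))] <- 1
    A <- cbind(A, Art)
  }
  basis <- nv + seq_len(m)                 # slack basis by default
  if (n_art > 0L) basis[art_rows] <- nv + m + seq_len(n_art)

  tab <- cbind(A, b)

  pivot <- function(tab, r, cidx) {
    tab[r, ] <- tab[r, ] / tab[r, cidx]
    for (i in seq_len(nrow(tab))) {
      if (i != r && abs(tab[i, cidx]) > 0)
        tab[i, ] <- tab[i, ] - tab[i, cidx] * tab[r, ]
    }
    tab
  }

  run_simplex <- function(tab, basis, cost) {
    for (iter in seq_len(max_iter)) {
      # reduced costs
      cb <- cost[basis]
      z <- as.numeric(crossprod(cb, tab[, seq_len(n_tot), drop = FALSE]))
      red <- cost[seq_len(n_tot)] - z
      enter <- which(red < -tol)
      if (length(enter) == 0L) return(list(tab = tab, basis = basis,
                                           status = 0L))
      e <- min(enter)                      # Bland's rule
      col <- tab[, e]
      pos <- which(col > tol)
      if (length(pos) == 0L) return(list(tab = tab, basis = basis,
                                         status = 2L))  # unbounded
      ratios <- tab[pos, n_tot + 1L] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      r <- cand[which.min(basis[cand])]    # Bland tie-break on leaving var
      tab <- pivot(tab, r, e)
      basis[r] <- e
    }
    list(tab = tab, basis = basis, status = 3L)  # iteration limit
  }

  if (n_art > 0L) {
    cost1 <- c(rep(0, nv + m), rep(1, n_art))
    ph1 <- run_simplex(tab, basis, cost1)
    if (ph1$status != 0L)
      return(list(status = ph1$status, x = NULL,
                  message = "phase-1 failure"))
    obj1 <- sum(cost1[ph1$basis] * ph1$tab[, n_tot + 1L])
    if (obj1 > 1e-7)
      return(list(status = 1L, x = NULL, message = "infeasible"))
    tab <- ph1$tab; basis <- ph1$basis
    # drive any remaining artificial variables out of the basis
    for (r in which(basis > nv + m)) {
      piv_col <- which(abs(tab[r, seq_len(nv + m)]) > tol)
      if (length(piv_col) > 0L) {
        tab <- pivot(tab, r, piv_col[1L])
        basis[r] <- piv_col[1L]
      }
    }
    # freeze artificials at zero for phase 2
    tab[, nv + m + seq_len(n_art)] <- 0
  }
  cost2 <- c(cvec, rep(0, m + n_art))
  ph2 <- run_simplex(tab, basis, cost2)
  if (ph2$status == 2L)
    return(list(status = 2L, x = NULL, message = "unbounded"))
  if (ph2$status != 0L)
    return(list(status = ph2$status, x = NULL,
                message = "iteration limit reached"))
  x <- numeric(n_tot)
  x[ph2$basis] <- ph2$tab[, n_tot + 1L]
  list(status = 0L, x = x[seq_len(nv)],
       objective = sum(cvec * x[seq_len(nv)]), message = "optimal")
}
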