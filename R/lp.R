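## Dense two-phase simplex for linear programs with box bounds, the kind of LP
## flux balance analysis generates:  optimise  c'v  s.t.  A v (=,<=,>=) rhs,
## lb <= v <= ub.  Bounded variables are handled by shifting to x = v - lb and
## adding explicit upper-bound rows with slacks, which keeps the pivoting logic
## to the textbook standard form.  Bland's rule is used throughout, so the
## method cannot cycle; basic values are re-solved from the final basis with
## a dense linear solve so that equality residuals sit at machine precision.
## Intended for the small-to-medium networks this package works with (up to a
## few hundred reactions); it is a dense method and makes no use of sparsity.

.LP_BIG <- 1e6

#' Solve a linear program with box-bounded variables
#'
#' Maximizes (or minimizes) `obj %*% v` subject to `A v (dir) rhs` and
#' `lb <= v <= ub`. Infinite bounds are clipped to `+/- 1e6`.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (dense or `Matrix` sparse), m x n.
#' @param rhs right-hand sides, length m (default all zero).
#' @param dir constraint directions, one of `"="`, `"<="`, `">="` per row
#'   (default all `"="`).
#' @param lb,ub variable bounds, length n.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   and, when optimal, `objval` and the solution vector `x` (length n).
#' @keywords internal
lp_solve <- function(obj, A, rhs = NULL, dir = NULL, lb, ub,
                     maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(lb) == n, length(ub) == n)
  if (is.null(rhs)) rhs <- numeric(m)
  if (is.null(dir)) dir <- rep("=", m)
  stopifnot(length(rhs) == m, length(dir) == m, all(dir %in% c("=", "<=", ">=")))

  ## inequality rows -> equality rows with slack/surplus variables
  ineq <- which(dir != "=")
  if (length(ineq)) {
    Sl <- matrix(0, m, length(ineq))
    for (k in seq_along(ineq)) Sl[ineq[k], k] <- if (dir[ineq[k]] == "<=") 1 else -1
    A <- cbind(A, Sl)
    obj2 <- c(obj, numeric(length(ineq)))
    lb2 <- c(lb, numeric(length(ineq)))
    ub2 <- c(ub, rep(2 * .LP_BIG, length(ineq)))
  } else {
    obj2 <- obj; lb2 <- lb; ub2 <- ub
  }
  res <- lp_solve_eq(obj2, A, rhs, lb2, ub2, maximize = maximize, tol = tol)
  if (res$status == "optimal") {
    res$x <- res$x[seq_len(n)]
    res$objval <- sum(obj * res$x)
  }
  res
}

## Equality-constrained core: optimise obj'v s.t. A v = rhs, lb <= v <= ub.
lp_solve_eq <- function(obj, A, rhs, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  m <- nrow(A)
  lb <- pmax(lb, -.LP_BIG)
  ub <- pmin(ub, .LP_BIG)
  if (any(lb > ub + 1e-9)) return(list(status = "infeasible"))
  d <- pmax(ub - lb, 0)

  ## shift x = v - lb >= 0; standard form with upper-bound slack rows
  b1 <- rhs - as.vector(A %*% lb)
  Astd <- rbind(cbind(A, matrix(0, m, n)),
                cbind(diag(n), diag(n)))
  bstd <- c(b1, d)
  sgn <- ifelse(bstd < 0, -1, 1)
  Astd <- sgn * Astd
  bstd <- sgn * bstd

  nstruct <- 2L * n                      # x columns, then slack columns
  ntot <- nstruct + m                    # + artificials on the equality rows
  Afull <- cbind(Astd, rbind(diag(m), matrix(0, n, m)))
  Tb <- cbind(Afull, bstd)
  basis <- c(nstruct + seq_len(m),       # artificials basic on equality rows
             n + seq_len(n))             # slacks basic on bound rows
  kept <- seq_len(m + n)                 # original standard-form rows retained

  ## phase 1: drive artificials to zero
  c1 <- c(numeric(nstruct), rep(1, m))
  ph1 <- simplex_core(Tb, basis, c1, ncand = ntot, tol = tol)
  if (ph1$status != "optimal") return(list(status = "infeasible"))
  Tb <- ph1$Tb; basis <- ph1$basis
  if (sum(c1[basis] * Tb[, ncol(Tb)]) > 1e-7) return(list(status = "infeasible"))

  ## pivot leftover zero-valued artificials out of the basis; rows where no
  ## pivot exists are linearly dependent and dropped
  drop_rows <- integer(0)
  for (i in seq_along(basis)) {
    if (basis[i] > nstruct) {
      piv <- which(abs(Tb[i, seq_len(nstruct)]) > 1e-7)
      if (length(piv)) {
        Tb <- pivot_tableau(Tb, i, piv[1L])
        basis[i] <- piv[1L]
      } else drop_rows <- c(drop_rows, i)
    }
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
    kept <- kept[-drop_rows]
  }

  ## phase 2 (artificial columns are retained but may never re-enter)
  c2 <- c(if (maximize) -obj else obj, numeric(n), rep(0, m))
  ph2 <- simplex_core(Tb, basis, c2, ncand = nstruct, tol = tol)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  Tb <- ph2$Tb; basis <- ph2$basis

  ## re-solve basic values from the final basis for a clean residual
  xfull <- numeric(ntot)
  xb <- tryCatch(
    qr.solve(Afull[kept, basis, drop = FALSE], bstd[kept]),
    error = function(e) NULL)
  if (is.null(xb) || anyNA(xb) ||
      max(abs(xb - Tb[, ncol(Tb)])) > 1e-6) {
    xfull[basis] <- Tb[, ncol(Tb)]
  } else {
    xfull[basis] <- xb
  }
  x <- lb + xfull[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)             # clip roundoff at the bounds
  list(status = "optimal", x = x, objval = sum(obj * x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## One simplex run (minimization) on tableau Tb with the given starting basis.
## Columns 1..ncand are eligible to enter.  Entering variable: most negative
## reduced cost (Dantzig) until a run of degenerate pivots suggests stalling,
## then Bland's rule (lowest eligible index in, lowest basic index out among
## ratio ties), which provably cannot cycle.
simplex_core <- function(Tb, basis, cost, ncand, tol = 1e-9,
                         maxit = 100000L) {
  nc <- ncol(Tb)
  degen <- 0L
  for (it in seq_len(maxit)) {
    cb <- cost[basis]
    r <- cost[seq_len(ncand)] -
      as.vector(crossprod(Tb[, seq_len(ncand), drop = FALSE], cb))
    ent <- which(r < -tol)
    if (!length(ent)) return(list(Tb = Tb, basis = basis, status = "optimal"))
    j <- if (degen > 40L) ent[1L] else ent[which.min(r[ent])]
    col <- Tb[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
    ratios <- Tb[pos, nc] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    i <- if (degen > 40L) cand[which.min(basis[cand])] else cand[1L]
    degen <- if (rmin < tol) degen + 1L else 0L
    Tb <- pivot_tableau(Tb, i, j)
    basis[i] <- j
  }
  stop("simplex: iteration limit reached")
}

pivot_tableau <- function(Tb, i, j) {
  prow <- Tb[i, ] / Tb[i, j]
  Tb <- Tb - tcrossprod(Tb[, j], prow)
  Tb[i, ] <- prow
  Tb
}
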