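#' Solve a bounded linear program with equality constraints
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to \code{A x = b} and
#' \code{lb <= x <= ub}, using a deterministic two-phase dense simplex with
#' Bland's anti-cycling rule. All bounds must be finite; flux-balance
#' problems use the conventional +/-1000 default bounds, so this is not a
#' practical restriction.
#'
#' The solver is intentionally self-contained and pinned: identical inputs
#' always produce the identical optimal basis, which the downstream flux
#' analyses rely on for reproducibility.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A dense numeric constraint matrix (m x n) of equality rows.
#' @param b right-hand side, length m.
#' @param lb,ub finite variable bounds, length n.
#' @param maximize if TRUE, maximize the objective.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap (error if exceeded; Bland's rule makes
#'   cycling impossible so this only guards against pathological inputs).
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{x} (solution, on the original scale) and \code{objval}.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = FALSE,
                     tol = 1e-9, max_iter = 50000L) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A),
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))

  ## shift variables to y = x - lb >= 0 with y <= u = ub - lb
  m1 <- nrow(A)
  beq <- as.numeric(b - A %*% lb)
  u <- ub - lb
  cc <- if (maximize) -obj else obj

  ## fixed variables (u == 0) stay at zero; drop them from the LP
  fixed <- u <= tol
  keep <- which(!fixed)
  if (length(keep) == 0L) {
    x <- lb
    res <- max(abs(A %*% x - b))
    if (res > 1e-6) return(list(status = "infeasible", x = NULL, objval = NA_real_))
    return(list(status = "optimal", x = x, objval = sum(obj * x)))
  }
  Ak <- A[, keep, drop = FALSE]
  ck <- cc[keep]
  uk <- u[keep]
  nk <- length(keep)

  ## rows: m1 equality + nk upper-bound rows (y_i + s_i = u_i)
  ## cols: y (nk) + s (nk) + artificial (m1) + RHS
  sgn <- ifelse(beq < 0, -1, 1)
  M <- m1 + nk
  N <- 2L * nk + m1
  T <- matrix(0, M, N + 1L)
  T[seq_len(m1), seq_len(nk)] <- Ak * sgn
  T[seq_len(m1), 2L * nk + seq_len(m1)] <- diag(m1)
  T[seq_len(m1), N + 1L] <- beq * sgn
  T[m1 + seq_len(nk), seq_len(nk)] <- diag(nk)
  T[m1 + seq_len(nk), nk + seq_len(nk)] <- diag(nk)
  T[m1 + seq_len(nk), N + 1L] <- uk

  basis <- c(2L * nk + seq_len(m1), nk + seq_len(nk))

  ## cost rows carried with the tableau: row 1 = phase-1, row 2 = phase-2
  cost <- matrix(0, 2L, N + 1L)
  cost[1L, 2L * nk + seq_len(m1)] <- 1
  cost[2L, seq_len(nk)] <- ck
  ## price out the initial basis (artificials are basic in phase-1 row)
  for (i in seq_len(m1))
    cost[1L, ] <- cost[1L, ] - T[i, ]

  artificial <- c(rep(FALSE, 2L * nk), rep(TRUE, m1))

  pivot <- function(r, j) {
    piv <- T[r, j]
    T[r, ] <<- T[r, ] / piv
    colj <- T[, j]
    colj[r] <- 0
    T <<- T - outer(colj, T[r, ])
    cost <<- cost - outer(cost[, j], T[r, ])
    basis[r] <<- j
  }

  run_phase <- function(crow, allow_artificial) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("lp_solve: iteration limit exceeded")
      red <- cost[crow, seq_len(N)]
      cand <- which(red < -tol)
      if (!allow_artificial) cand <- cand[!artificial[cand]]
      if (length(cand) == 0L) return("optimal")
      j <- cand[1L]                       # Bland: smallest index enters
      col <- T[, j]
      rows <- which(col > tol)
      if (length(rows) == 0L) return("unbounded")
      ratio <- T[rows, N + 1L] / col[rows]
      rmin <- min(ratio)
      tied <- rows[ratio <= rmin + tol * (1 + abs(rmin))]
      r <- tied[which.min(basis[tied])]   # Bland: smallest basis index leaves
      pivot(r, j)
    }
  }

  ## phase 1: drive artificials to zero
  st <- run_phase(1L, allow_artificial = TRUE)
  if (st != "optimal" || -cost[1L, N + 1L] > 1e-7 * (1 + max(abs(beq))))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))

  ## pivot any basic artificial out on a non-artificial column if possible
  for (r in which(artificial[basis])) {
    j <- which(!artificial[seq_len(N)] & abs(T[r, seq_len(N)]) > tol)[1L]
    if (!is.na(j)) pivot(r, j)
  }

  ## phase 2
  st <- run_phase(2L, allow_artificial = FALSE)
  if (st == "unbounded")
    return(list(status = "unbounded", x = NULL, objval = NA_real_))

  yk <- numeric(N)
  yk[basis] <- T[, N + 1L]
  y <- numeric(n)
  y[keep] <- yk[seq_len(nk)]
  x <- y + lb
  list(status = "optimal", x = x, objval = sum(obj * x))
}
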