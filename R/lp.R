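# Dense two-phase simplex shared by every DEA solve.
#
# The DEA programs used here are small (tens of variables and constraints),
# so a dense tableau method is appropriate. Dantzig pricing is used first
# for speed, switching to Bland's rule after a fixed number of iterations
# to guarantee termination under degeneracy.

.simplex_core <- function(TT, basis, cost, tol, phase_one_n = 0L,
                          max_iter = 20000L) {
  m <- nrow(TT); N <- ncol(TT) - 1L
  bland_after <- 1000L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) return(list(status = "maxiter", TT = TT, basis = basis))
    cb <- cost[basis]
    red <- cost - as.vector(crossprod(TT[, seq_len(N), drop = FALSE], cb))
    red[basis] <- 0                        # exact zeros for basic columns
    cand <- which(red < -tol)
    if (!length(cand))
      return(list(status = "optimal", TT = TT, basis = basis))
    j <- if (it <= bland_after) cand[which.min(red[cand])] else cand[1L]
    d <- TT[, j]
    pos <- which(d > tol)
    if (!length(pos))
      return(list(status = "unbounded", TT = TT, basis = basis))
    ratios <- TT[pos, N + 1L] / d[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
    i <- ties[which.min(basis[ties])]      # Bland tie-break on leaving index
    # pivot on (i, j)
    TT[i, ] <- TT[i, ] / TT[i, j]
    others <- setdiff(seq_len(m), i)
    TT[others, ] <- TT[others, ] - outer(TT[others, j], TT[i, ])
    TT[, j] <- 0; TT[i, j] <- 1
    basis[i] <- j
  }
}

#' Solve a linear program
#'
#' Internal two-phase simplex used by the DEA and Malmquist solvers.
#' Minimises (or maximises) \code{objective \%*\% x} over \code{x >= 0}
#' subject to optional \code{<=}, \code{>=} and \code{==} constraint
#' blocks.
#'
#' @param objective numeric objective coefficients.
#' @param A_le,b_le less-than-or-equal constraint block (matrix, rhs).
#' @param A_ge,b_ge greater-than-or-equal constraint block.
#' @param A_eq,b_eq equality constraint block.
#' @param maximize logical; maximise instead of minimise.
#' @param eps feasibility/pivot tolerance.
#'
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"} or \code{"maxiter"}), \code{value}, and the
#'   solution vector \code{x} (NULL unless optimal).
#' @keywords internal
solve_lp <- function(objective, A_le = NULL, b_le = NULL,
                     A_ge = NULL, b_ge = NULL,
                     A_eq = NULL, b_eq = NULL,
                     maximize = FALSE, eps = 1e-9) {
  nv <- length(objective)
  as_block <- function(A, b) {
    if (is.null(A)) return(NULL)
    A <- as.matrix(A)
    stopifnot(ncol(A) == nv, nrow(A) == length(b))
    unname(cbind(A, b))
  }
  Mle <- as_block(A_le, b_le)
  Mge <- as_block(A_ge, b_ge)
  Meq <- as_block(A_eq, b_eq)
  n_le <- if (is.null(Mle)) 0L else nrow(Mle)
  n_ge <- if (is.null(Mge)) 0L else nrow(Mge)
  n_eq <- if (is.null(Meq)) 0L else nrow(Meq)
  m <- n_le + n_ge + n_eq
  stopifnot(m > 0L)

  # standard form: [A | slacks] x = b with slack +I on <= rows, -I on >= rows
  n_sl <- n_le + n_ge
  A <- matrix(0, m, nv + n_sl)
  b <- numeric(m)
  rows <- rbind(Mle, Mge, Meq)
  A[, seq_len(nv)] <- rows[, seq_len(nv), drop = FALSE]
  b <- rows[, nv + 1L]
  if (n_le) A[cbind(seq_len(n_le), nv + seq_len(n_le))] <- 1
  if (n_ge) A[cbind(n_le + seq_len(n_ge), nv + n_le + seq_len(n_ge))] <- -1
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # phase 1: artificial basis
  TT <- cbind(A, diag(m), b)
  basis <- ncol(A) + seq_len(m)
  c1 <- c(rep(0, ncol(A)), rep(1, m))
  # eliminate artificial costs from the start implicitly via reduced costs
  r1 <- .simplex_core(TT, basis, c1, eps)
  if (r1$status != "optimal")
    return(list(status = if (r1$status == "maxiter") "maxiter" else "infeasible",
                value = NA_real_, x = NULL))
  TT <- r1$TT; basis <- r1$basis
  feas <- sum(c1[basis] * TT[, ncol(TT)])
  if (feas > 1e-7 * (1 + max(abs(b))))
    return(list(status = "infeasible", value = NA_real_, x = NULL))

  # drive remaining (zero-valued) artificials out of the basis
  art <- which(basis > ncol(A))
  drop_rows <- integer(0)
  for (i in art) {
    piv <- which(abs(TT[i, seq_len(ncol(A))]) > eps)
    if (length(piv)) {
      j <- piv[1L]
      TT[i, ] <- TT[i, ] / TT[i, j]
      others <- setdiff(seq_len(m), i)
      TT[others, ] <- TT[others, ] - outer(TT[others, j], TT[i, ])
      TT[, j] <- 0; TT[i, j] <- 1
      basis[i] <- j
    } else drop_rows <- c(drop_rows, i)     # redundant constraint row
  }
  keep_cols <- c(seq_len(ncol(A)), ncol(TT))
  TT <- TT[, keep_cols, drop = FALSE]
  if (length(drop_rows)) {
    TT <- TT[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
    m <- nrow(TT)
  }

  c2 <- c(if (maximize) -objective else objective, rep(0, n_sl))
  r2 <- .simplex_core(TT, basis, c2, eps)
  if (r2$status != "optimal")
    return(list(status = r2$status, value = NA_real_, x = NULL))
  x_full <- numeric(ncol(A))
  x_full[r2$basis] <- r2$TT[, ncol(r2$TT)]
  x <- x_full[seq_len(nv)]
  val <- sum(objective * x)
  list(status = "optimal", value = val, x = x)
}
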