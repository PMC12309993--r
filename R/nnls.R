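#' Non-negative least squares (active set)
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` by the active-set method
#' in its normal-equation form (fast NNLS), which suits the deconvolution
#' setting: many solves on the same small design. Ties in the
#' gradient-selection step resolve to the smallest column index, so
#' duplicated columns give a deterministic (first-column) solution.
#'
#' @param A design matrix (m x n).
#' @param b response vector (length m).
#' @param tol tolerance on the dual feasibility check, relative to the
#'   largest gradient magnitude at x = 0.
#' @return list with `x` (solution), `residual` (b - A x), `passive`
#'   (logical, coefficients free at the solution).
#' @keywords internal
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  x <- fnnls(crossprod(A), drop(crossprod(A, b)), tol = tol)
  list(x = x, residual = drop(b - A %*% x), passive = x > 0)
}

# weighted NNLS: minimize sum w_i (b_i - (Ax)_i)^2
wnnls_solve <- function(A, b, w, tol = 1e-10) {
  x <- fnnls(crossprod(A, A * w), drop(crossprod(A, w * b)), tol = tol)
  list(x = x, residual = drop(b - A %*% x), passive = x > 0)
}

# core active-set iteration on the normal equations (Bro & de Jong style)
fnnls <- function(AtA, Atb, tol = 1e-10) {
  n <- length(Atb)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  scale <- max(abs(Atb), 1)
  w <- Atb
  max_outer <- 5L * n + 20L
  outer <- 0L
  while (any(!passive) && max(w[!passive]) > tol * scale &&
         outer < max_outer) {
    outer <- outer + 1L
    free <- which(!passive)
    j <- free[which.max(w[free])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      s <- tryCatch(
        solve(AtA[P, P, drop = FALSE], Atb[P]),
        error = function(e) NULL
      )
      if (is.null(s)) {  # singular subproblem: drop the newest column
        passive[j] <- FALSE
        break
      }
      if (all(s > tol * 1e-2)) {
        x[] <- 0
        x[P] <- s
        break
      }
      neg <- s <= tol * 1e-2
      idx <- P[neg]
      alpha <- min(x[idx] / (x[idx] - s[neg] + .Machine$double.eps))
      full <- numeric(n); full[P] <- s
      x <- x + alpha * (full - x)
      passive[passive & x <= tol * 1e-2] <- FALSE
      x[!passive] <- 0
    }
    w <- Atb - drop(AtA %*% x)
  }
  x
}
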