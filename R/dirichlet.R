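#' Dirichlet regression of cell-type proportions
#'
#' Models per-sample composition vectors `y_i` on the simplex as
#' `y_i ~ Dirichlet(alpha_i)` with the common parameterization
#' `alpha_ic = exp(x_i' beta_c)`: every concentration parameter is an
#' exponential-linear function of the sample covariates (e.g. genotype,
#' treatment and their interaction). The log-likelihood
#' `sum_i [ ln G(sum_c a_ic) - sum_c ln G(a_ic) + sum_c (a_ic - 1) ln y_ic ]`
#' is maximized by quasi-Newton (BFGS) with analytic gradient, starting
#' from moment-based intercepts. Wald z statistics use standard errors from
#' the inverse observed information.
#'
#' @param props a [proportion_table()] or samples x parts matrix (rows sum
#'   to 1; zeros handled by [squeeze_zeros()]).
#' @param design data.frame of sample covariates, rows aligned with
#'   `props`.
#' @param formula right-hand-side model formula over `design` columns
#'   (default intercept-only `~ 1`).
#' @param pseudo zero-handling pseudocount (see [squeeze_zeros()]).
#' @param max_iter BFGS iteration cap.
#' @return a `DirichletFit`: list with `beta` (terms x cell types), `se`,
#'   `wald` (`z`, `p`), `coef_table` (term, cell_type, beta, se, z, p),
#'   `loglik`, `converged`, `grad_norm`, `vcov`, and bookkeeping
#'   (`formula`, `cell_types`, `n`).
#' @export
fit_dirichlet <- function(props, design = NULL, formula = ~1, pseudo = 0,
                          max_iter = 500) {
  y <- if (inherits(props, "ProportionTable")) props$proportions else as.matrix(props)
  y <- squeeze_zeros(y, pseudo)
  if (any(y <= 0)) stop("proportions must be strictly interior after zero-handling")
  n <- nrow(y); C <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- sprintf("part%d", seq_len(C))
  if (is.null(design)) design <- data.frame(row.names = seq_len(n))
  if (nrow(design) != n) stop("design rows must align 1:1 with proportion rows")
  X <- stats::model.matrix(formula, design)
  p <- ncol(X)
  logy <- log(y)

  nll <- function(bvec) {
    beta <- matrix(bvec, p, C)
    eta <- X %*% beta
    if (any(eta > 30)) return(1e10)  # guard against overflow excursions
    alpha <- exp(eta)
    a0 <- rowSums(alpha)
    -sum(lgamma(a0) - rowSums(lgamma(alpha)) + rowSums((alpha - 1) * logy))
  }
  ngr <- function(bvec) {
    beta <- matrix(bvec, p, C)
    eta <- X %*% beta
    eta <- pmin(eta, 30)
    alpha <- exp(eta)
    a0 <- rowSums(alpha)
    # d ll / d eta_ic = alpha_ic * (digamma(a0_i) - digamma(alpha_ic) + log y_ic)
    dl <- alpha * (digamma(a0) - digamma(alpha) + logy)
    -as.vector(crossprod(X, dl))
  }

  beta0 <- dirichlet_init(y, X)
  opt <- stats::optim(as.vector(beta0), nll, ngr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12),
                      hessian = TRUE)
  converged <- opt$convergence == 0
  if (!converged) {
    warning("Dirichlet regression did not converge; inspect the fit")
  }
  beta <- matrix(opt$par, p, C, dimnames = list(colnames(X), colnames(y)))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    warning("observed information is singular (separation-like degeneracy); standard errors unavailable")
    se <- matrix(NA_real_, p, C, dimnames = dimnames(beta))
    vc <- NULL
  } else {
    se <- matrix(sqrt(diag(vc)), p, C, dimnames = dimnames(beta))
  }
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  coef_table <- data.frame(
    term = rep(rownames(beta), times = C),
    cell_type = rep(colnames(beta), each = p),
    beta = as.vector(beta), se = as.vector(se),
    z = as.vector(z), p = as.vector(pv),
    stringsAsFactors = FALSE
  )
  structure(
    list(beta = beta, se = se, wald = list(z = z, p = pv),
         coef_table = coef_table, loglik = -opt$value,
         converged = converged,
         grad_norm = max(abs(ngr(opt$par))),
         vcov = vc, formula = formula, cell_types = colnames(y), n = n),
    class = "DirichletFit"
  )
}

# moment-based start: common precision from component variances, then
# project log(alpha_hat) onto the column space of X per component.
dirichlet_init <- function(y, X) {
  m <- colMeans(y)
  v <- apply(y, 2, stats::var)
  s <- m * (1 - m) / pmax(v, 1e-10) - 1
  s <- stats::median(s[is.finite(s) & s > 0])
  if (!is.finite(s) || s <= 0) s <- ncol(y)
  la <- log(pmax(m * s, 1e-6))
  beta0 <- matrix(0, ncol(X), ncol(y))
  for (cc in seq_len(ncol(y))) {
    cf <- stats::lm.fit(X, rep(la[cc], nrow(X)))$coefficients
    cf[is.na(cf)] <- 0
    beta0[, cc] <- cf
  }
  beta0
}

#' @export
print.DirichletFit <- function(x, ...) {
  cat(sprintf("DirichletFit: %d samples, %d cell types, logLik = %.3f%s\n",
              x$n, length(x$cell_types), x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coef_table, digits = 4)
  invisible(x)
}

#' Dirichlet log-likelihood of a fitted model
#'
#' @param object a [fit_dirichlet()] result.
#' @param ... unused.
#' @return the maximized log-likelihood.
#' @export
logLik.DirichletFit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}
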