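# Negative-binomial GLM engine: per-gene IRLS with log link and offset,
# per-gene dispersion by maximum (optionally small-sample adjusted)
# likelihood with a method-of-moments start.

# IRLS for fixed dispersion phi (phi = 0 is Poisson). ln mu = offset + X beta.
# Weighted LS step solved via Cholesky on the normal equations (X is well
# conditioned here: cell means plus a few covariates).
nb_irls <- function(y, X, offset, phi, beta0 = NULL, max_iter = 100,
                    tol = 1e-8) {
  n <- length(y); p <- ncol(X)
  if (is.null(beta0)) {
    # least-squares start on shifted log counts
    beta0 <- tryCatch(qr.coef(qr(X), log(y + 0.5) - offset),
                      error = function(e) rep(0, p))
    beta0[is.na(beta0)] <- 0
  }
  eta <- pmin(offset + drop(X %*% beta0), 50)
  mu <- pmax(exp(eta), 1e-10)
  dev <- nb_deviance(y, mu, phi)
  beta <- beta0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    XW <- X * W
    beta_new <- tryCatch(
      drop(chol2inv(chol(crossprod(X, XW))) %*% crossprod(XW, z)),
      error = function(e) {
        cf <- stats::lm.wfit(X, z, W)$coefficients
        cf[is.na(cf)] <- 0
        cf
      }
    )
    eta_new <- pmin(offset + drop(X %*% beta_new), 50)
    mu_new <- pmax(exp(eta_new), 1e-10)
    dev_new <- nb_deviance(y, mu_new, phi)
    # step-halving if deviance worsens
    half <- 0
    while (!is.finite(dev_new) || (dev_new > dev + 1e-8)) {
      half <- half + 1
      if (half > 20) break
      beta_new <- (beta + beta_new) / 2
      eta_new <- pmin(offset + drop(X %*% beta_new), 50)
      mu_new <- pmax(exp(eta_new), 1e-10)
      dev_new <- nb_deviance(y, mu_new, phi)
    }
    delta <- abs(dev - dev_new)
    beta <- beta_new; eta <- eta_new; mu <- mu_new
    if (is.finite(dev) && delta < tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  W <- mu / (1 + phi * mu)
  xtwx <- crossprod(X, X * W)
  list(beta = beta, mu = mu, eta = eta, deviance = dev, xtwx = xtwx,
       converged = converged)
}

nb_deviance <- function(y, mu, phi) {
  if (phi < 1e-12) {
    r <- y * log(ifelse(y > 0, y / mu, 1)) - (y - mu)
    return(2 * sum(r))
  }
  a <- y * log(ifelse(y > 0, y / mu, 1))
  b <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
  2 * sum(a - b)
}

nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-10) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# profile (adjusted) likelihood in log-phi given current mu; the adjustment
# subtracts 0.5 * logdet(X'WX), the usual REML-like small-sample correction
# for estimating dispersion after fitting p mean parameters.
nb_phi_mle <- function(y, X, mu, adjust = TRUE,
                       interval = c(1e-8, 50)) {
  obj <- function(lphi) {
    phi <- exp(lphi)
    ll <- nb_loglik(y, mu, phi)
    if (adjust) {
      W <- mu / (1 + phi * mu)
      d <- determinant(crossprod(X, X * W), logarithm = TRUE)$modulus
      ll <- ll - 0.5 * as.numeric(d)
    }
    -ll
  }
  opt <- stats::optimize(obj, log(interval), tol = 1e-4)
  exp(opt$minimum)
}

# full per-gene fit: Poisson start, moment dispersion, alternate
# phi <-> beta updates.
nb_fit_gene <- function(y, X, offset, adjust = TRUE, max_iter = 100,
                        tol = 1e-8) {
  n <- length(y); p <- ncol(X)
  pois <- nb_irls(y, X, offset, phi = 0, max_iter = max_iter, tol = tol)
  mu <- pois$mu
  phi <- sum((y - mu)^2 - mu) / sum(mu^2)
  phi <- min(max(phi, 1e-8), 50)
  fit <- pois
  for (round in 1:3) {
    phi_new <- nb_phi_mle(y, X, fit$mu, adjust = adjust)
    if (abs(log(phi_new) - log(phi)) < 1e-3 && round > 1) {
      phi <- phi_new
      break
    }
    if (phi_new > 1e-7 || round == 1) {
      fit <- nb_irls(y, X, offset, phi_new, beta0 = fit$beta,
                     max_iter = max_iter, tol = tol)
    }
    if (abs(log(phi_new) - log(phi)) < 1e-3) {
      phi <- phi_new
      break
    }
    phi <- phi_new
  }
  cov <- tryCatch(solve(fit$xtwx), error = function(e) NULL)
  if (is.null(cov)) {
    cov <- matrix(NA_real_, p, p)
    fit$converged <- FALSE
  }
  list(beta = fit$beta, se = sqrt(pmax(diag(cov), 0)), cov = cov,
       phi = phi, mu = fit$mu, converged = fit$converged)
}
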