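#' Expression filter for differential-expression testing
#'
#' Keeps genes with more than `min_reads` reads in at least `min_samples`
#' samples (defaults: > 10 reads in >= 4 samples). Filtered genes carry no
#' test results downstream.
#'
#' @param counts raw integer counts, genes x samples.
#' @param min_reads strict lower bound on per-sample reads.
#' @param min_samples number of samples that must exceed `min_reads`.
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, min_reads = 10, min_samples = 4) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > min_reads) >= min_samples
  if (!any(keep)) stop("no genes survive the expression filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: the median, over genes with a
#' positive geometric mean, of the ratio of the sample's count to that
#' geometric mean. Falls back to library-size ratios (normalized to
#' geometric mean 1) with a warning when no gene is positive in all
#' samples.
#'
#' @param counts filtered counts, genes x samples.
#' @return named numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- log(counts)
  geo <- rowMeans(lg)
  ok <- is.finite(geo)
  if (!any(ok)) {
    warning("no gene is positive in all samples; using library-size ratios")
    ls <- colSums(counts)
    s <- ls / exp(mean(log(ls)))
  } else {
    s <- apply(lg[ok, , drop = FALSE], 2, function(col) {
      exp(stats::median(col - geo[ok]))
    })
  }
  stats::setNames(s, colnames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' NAs are passed through.
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene negative-binomial differential expression
#'
#' Fits, for every gene, a negative-binomial GLM with log link and
#' log-size-factor offset: `counts_gi ~ NB(mu_gi, phi_g)` with
#' `ln mu_gi = ln s_i + x_i' beta_g`. Dispersion is estimated per gene by
#' maximum likelihood from a method-of-moments start (no empirical-Bayes
#' shrinkage across genes; `dispersion_adjust = TRUE` switches to a
#' REML-like adjusted profile likelihood); coefficients get Wald tests and
#' per-coefficient BH adjustment across genes.
#'
#' Compositional covariates enter the model via `covariates` (a
#' [CompositionCovariates][clr_transform()] object or plain matrix): their
#' columns are appended to the design and to the formula as additive
#' terms. CLR components sum to zero across the full set, so with an
#' intercept only a subset (by default the major cell types, e.g.
#' cardiomyocyte and fibroblast) should be included — pass the subset you
#' want; the design is checked for full rank either way.
#'
#' @param counts filtered integer counts, genes x samples.
#' @param design data.frame of sample covariates (factors with explicit
#'   levels), rows aligned with count columns.
#' @param formula right-hand-side formula over `design` columns, e.g.
#'   `~ genotype * treatment` or cell-means `~ 0 + group`.
#' @param covariates optional `CompositionCovariates` or matrix of extra
#'   per-sample columns appended as additive terms.
#' @param size_factors optional per-sample normalization; computed by
#'   [estimate_size_factors()] when `NULL`.
#' @param dispersion_adjust use the small-sample adjusted profile
#'   likelihood for dispersion instead of the plain per-gene MLE (default
#'   FALSE).
#' @param max_iter,tol IRLS controls.
#' @return a `DEFit`: list with `beta`, `se` (genes x coefficients, natural
#'   log scale), `cov` (coefficients x coefficients x genes), `phi`,
#'   `base_mean` (mean of size-factor-normalized counts), `size_factors`,
#'   `X`, `converged`. Use [de_results()] or [wald_contrast()] to extract
#'   result tables.
#' @export
fit_de <- function(counts, design, formula, covariates = NULL,
                   size_factors = NULL, dispersion_adjust = FALSE,
                   max_iter = 100, tol = 1e-8) {
  counts <- as.matrix(counts)
  if (nrow(design) != ncol(counts)) {
    stop("design rows must align 1:1 with count columns")
  }
  if (!is.null(covariates)) {
    cv <- if (inherits(covariates, "CompositionCovariates")) {
      covariates$values
    } else {
      as.matrix(covariates)
    }
    if (nrow(cv) != ncol(counts)) stop("covariate rows must align with samples")
    cols <- colnames(cv)
    if (is.null(cols)) cols <- sprintf("cov%d", seq_len(ncol(cv)))
    cols <- make.names(cols)
    colnames(cv) <- cols
    design <- cbind(design, as.data.frame(cv))
    formula <- stats::update(
      formula, paste("~ . +", paste(cols, collapse = " + "))
    )
  }
  X <- stats::model.matrix(formula, design)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; drop collinear covariates (all CLR components with an intercept are collinear)")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  offset <- log(size_factors)

  G <- nrow(counts); p <- ncol(X)
  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(counts), colnames(X)))
  se <- beta
  covs <- array(NA_real_, c(p, p, G))
  phi <- stats::setNames(numeric(G), rownames(counts))
  conv <- stats::setNames(logical(G), rownames(counts))
  for (g in seq_len(G)) {
    fg <- nb_fit_gene(counts[g, ], X, offset, adjust = dispersion_adjust,
                      max_iter = max_iter, tol = tol)
    beta[g, ] <- fg$beta
    se[g, ] <- fg$se
    covs[, , g] <- fg$cov
    phi[g] <- fg$phi
    conv[g] <- fg$converged
  }
  structure(
    list(beta = beta, se = se, cov = covs, phi = phi,
         base_mean = rowMeans(sweep(counts, 2, size_factors, "/")),
         size_factors = size_factors, X = X, formula = formula,
         converged = conv),
    class = "DEFit"
  )
}

#' @export
print.DEFit <- function(x, ...) {
  cat(sprintf("DEFit: %d genes, %d coefficients (%s), %d/%d converged\n",
              nrow(x$beta), ncol(x$beta),
              paste(colnames(x$beta), collapse = ", "),
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' Wald test of a model coefficient
#'
#' @param fit a [fit_de()] result.
#' @param coef coefficient name or index.
#' @return data.frame with columns gene, baseMean, log2FC, lfcSE, stat,
#'   pvalue, padj (BH across genes; non-converged genes get NA p-values).
#' @export
de_results <- function(fit, coef) {
  stopifnot(inherits(fit, "DEFit"))
  if (is.character(coef)) coef <- match(coef, colnames(fit$beta))
  if (is.na(coef) || coef < 1 || coef > ncol(fit$beta)) {
    stop("unknown coefficient")
  }
  b <- fit$beta[, coef]; s <- fit$se[, coef]
  stat <- b / s
  pv <- 2 * stats::pnorm(-abs(stat))
  pv[!fit$converged | !is.finite(stat)] <- NA
  data.frame(
    gene = rownames(fit$beta), baseMean = fit$base_mean,
    log2FC = b / log(2), lfcSE = s / log(2), stat = stat,
    pvalue = pv, padj = bh_adjust(pv), row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Wald test of a linear contrast of coefficients
#'
#' @param fit a [fit_de()] result.
#' @param contrast numeric vector, one entry per model coefficient (e.g.
#'   `+1` on a condition's cell mean and `-1` on the baseline's).
#' @return data.frame as in [de_results()].
#' @export
wald_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "DEFit"))
  p <- ncol(fit$beta)
  if (length(contrast) != p) stop("contrast length must match coefficients")
  est <- drop(fit$beta %*% contrast)
  G <- nrow(fit$beta)
  cc <- as.vector(outer(contrast, contrast))
  var <- colSums(matrix(fit$cov, p * p, G) * cc)
  s <- sqrt(pmax(var, 0))
  stat <- est / s
  pv <- 2 * stats::pnorm(-abs(stat))
  pv[!fit$converged | !is.finite(stat)] <- NA
  data.frame(
    gene = rownames(fit$beta), baseMean = fit$base_mean,
    log2FC = est / log(2), lfcSE = s / log(2), stat = stat,
    pvalue = pv, padj = bh_adjust(pv), row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Fit the same DE model under several covariate representations
#'
#' Runs [fit_de()] once per entry of `covariate_sets` (e.g. `none`, `raw`,
#' `clr`, `pca`) on an identical gene universe, for before/after
#' significance comparisons and benchmarking.
#'
#' @param counts filtered counts, genes x samples.
#' @param design data.frame of sample covariates.
#' @param formula base right-hand-side formula.
#' @param covariate_sets named list; each element is `NULL` (no adjustment),
#'   a `CompositionCovariates`, or a matrix of extra columns.
#' @param ... passed to [fit_de()].
#' @return named list of `DEFit` objects, one per representation.
#' @export
compare_models <- function(counts, design, formula,
                           covariate_sets = list(none = NULL), ...) {
  if (is.null(names(covariate_sets))) {
    stop("covariate_sets must be a named list")
  }
  lapply(covariate_sets, function(cv) {
    fit_de(counts, design, formula, covariates = cv, ...)
  })
}
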