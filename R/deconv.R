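#' Proportion table
#'
#' Per-sample cell-type RNA fractions. Rows are samples, columns cell
#' types; every row is non-negative and sums to 1. The values are RNA
#' fractions ("how much RNA comes from each cell type"), not cell counts:
#' large cells (cardiomyocytes) contribute disproportionate RNA per cell.
#'
#' @param proportions numeric matrix, samples x cell types, with dimnames.
#' @return a `ProportionTable`.
#' @export
proportion_table <- function(proportions) {
  proportions <- as.matrix(proportions)
  if (is.null(colnames(proportions))) stop("cell types must be named")
  if (is.null(rownames(proportions))) {
    rownames(proportions) <- sprintf("sample%d", seq_len(nrow(proportions)))
  }
  if (any(proportions < -1e-12)) stop("proportions must be non-negative")
  rs <- rowSums(proportions)
  if (any(abs(rs - 1) > 1e-9)) stop("each row must sum to 1 (within 1e-9)")
  structure(
    list(proportions = pmax(proportions, 0),
         sample_ids = rownames(proportions),
         cell_types = colnames(proportions)),
    class = "ProportionTable"
  )
}

#' @export
print.ProportionTable <- function(x, ...) {
  cat(sprintf("ProportionTable: %d samples x %d cell types\n",
              length(x$sample_ids), length(x$cell_types)))
  print(utils::head(round(x$proportions, 4)))
  invisible(x)
}

#' Weighted-NNLS deconvolution of one or more bulk samples
#'
#' Estimates cell-type RNA fractions from bulk counts restricted to the
#' signature's marker genes. Per sample, the relative abundance
#' `y_g = counts_g / sum(marker counts)` is modeled as
#' `y_g = sum_k c_k S_k theta_gk` with `c_k >= 0`, solved by iteratively
#' re-weighted non-negative least squares: an unweighted NNLS fit
#' initializes the coefficients, then per-gene weights
#' `w_g = 1 / (residual_g^2 + sum_k c_k^2 sigma2_gk S_k^2 + eps)`
#' down-weight genes with large residuals or high cross-subject reference
#' variance, and the weighted problem is re-solved until the coefficients
#' stabilize. Reported proportions are `p_k = c_k S_k / sum_j c_j S_j`, the
#' normalized cell-type RNA fractions.
#'
#' With an all-zero `sigma2` (single-subject reference) the scheme degrades
#' gracefully to residual-only weighting.
#'
#' @param bulk counts matrix (genes x samples) or vector; only signature
#'   marker genes are used, so extra rows are ignored.
#' @param signature a [build_signature()] object.
#' @param max_iter maximum re-weighting iterations.
#' @param tol convergence tolerance on the maximum relative change in `c`.
#' @param eps weight stabilizer.
#' @return a `DeconvFit`: list with `proportions` (a [proportion_table()]),
#'   `weights` (marker genes x samples), `residuals` (same shape),
#'   `n_iterations`, `converged`.
#' @export
estimate_proportions <- function(bulk, signature, max_iter = 1000,
                                 tol = 1e-6, eps = 1e-8) {
  stopifnot(inherits(signature, "Signature"))
  if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1,
                                         dimnames = list(names(bulk), "sample1"))
  if (is.null(rownames(bulk))) stop("bulk matrix must carry gene row names")
  if (is.null(colnames(bulk))) {
    colnames(bulk) <- sprintf("sample%d", seq_len(ncol(bulk)))
  }
  markers <- signature$gene_ids
  missing <- setdiff(markers, rownames(bulk))
  if (length(missing) > 0) {
    stop(sprintf("bulk is missing %d signature marker genes (e.g. %s)",
                 length(missing), missing[1]))
  }
  Y <- as.matrix(bulk[markers, , drop = FALSE])
  S <- signature$cell_sizes
  A <- sweep(signature$theta, 2, S, "*")
  if (any(duplicated(t(A)))) {
    warning("signature has identical cell-type columns; NNLS resolves ties to the smallest index")
  }
  V <- sweep(signature$sigma2, 2, S^2, "*")  # sigma2_gk * S_k^2

  n_s <- ncol(Y)
  K <- length(S)
  props <- matrix(0, n_s, K, dimnames = list(colnames(Y), signature$cell_types))
  weights <- matrix(NA_real_, length(markers), n_s,
                    dimnames = list(markers, colnames(Y)))
  resids <- weights
  iters <- integer(n_s)
  conv <- logical(n_s)

  for (j in seq_len(n_s)) {
    tot <- sum(Y[, j])
    if (tot <= 0) stop(sprintf("bulk sample '%s' has zero marker counts", colnames(Y)[j]))
    y <- Y[, j] / tot
    fit <- nnls_solve(A, y)
    cc <- fit$x
    it <- 0L
    converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      w <- 1 / (fit$residual^2 + drop(V %*% cc^2) + eps)
      fit <- wnnls_solve(A, y, w)
      rel <- max(abs(fit$x - cc) / pmax(abs(cc), 1e-12))
      cc <- fit$x
      if (rel < tol) { converged <- TRUE; break }
    }
    if (sum(cc * S) <= 0) {
      stop(sprintf("deconvolution failed for sample '%s': all coefficients zero",
                   colnames(Y)[j]))
    }
    props[j, ] <- cc * S / sum(cc * S)
    weights[, j] <- 1 / (fit$residual^2 + drop(V %*% cc^2) + eps)
    resids[, j] <- fit$residual
    iters[j] <- it
    conv[j] <- converged
  }
  structure(
    list(proportions = proportion_table(props), weights = weights,
         residuals = resids, n_iterations = iters, converged = conv),
    class = "DeconvFit"
  )
}

#' @export
print.DeconvFit <- function(x, ...) {
  cat(sprintf("DeconvFit: %d samples, %s\n", length(x$n_iterations),
              if (all(x$converged)) "all converged" else "NOT all converged"))
  print(x$proportions)
  invisible(x)
}

#' Deconvolve a cohort of bulk samples
#'
#' Convenience wrapper over [estimate_proportions()] returning just the
#' [proportion_table()].
#'
#' @inheritParams estimate_proportions
#' @return a `ProportionTable` with one row per bulk sample.
#' @export
deconvolve_cohort <- function(bulk, signature, max_iter = 1000, tol = 1e-6) {
  estimate_proportions(bulk, signature, max_iter = max_iter, tol = tol)$proportions
}
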