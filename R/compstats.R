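#' Replace zeros in a proportion table
#'
#' Compositional transforms and the Dirichlet likelihood need strictly
#' positive parts. When zeros are present the table is compressed toward
#' the barycenter with `y* = (y * (n - 1) + 1/C) / n` (n = number of
#' samples, C = number of parts), the convention of the Dirichlet-regression
#' literature; alternatively a pseudocount can be added and rows re-closed.
#'
#' @param p samples x parts matrix with rows summing to 1.
#' @param pseudo if > 0, add this pseudocount and renormalize instead of
#'   compressing.
#' @return matrix of the same shape with strictly positive rows summing to 1.
#' @export
squeeze_zeros <- function(p, pseudo = 0) {
  p <- as.matrix(p)
  if (pseudo > 0) {
    p <- p + pseudo
    return(p / rowSums(p))
  }
  if (any(p == 0)) {
    n <- nrow(p)
    p <- (p * (n - 1) + 1 / ncol(p)) / n
  }
  p
}

#' Centered log-ratio transform of cell-type proportions
#'
#' Maps each composition to `z_k = ln(p_k / g(p))` with `g` the geometric
#' mean of the parts, taking the simplex to an unconstrained zero-sum space
#' where proportions can serve as regression covariates without the
#' unit-sum coupling.
#'
#' @param props a [proportion_table()] or samples x parts matrix.
#' @param pseudo passed to [squeeze_zeros()].
#' @return a `CompositionCovariates` object (list with `values`, `kind =
#'   "clr"`, `component_labels`); rows of `values` sum to 0.
#' @export
clr_transform <- function(props, pseudo = 0) {
  p <- if (inherits(props, "ProportionTable")) props$proportions else as.matrix(props)
  p <- squeeze_zeros(p, pseudo)
  if (any(p <= 0)) stop("proportions must be strictly positive after zero-handling")
  lp <- log(p)
  z <- lp - rowMeans(lp)
  structure(
    list(values = z, kind = "clr", component_labels = colnames(z)),
    class = "CompositionCovariates"
  )
}

#' Principal components of cell-type proportions
#'
#' Column-centers the proportion matrix and projects onto the leading
#' principal axes. Because rows sum to one, at most C - 1 components are
#' non-degenerate.
#'
#' @param props a [proportion_table()] or samples x parts matrix.
#' @param n_components number of scores to keep (default 1, the dominant
#'   axis of compositional variation).
#' @return a `CompositionCovariates` with `kind = "pca"`; attribute
#'   `explained_variance` gives the per-component share of total variance,
#'   and `rotation` the loadings.
#' @export
pca_props <- function(props, n_components = 1) {
  p <- if (inherits(props, "ProportionTable")) props$proportions else as.matrix(props)
  if (nrow(p) < 2) stop("PCA needs at least 2 samples")
  if (n_components > ncol(p)) {
    stop(sprintf("n_components (%d) exceeds the number of cell types (%d)",
                 n_components, ncol(p)))
  }
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(p)
  out <- structure(
    list(values = scores, kind = "pca", component_labels = colnames(scores)),
    class = "CompositionCovariates"
  )
  tot <- sum(pc$sdev^2)
  attr(out, "explained_variance") <-
    if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  attr(out, "rotation") <- pc$rotation[, seq_len(k), drop = FALSE]
  out
}

#' Raw proportions as covariates
#'
#' @param props a [proportion_table()] or matrix.
#' @param cell_types optional subset of columns to keep.
#' @return a `CompositionCovariates` with `kind = "raw"`.
#' @export
raw_covariates <- function(props, cell_types = NULL) {
  p <- if (inherits(props, "ProportionTable")) props$proportions else as.matrix(props)
  if (!is.null(cell_types)) {
    if (!all(cell_types %in% colnames(p))) stop("unknown cell types requested")
    p <- p[, cell_types, drop = FALSE]
  }
  structure(
    list(values = p, kind = "raw", component_labels = colnames(p)),
    class = "CompositionCovariates"
  )
}

#' @export
print.CompositionCovariates <- function(x, ...) {
  cat(sprintf("CompositionCovariates (%s): %d samples x %d components\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}
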