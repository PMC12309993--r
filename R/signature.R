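#' Build a deconvolution signature from a clustered reference
#'
#' For every cell type the per-gene relative abundance theta is computed per
#' subject (counts of the gene over all nuclei of that type, divided by the
#' type's total counts — over the full gene universe, so per-subject columns
#' sum to one) and then averaged across subjects. The across-subject sample
#' variance sigma2 captures reference uncertainty and feeds the weighted
#' deconvolution. Cell-size factors S_k (mean total counts per nucleus of
#' type k) convert RNA fractions to the scale of the linear model.
#'
#' Both theta and sigma2 are returned restricted to the marker panel.
#'
#' @param reference a deduplicated [clustered_reference()], already subset to
#'   the bulk/reference gene intersection (see [intersect_genes()]).
#' @param panel a [select_markers()] panel.
#' @param universe character vector, the shared gene universe; panel markers
#'   must be contained in it.
#' @return `Signature` object: list with `theta` (markers x cell types),
#'   `sigma2` (same shape), `cell_sizes`, `gene_ids`, `cell_types`.
#' @export
build_signature <- function(reference, panel, universe = reference$gene_ids) {
  stopifnot(inherits(reference, "ClusteredReference"),
            inherits(panel, "MarkerPanel"))
  markers <- panel_genes(panel)
  if (!all(markers %in% universe)) {
    stop("panel markers must be a subset of the gene universe")
  }
  reference <- subset_genes(reference, universe)
  cl <- reference$nucleus_meta$cluster
  subj <- reference$nucleus_meta$subject
  types <- intersect(names(panel$markers), levels(cl))
  subjects <- levels(subj)

  n_mark <- length(markers)
  theta <- matrix(0, n_mark, length(types), dimnames = list(markers, types))
  sigma2 <- matrix(0, n_mark, length(types), dimnames = list(markers, types))
  cell_sizes <- stats::setNames(numeric(length(types)), types)
  midx <- match(markers, reference$gene_ids)

  for (ty in types) {
    in_type <- cl == ty
    if (!any(in_type)) stop(sprintf("cell type '%s' has no nuclei", ty))
    per_subj <- list()
    for (s in subjects) {
      sel <- in_type & subj == s
      if (!any(sel)) next  # type absent in this subject
      tot <- sum(reference$counts[, sel, drop = FALSE])
      th <- Matrix::rowSums(reference$counts[, sel, drop = FALSE]) / tot
      per_subj[[s]] <- th[midx]
    }
    mat <- do.call(cbind, per_subj)
    theta[, ty] <- rowMeans(mat)
    if (ncol(mat) >= 2) {
      sigma2[, ty] <- apply(mat, 1, stats::var)
    } else {
      warning(sprintf(
        "cell type '%s' present in < 2 subjects; sigma2 set to 0", ty))
    }
    cell_sizes[ty] <- mean(Matrix::colSums(reference$counts[, in_type, drop = FALSE]))
  }
  structure(
    list(theta = theta, sigma2 = sigma2, cell_sizes = cell_sizes,
         gene_ids = markers, cell_types = types),
    class = "Signature"
  )
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature: %d marker genes x %d cell types\n",
              length(x$gene_ids), length(x$cell_types)))
  invisible(x)
}
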