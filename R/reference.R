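#' Clustered single-nucleus reference
#'
#' Bundle a gene-by-nucleus count matrix with per-nucleus cluster and subject
#' labels. This is the raw material for marker selection
#' ([select_markers()]), signature construction ([build_signature()]) and
#' pseudo-bulk simulation ([simulate_experiment()]).
#'
#' @param counts non-negative integer matrix or `dgCMatrix`, genes in rows,
#'   nuclei in columns. Row names are gene symbols (may contain duplicates
#'   until [dedupe_genes()] is applied).
#' @param cluster_label factor or character vector, one cluster (cell-type)
#'   label per nucleus.
#' @param subject_id factor or character vector, one subject per nucleus.
#'   At least two subjects are needed for cross-subject variance estimation;
#'   a single subject is allowed but downstream variances degrade to zero.
#'
#' @return An object of class `ClusteredReference`: a list with elements
#'   `counts` (a `dgCMatrix`), `gene_ids`, and `nucleus_meta` (a data.frame
#'   with columns `cluster` and `subject`).
#' @export
clustered_reference <- function(counts, cluster_label, subject_id) {
  if (is.null(rownames(counts))) {
    stop("`counts` must carry gene symbols as row names")
  }
  if (length(cluster_label) != ncol(counts) || length(subject_id) != ncol(counts)) {
    stop("cluster_label and subject_id must have one entry per nucleus (column)")
  }
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("`counts` must be non-negative")
  meta <- data.frame(
    cluster = factor(cluster_label),
    subject = factor(subject_id),
    stringsAsFactors = FALSE
  )
  if (anyNA(meta$cluster) || anyNA(meta$subject)) {
    stop("every nucleus needs exactly one cluster label and one subject id")
  }
  structure(
    list(counts = counts, gene_ids = rownames(counts), nucleus_meta = meta),
    class = "ClusteredReference"
  )
}

#' @export
print.ClusteredReference <- function(x, ...) {
  cat(sprintf(
    "ClusteredReference: %d genes x %d nuclei | %d clusters, %d subjects\n",
    nrow(x$counts), ncol(x$counts),
    nlevels(x$nucleus_meta$cluster), nlevels(x$nucleus_meta$subject)
  ))
  invisible(x)
}

#' Resolve duplicate gene symbols
#'
#' Gene symbol harmonization across annotation sources leaves duplicate
#' symbols; for each duplicated symbol only the row with the highest mean
#' expression across all nuclei is kept. Deterministic: ties on the mean are
#' broken by the first occurrence.
#'
#' @param reference a [clustered_reference()] object.
#' @return the reference with unique `gene_ids`; references that are already
#'   duplicate-free are returned unchanged.
#' @export
dedupe_genes <- function(reference) {
  stopifnot(inherits(reference, "ClusteredReference"))
  ids <- reference$gene_ids
  if (!anyDuplicated(ids)) return(reference)
  means <- Matrix::rowMeans(reference$counts)
  # stable order: by symbol, then decreasing mean; keep first per symbol
  ord <- order(ids, -means)
  keep <- ord[!duplicated(ids[ord])]
  keep <- sort(keep)
  reference$counts <- reference$counts[keep, , drop = FALSE]
  reference$gene_ids <- ids[keep]
  reference
}

#' Intersect reference and bulk gene universes
#'
#' Downstream stages (marker selection restricted to deconvolvable genes,
#' signature construction, simulation) operate only on genes measured in both
#' the single-nucleus reference and the bulk assay.
#'
#' @param reference_genes character vector of deduplicated reference symbols.
#' @param bulk_genes character vector of deduplicated bulk symbols.
#' @return the sorted intersection.
#' @export
intersect_genes <- function(reference_genes, bulk_genes) {
  if (anyDuplicated(reference_genes) || anyDuplicated(bulk_genes)) {
    stop("gene lists must be deduplicated before intersection")
  }
  common <- sort(intersect(reference_genes, bulk_genes))
  if (length(common) == 0L) {
    stop(sprintf(
      "no genes shared between reference (%d genes) and bulk (%d genes)",
      length(reference_genes), length(bulk_genes)
    ))
  }
  common
}

#' Subset a reference to a gene universe
#'
#' Restricts the count matrix to `genes` (typically the bulk/reference
#' intersection from [intersect_genes()]), preserving the order of `genes`.
#'
#' @param reference a [clustered_reference()].
#' @param genes character vector; must all be present in the reference.
#' @return the restricted reference.
#' @export
subset_genes <- function(reference, genes) {
  idx <- match(genes, reference$gene_ids)
  if (anyNA(idx)) stop("some requested genes are absent from the reference")
  reference$counts <- reference$counts[idx, , drop = FALSE]
  reference$gene_ids <- genes
  reference
}
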