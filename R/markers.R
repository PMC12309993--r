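#' Select cell-type marker genes by one-vs-rest testing
#'
#' For every cluster large enough to trust, each gene is tested for higher
#' expression inside the cluster than outside (Welch's t-test on
#' log1p counts-per-10k per nucleus). P-values are BH-adjusted across genes
#' within each cluster; the top `k` positive-effect genes per cluster are
#' retained, ordered by adjusted p-value. A gene that would win in several
#' clusters is assigned to the cluster where its adjusted p-value is
#' smallest, so marker lists are disjoint. Ties on the adjusted p-value are
#' broken by larger log fold change, then by gene symbol.
#'
#' @param reference a deduplicated [clustered_reference()].
#' @param k markers retained per cluster (default 15).
#' @param min_cluster_size clusters with fewer nuclei are dropped before
#'   testing (default 500).
#' @param scale_factor,pseudocount normalization constants: expression is
#'   `log(1 + count / library_size * scale_factor)` per nucleus.
#' @return An object of class `MarkerPanel`: list with `markers` (named list,
#'   cluster -> ordered gene vector), `statistics` (data.frame with columns
#'   cluster, gene, rank, effect, pvalue, padj) and `k`.
#' @export
select_markers <- function(reference, k = 15, min_cluster_size = 500,
                           scale_factor = 1e4, pseudocount = 1) {
  stopifnot(inherits(reference, "ClusteredReference"))
  if (anyDuplicated(reference$gene_ids)) {
    stop("reference has duplicate gene symbols; run dedupe_genes() first")
  }
  cl <- reference$nucleus_meta$cluster
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= min_cluster_size]
  if (length(keep_cl) < 2) {
    stop(sprintf(
      "need >= 2 clusters with >= %d nuclei; got %d", min_cluster_size,
      length(keep_cl)
    ))
  }
  in_universe <- cl %in% keep_cl
  counts <- reference$counts[, in_universe, drop = FALSE]
  cl <- factor(as.character(cl[in_universe]), levels = keep_cl)
  genes <- reference$gene_ids

  expr <- normalize_log_cp10k(counts, scale_factor, pseudocount)
  expr_sq <- expr
  expr_sq@x <- expr_sq@x^2

  stats_list <- vector("list", length(keep_cl))
  for (ci in seq_along(keep_cl)) {
    inside <- cl == keep_cl[ci]
    n1 <- sum(inside); n0 <- sum(!inside)
    m1 <- Matrix::rowSums(expr[, inside, drop = FALSE]) / n1
    m0 <- Matrix::rowSums(expr[, !inside, drop = FALSE]) / n0
    v1 <- (Matrix::rowSums(expr_sq[, inside, drop = FALSE]) - n1 * m1^2) /
      (n1 - 1)
    v0 <- (Matrix::rowSums(expr_sq[, !inside, drop = FALSE]) - n0 * m0^2) /
      (n0 - 1)
    v1 <- pmax(v1, 0); v0 <- pmax(v0, 0)
    se2 <- v1 / n1 + v0 / n0
    effect <- m1 - m0
    tstat <- effect / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    # degenerate genes: no variance anywhere
    p[se2 == 0 & effect == 0] <- 1
    p[se2 == 0 & effect != 0] <- 0
    stats_list[[ci]] <- data.frame(
      cluster = keep_cl[ci], gene = genes, effect = effect,
      pvalue = p, padj = stats::p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE
    )
  }
  stats <- do.call(rbind, stats_list)
  rownames(stats) <- NULL

  pos <- stats[stats$effect > 0, , drop = FALSE]
  # assign each gene to its best cluster (smallest padj, then largest effect)
  ord <- order(pos$gene, pos$padj, -pos$effect)
  best <- pos[ord, ][!duplicated(pos$gene[ord]), , drop = FALSE]

  markers <- stats::setNames(vector("list", length(keep_cl)), keep_cl)
  panel_rows <- list()
  for (cname in keep_cl) {
    cand <- best[best$cluster == cname, , drop = FALSE]
    if (nrow(cand) == 0L) {
      warning(sprintf("cluster '%s' has no positive-effect genes; empty marker list", cname))
      markers[[cname]] <- character(0)
      next
    }
    cand <- cand[order(cand$padj, -cand$effect, cand$gene), , drop = FALSE]
    cand <- utils::head(cand, k)
    if (nrow(cand) < k) {
      warning(sprintf("cluster '%s': only %d of %d markers available", cname,
                      nrow(cand), k))
    }
    cand$rank <- seq_len(nrow(cand))
    markers[[cname]] <- cand$gene
    panel_rows[[cname]] <- cand
  }
  selected <- do.call(rbind, panel_rows)
  rownames(selected) <- NULL
  structure(
    list(markers = markers, statistics = selected, all_statistics = stats,
         k = k),
    class = "MarkerPanel"
  )
}

#' @export
print.MarkerPanel <- function(x, ...) {
  cat(sprintf("MarkerPanel: %d clusters, %d markers total (k = %d)\n",
              length(x$markers), length(unlist(x$markers)), x$k))
  invisible(x)
}

#' All marker genes of a panel
#' @param panel a `MarkerPanel`.
#' @return character vector of the union of per-cluster marker lists.
#' @export
panel_genes <- function(panel) {
  stopifnot(inherits(panel, "MarkerPanel"))
  unique(unlist(panel$markers, use.names = FALSE))
}

# library-size normalize to counts-per-`scale_factor`, then log(pseudo + x).
# Stays sparse when pseudocount = 1 (log1p(0) = 0).
normalize_log_cp10k <- function(counts, scale_factor = 1e4, pseudocount = 1) {
  libs <- Matrix::colSums(counts)
  if (any(libs == 0)) stop("nuclei with zero total counts are not allowed")
  norm <- counts
  per_col <- rep.int(libs, diff(norm@p))
  norm@x <- norm@x / per_col * scale_factor
  if (pseudocount == 1) {
    norm@x <- log1p(norm@x)
    norm
  } else {
    # general pseudocount breaks sparsity; fall back to dense
    log(as.matrix(norm) + pseudocount)
  }
}
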