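#' Read a clustered single-nucleus reference from disk
#'
#' Accepts either a sparse MatrixMarket triple (`counts.mtx` plus
#' `genes.tsv` and `barcodes.tsv`, one entry per line; a two-column
#' genes file uses the second column as the symbol) or a dense TSV with
#' gene symbols in the first column and barcodes as headers. Nucleus
#' metadata is a TSV with columns `barcode`, `cluster`, `subject`.
#'
#' @param counts_path path to `.mtx` or dense TSV counts.
#' @param meta_path path to the nucleus metadata TSV.
#' @param genes_path,barcodes_path sidecar files for the MatrixMarket
#'   layout; default to `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @return a [clustered_reference()].
#' @export
read_reference <- function(counts_path, meta_path, genes_path = NULL,
                           barcodes_path = NULL) {
  if (grepl("\\.mtx$", counts_path)) {
    dir <- dirname(counts_path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    counts <- methods::as(Matrix::readMM(counts_path), "CsparseMatrix")
    genes <- utils::read.delim(genes_path, header = FALSE,
                               stringsAsFactors = FALSE)
    rownames(counts) <- genes[[min(2, ncol(genes))]]
    colnames(counts) <- utils::read.delim(barcodes_path, header = FALSE,
                                          stringsAsFactors = FALSE)[[1]]
  } else {
    tab <- utils::read.delim(counts_path, row.names = 1, check.names = FALSE)
    counts <- Matrix::Matrix(as.matrix(tab), sparse = TRUE)
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("barcode", "cluster", "subject")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns barcode, cluster, subject")
  }
  idx <- match(colnames(counts), meta$barcode)
  if (anyNA(idx)) stop("metadata is missing some barcodes")
  clustered_reference(counts, meta$cluster[idx], meta$subject[idx])
}

#' Read a bulk count matrix
#'
#' @param path TSV with gene symbols in the first column, samples as the
#'   remaining columns.
#' @return numeric matrix, genes x samples.
#' @export
read_bulk_counts <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}

#' Write / read a marker panel as TSV
#'
#' Columns: cluster, gene, rank, effect, padj.
#'
#' @param panel a [select_markers()] panel.
#' @param path output TSV path.
#' @return `write_marker_panel` returns `path` invisibly;
#'   `read_marker_panel` returns a `MarkerPanel`.
#' @export
write_marker_panel <- function(panel, path) {
  stopifnot(inherits(panel, "MarkerPanel"))
  tab <- panel$statistics[, c("cluster", "gene", "rank", "effect", "padj")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_panel
#' @export
read_marker_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[order(tab$cluster, tab$rank), , drop = FALSE]
  markers <- split(tab$gene, tab$cluster)
  structure(
    list(markers = markers, statistics = tab, all_statistics = NULL,
         k = max(tab$rank)),
    class = "MarkerPanel"
  )
}

#' Write / read a signature as a TSV trio
#'
#' `theta.tsv` and `sigma2.tsv` are marker-gene x cell-type matrices;
#' `cell_sizes.tsv` holds the per-type size factors.
#'
#' @param signature a [build_signature()] object.
#' @param dir output directory (created if needed).
#' @return `write_signature` returns `dir` invisibly; `read_signature`
#'   returns a `Signature`.
#' @export
write_signature <- function(signature, dir) {
  stopifnot(inherits(signature, "Signature"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(signature$theta, file.path(dir, "theta.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(signature$sigma2, file.path(dir, "sigma2.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(
    data.frame(cell_type = names(signature$cell_sizes),
               size = signature$cell_sizes),
    file.path(dir, "cell_sizes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_signature
#' @export
read_signature <- function(dir) {
  theta <- as.matrix(utils::read.delim(file.path(dir, "theta.tsv"),
                                       check.names = FALSE))
  sigma2 <- as.matrix(utils::read.delim(file.path(dir, "sigma2.tsv"),
                                        check.names = FALSE))
  sizes <- utils::read.delim(file.path(dir, "cell_sizes.tsv"),
                             stringsAsFactors = FALSE)
  structure(
    list(theta = theta, sigma2 = sigma2,
         cell_sizes = stats::setNames(sizes$size, sizes$cell_type),
         gene_ids = rownames(theta), cell_types = colnames(theta)),
    class = "Signature"
  )
}

#' Write / read a proportion table as long-format CSV
#'
#' Columns: sample, cell_type, proportion.
#'
#' @param props a [proportion_table()].
#' @param path CSV path.
#' @return `write_proportions` returns `path` invisibly;
#'   `read_proportions` returns a `ProportionTable`.
#' @export
write_proportions <- function(props, path) {
  stopifnot(inherits(props, "ProportionTable"))
  long <- data.frame(
    sample = rep(props$sample_ids, times = length(props$cell_types)),
    cell_type = rep(props$cell_types, each = length(props$sample_ids)),
    proportion = as.vector(props$proportions)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  wide <- stats::xtabs(proportion ~ sample + cell_type, data = long)
  m <- matrix(wide, nrow(wide), ncol(wide),
              dimnames = list(rownames(wide), colnames(wide)))
  # restore original sample order
  m <- m[unique(long$sample), , drop = FALSE]
  proportion_table(m)
}

#' Write a simulated experiment with its ground truth
#'
#' Emits `bulk_counts.tsv`, `true_proportions.csv`, `spiked_genes.tsv`
#' (gene, condition, log2fc) and a YAML snapshot of every design parameter
#' including the seed.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(sim, dir) {
  stopifnot(inherits(sim, "SimTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$bulk_counts, file.path(dir, "bulk_counts.tsv"),
                     sep = "\t", quote = FALSE)
  write_proportions(proportion_table(sim$true_proportions),
                    file.path(dir, "true_proportions.csv"))
  fc <- sim$spiked_log2fc[sim$spiked_genes, , drop = FALSE]
  long <- data.frame(
    gene = rep(rownames(fc), times = ncol(fc)),
    condition = rep(colnames(fc), each = nrow(fc)),
    log2fc = as.vector(fc)
  )
  utils::write.table(long, file.path(dir, "spiked_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$design
  attributes(cfg) <- list(names = names(cfg))
  cfg <- lapply(cfg, function(x) if (is.null(x)) NULL else unclass(x))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write per-coefficient DE results
#'
#' @param results a [de_results()] / [wald_contrast()] table.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
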