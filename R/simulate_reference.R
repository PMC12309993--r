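#' Generate a synthetic clustered single-nucleus reference
#'
#' Emulates a clustered cardiac snRNA-seq dataset: each cell type gets a
#' gamma-distributed baseline expression vector modulated by log-normal
#' type-specific factors, plus a disjoint set of planted marker genes that
#' are strongly boosted in their own type and suppressed elsewhere
#' (cluster-exclusive). Nucleus counts are drawn Poisson around
#' subject-jittered means, with per-type sequencing depth reflecting cell
#' size (the first type plays the large-cell cardiomyocyte role by default).
#'
#' @param n_genes number of genes.
#' @param n_cell_types number of clusters (>= 2).
#' @param n_subjects number of reference subjects.
#' @param n_nuclei_per_type nuclei per cell type (split evenly across
#'   subjects).
#' @param marker_frac fraction of `n_genes` planted as exclusive markers for
#'   each type (so `marker_frac * n_genes` markers per type).
#' @param seed RNG seed; identical seeds give bit-identical references.
#' @param base_depth mean total counts per nucleus for a cell-size factor of 1.
#' @param cell_size_factors per-type depth multipliers; default gives the
#'   first (cardiomyocyte-like) type 2.5x the RNA content of the others.
#' @param type_sdlog sdlog of the log-normal type-specific expression factors;
#'   controls how distinct the cell-type transcriptomes are.
#' @param subject_sdlog sdlog of per-(gene, subject) jitter.
#' @param marker_boost,marker_offtype multiplier applied to a planted marker's
#'   mean in its own type / in all other types.
#' @param cell_type_names,gene_prefix labels.
#' @return a [clustered_reference()].
#' @export
make_fixture_reference <- function(n_genes = 2000, n_cell_types = 5,
                                   n_subjects = 3, n_nuclei_per_type = 120,
                                   marker_frac = 0.05, seed = 1,
                                   base_depth = 2500,
                                   cell_size_factors = NULL,
                                   type_sdlog = 1.5, subject_sdlog = 0.15,
                                   marker_boost = 8, marker_offtype = 0.05,
                                   cell_type_names = NULL,
                                   gene_prefix = "g") {
  if (n_cell_types < 2) stop("need at least 2 cell types")
  set.seed(seed)
  if (is.null(cell_type_names)) {
    cell_type_names <- if (n_cell_types == 5) {
      c("CM", "FB", "EC", "Peri", "Mac")
    } else {
      paste0("T", seq_len(n_cell_types))
    }
  }
  if (is.null(cell_size_factors)) {
    cell_size_factors <- c(2.5, rep(1, n_cell_types - 1))
  }
  genes <- sprintf("%s%04d", gene_prefix, seq_len(n_genes))

  lambda <- stats::rgamma(n_genes, shape = 0.4, rate = 1)
  lambda <- pmax(lambda, 1e-4)
  type_fac <- matrix(
    stats::rlnorm(n_genes * n_cell_types, meanlog = 0, sdlog = type_sdlog),
    n_genes, n_cell_types
  )
  means <- lambda * type_fac  # genes x types

  n_markers <- round(marker_frac * n_genes)
  marker_of <- rep(NA_character_, n_genes)
  if (n_markers * n_cell_types > n_genes) {
    stop("marker_frac too large: planted markers would exceed the gene universe")
  }
  pool <- sample.int(n_genes, n_markers * n_cell_types)
  for (ty in seq_len(n_cell_types)) {
    idx <- pool[((ty - 1) * n_markers + 1):(ty * n_markers)]
    means[idx, ] <- means[idx, ] * marker_offtype
    means[idx, ty] <- means[idx, ty] / marker_offtype * marker_boost
    marker_of[idx] <- cell_type_names[ty]
  }

  per_subj <- rep(n_nuclei_per_type %/% n_subjects, n_subjects)
  per_subj[seq_len(n_nuclei_per_type %% n_subjects)] <-
    per_subj[seq_len(n_nuclei_per_type %% n_subjects)] + 1

  blocks <- list(); cl <- character(0); sb <- character(0)
  for (ty in seq_len(n_cell_types)) {
    prof <- means[, ty] / sum(means[, ty])
    for (s in seq_len(n_subjects)) {
      n_nuc <- per_subj[s]
      if (n_nuc == 0) next
      jit <- stats::rlnorm(n_genes, meanlog = 0, sdlog = subject_sdlog)
      mu <- prof * jit
      mu <- mu / sum(mu) * base_depth * cell_size_factors[ty]
      cnt <- matrix(stats::rpois(n_genes * n_nuc, rep(mu, n_nuc)),
                    n_genes, n_nuc)
      blocks[[length(blocks) + 1]] <- cnt
      cl <- c(cl, rep(cell_type_names[ty], n_nuc))
      sb <- c(sb, rep(sprintf("S%d", s), n_nuc))
    }
  }
  counts <- do.call(cbind, blocks)
  dimnames(counts) <- list(genes, sprintf("N%05d", seq_len(ncol(counts))))
  ref <- clustered_reference(Matrix::Matrix(counts, sparse = TRUE), cl, sb)
  attr(ref, "planted_markers") <- stats::setNames(marker_of, genes)
  ref
}

#' Per-cell-type transcriptomic probability profile
#'
#' Sums the counts of all nuclei in the cluster and normalizes by the total,
#' giving the probability that a read sampled from this cell type comes from
#' each gene. These profiles are the building blocks of pseudo-bulk
#' mixtures.
#'
#' @param reference a [clustered_reference()].
#' @param cell_type cluster label.
#' @return named non-negative numeric vector over genes, summing to 1.
#' @export
cluster_profile <- function(reference, cell_type) {
  stopifnot(inherits(reference, "ClusteredReference"))
  sel <- reference$nucleus_meta$cluster == cell_type
  if (!any(sel)) stop(sprintf("cluster '%s' is empty or absent", cell_type))
  tot <- Matrix::rowSums(reference$counts[, sel, drop = FALSE])
  prof <- tot / sum(tot)
  names(prof) <- reference$gene_ids
  prof
}

# genes x types matrix of cluster profiles
cluster_profiles <- function(reference, cell_types = NULL) {
  if (is.null(cell_types)) {
    cell_types <- levels(reference$nucleus_meta$cluster)
  }
  vapply(cell_types, function(ty) cluster_profile(reference, ty),
         numeric(length(reference$gene_ids)))
}
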