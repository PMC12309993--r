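#' Mixture-simulation design
#'
#' Describes a sweep of pseudo-bulk conditions in which the major cell
#' type's proportion is varied around a baseline while two minor types
#' (fibroblasts and macrophages in the cardiac setting) absorb the change in
#' anti-correlation, with Gaussian jitter on the target proportions and
#' log-normally distributed fold changes spiked into a random gene subset.
#'
#' @param cm_min,cm_max,cm_step grid of major-type proportions; the default
#'   0.30-0.70 in steps of 0.005 yields 81 conditions. `cm_step` must divide
#'   the range evenly.
#' @param cm_grid explicit grid (overrides min/max/step), e.g. a pruned
#'   desk-scale subset `c(0.40, 0.45, 0.50, 0.55, 0.60)`.
#' @param baseline_cm the control condition (must lie on the grid).
#' @param n_replicates samples per condition.
#' @param total_reads multinomial reads per sample. Desk default 1e5; a
#'   full-scale run uses 25e6.
#' @param major_type label of the varied cell type.
#' @param anticorr_split named non-negative weights summing to 1: the share
#'   of the major-type change absorbed by each anti-correlated minor type.
#' @param noise_sd sd of additive Gaussian jitter on target proportions.
#' @param spike_fraction fraction of genes spiked as composition-independent
#'   true positives in non-baseline conditions.
#' @param spike_mu_log2,spike_sd_log2 log2-scale mean and sd of spiked fold
#'   changes (0.58 corresponds to a 1.5x linear fold change).
#' @param spike_mode `"lognormal"` draws log2 fold changes from
#'   Normal(spike_mu_log2, spike_sd_log2); `"double"` fixes every spiked
#'   fold change at 2x.
#' @param baseline_props optional named baseline composition; when `NULL` the
#'   major type gets `baseline_cm` and the rest is split among the remaining
#'   types in proportion to their total RNA in the reference.
#' @param seed RNG seed for the whole simulated experiment.
#' @return a `MixtureDesign` object (list).
#' @export
mixture_design <- function(cm_min = 0.30, cm_max = 0.70, cm_step = 0.005,
                           cm_grid = NULL, baseline_cm = 0.50,
                           n_replicates = 4, total_reads = 1e5,
                           major_type = "CM",
                           anticorr_split = c(FB = 0.6, Mac = 0.4),
                           noise_sd = 0.005, spike_fraction = 0.10,
                           spike_mu_log2 = 0.58, spike_sd_log2 = 0.5,
                           spike_mode = c("lognormal", "double"),
                           baseline_props = NULL, seed = 1) {
  spike_mode <- match.arg(spike_mode)
  if (is.null(cm_grid)) {
    n_steps <- (cm_max - cm_min) / cm_step
    if (abs(n_steps - round(n_steps)) > 1e-8) {
      stop("cm_step does not divide the range [cm_min, cm_max] evenly")
    }
    cm_grid <- cm_min + cm_step * seq.int(0, round(n_steps))
  }
  if (any(cm_grid <= 0 | cm_grid >= 1)) stop("cm_grid must lie in (0, 1)")
  if (any(anticorr_split < 0) || abs(sum(anticorr_split) - 1) > 1e-8) {
    stop("anticorr_split must be non-negative and sum to 1")
  }
  if (spike_fraction < 0 || spike_fraction >= 1) {
    stop("spike_fraction must be in [0, 1)")
  }
  if (!is.null(baseline_props)) {
    if (is.null(names(baseline_props)) ||
        abs(sum(baseline_props) - 1) > 1e-8) {
      stop("baseline_props must be named and sum to 1")
    }
  }
  structure(
    list(cm_grid = cm_grid, baseline_cm = baseline_cm,
         n_replicates = n_replicates, total_reads = total_reads,
         major_type = major_type, anticorr_split = anticorr_split,
         noise_sd = noise_sd, spike_fraction = spike_fraction,
         spike_mu_log2 = spike_mu_log2, spike_sd_log2 = spike_sd_log2,
         spike_mode = spike_mode, baseline_props = baseline_props,
         seed = seed),
    class = "MixtureDesign"
  )
}

#' Enumerate the sweep conditions of a mixture design
#'
#' @param design a [mixture_design()].
#' @return data.frame with columns `condition`, `cm_target`, `is_baseline`;
#'   exactly one baseline row.
#' @export
design_sweep <- function(design) {
  stopifnot(inherits(design, "MixtureDesign"))
  is_base <- abs(design$cm_grid - design$baseline_cm) < 1e-9
  if (sum(is_base) != 1) {
    stop("baseline_cm must appear exactly once on the grid")
  }
  data.frame(
    condition = sprintf("cm_%.3f", design$cm_grid),
    cm_target = design$cm_grid,
    is_baseline = is_base,
    stringsAsFactors = FALSE
  )
}

#' Target proportions for one simulated sample
#'
#' Shifts the major type to `cm_target`; the anti-correlated minor types
#' absorb the opposite change according to `design$anticorr_split`; the
#' remaining types fill the residual mass in proportion to their baseline.
#' Gaussian jitter (sd `design$noise_sd`, drawn from the current RNG stream)
#' is added, negatives are clipped to zero, and the vector is renormalized
#' to sum to one.
#'
#' @param cm_target major-type proportion for this condition.
#' @param design a [mixture_design()].
#' @param baseline_props named baseline composition summing to 1.
#' @return named proportion vector summing to 1.
#' @export
perturb_proportions <- function(cm_target, design, baseline_props) {
  stopifnot(inherits(design, "MixtureDesign"))
  if (abs(sum(baseline_props) - 1) > 1e-8) {
    stop("baseline_props must sum to 1")
  }
  major <- design$major_type
  split <- design$anticorr_split
  if (!major %in% names(baseline_props) ||
      !all(names(split) %in% names(baseline_props))) {
    stop("major_type and anticorr_split names must match baseline_props")
  }
  delta <- cm_target - baseline_props[[major]]
  p <- baseline_props
  p[[major]] <- p[[major]] + delta
  p[names(split)] <- p[names(split)] - delta * split
  others <- setdiff(names(p), c(major, names(split)))
  if (length(others) > 0) {
    resid <- 1 - sum(p[c(major, names(split))])
    p[others] <- baseline_props[others] / sum(baseline_props[others]) * resid
  }
  if (any(p < -1e-9)) {
    warning("target proportions below zero; clipping")
  }
  p <- pmax(p, 0)
  if (design$noise_sd > 0) {
    p <- pmax(p + stats::rnorm(length(p), 0, design$noise_sd), 0)
  }
  p / sum(p)
}

#' Spike fold changes into cell-type profiles
#'
#' Each spiked gene gets one log2 fold change (shared across all cell types
#' and all samples of a condition); its probability mass is multiplied by
#' `2^log2fc` in every per-type profile, and profiles are renormalized.
#'
#' @param profiles genes x cell types matrix of probability profiles.
#' @param spiked_genes character vector of genes to spike.
#' @param design a [mixture_design()] (supplies the spike distribution).
#' @param log2fc optional explicit log2 fold changes (named or in
#'   `spiked_genes` order); when `NULL`, drawn according to
#'   `design$spike_mode` from the current RNG stream.
#' @return list with `profiles` (renormalized) and `log2fc` (named vector).
#' @export
spike_fold_changes <- function(profiles, spiked_genes, design, log2fc = NULL) {
  stopifnot(inherits(design, "MixtureDesign"))
  if (length(spiked_genes) == 0) {
    return(list(profiles = profiles,
                log2fc = stats::setNames(numeric(0), character(0))))
  }
  if (!all(spiked_genes %in% rownames(profiles))) {
    stop("spiked genes must belong to the profile gene universe")
  }
  if (is.null(log2fc)) {
    log2fc <- switch(design$spike_mode,
      lognormal = stats::rnorm(length(spiked_genes), design$spike_mu_log2,
                               design$spike_sd_log2),
      double = rep(1, length(spiked_genes))
    )
  }
  log2fc <- stats::setNames(as.numeric(log2fc), spiked_genes)
  out <- profiles
  out[spiked_genes, ] <- out[spiked_genes, , drop = FALSE] * 2^log2fc
  out <- sweep(out, 2, colSums(out), "/")
  list(profiles = out, log2fc = log2fc)
}

#' Multinomial pseudo-bulk read sampling
#'
#' @param profile_mixture probability vector over genes (the
#'   proportion-weighted mixture of cell-type profiles).
#' @param total_reads reads to draw (> 0).
#' @return integer count vector summing exactly to `total_reads`.
#' @export
sample_bulk <- function(profile_mixture, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (abs(sum(profile_mixture) - 1) > 1e-6) {
    stop("profile_mixture must be a probability vector")
  }
  cnt <- stats::rmultinom(1, size = total_reads, prob = profile_mixture)[, 1]
  names(cnt) <- names(profile_mixture)
  cnt
}

#' Simulate a pseudo-bulk mixture experiment with known truth
#'
#' Runs the full generative model: cell-type profiles are taken from the
#' reference ([cluster_profile()]); for every sweep condition the target
#' composition is perturbed per replicate ([perturb_proportions()]);
#' non-baseline conditions receive spiked fold changes on a fixed random
#' gene subset ([spike_fold_changes()], one draw per gene per condition);
#' reads are drawn multinomially ([sample_bulk()]). Fully reproducible under
#' `design$seed`.
#'
#' @param reference a [clustered_reference()] whose clusters are the cell
#'   types to mix.
#' @param design a [mixture_design()].
#' @return a `SimTruth` object: list with `bulk_counts` (genes x samples),
#'   `true_proportions` (samples x cell types), `sample_info` (sample,
#'   condition, cm_target, is_baseline), `spiked_genes`, `spiked_log2fc`
#'   (genes x non-baseline conditions, NA for unspiked genes), `design`.
#' @export
simulate_experiment <- function(reference, design) {
  stopifnot(inherits(reference, "ClusteredReference"),
            inherits(design, "MixtureDesign"))
  set.seed(design$seed)
  types <- levels(reference$nucleus_meta$cluster)
  profiles <- cluster_profiles(reference, types)
  genes <- reference$gene_ids
  sweep_tab <- design_sweep(design)

  baseline_props <- design$baseline_props
  if (is.null(baseline_props)) {
    baseline_props <- baseline_proportions(reference, design)
  }
  if (!setequal(names(baseline_props), types)) {
    stop("baseline_props names must match the reference cell types")
  }
  baseline_props <- baseline_props[types]

  n_spike <- round(design$spike_fraction * length(genes))
  spiked_genes <- sort(sample(genes, n_spike))

  n_cond <- nrow(sweep_tab)
  n_samples <- n_cond * design$n_replicates
  bulk <- matrix(0L, length(genes), n_samples, dimnames = list(genes, NULL))
  props <- matrix(0, n_samples, length(types),
                  dimnames = list(NULL, types))
  info <- vector("list", n_cond)
  fc_cols <- sweep_tab$condition[!sweep_tab$is_baseline]
  spiked_log2fc <- matrix(NA_real_, length(genes), length(fc_cols),
                          dimnames = list(genes, fc_cols))

  s <- 0L
  sample_ids <- character(n_samples)
  for (ci in seq_len(n_cond)) {
    cond <- sweep_tab$condition[ci]
    if (sweep_tab$is_baseline[ci] || n_spike == 0) {
      prof_c <- profiles
    } else {
      sp <- spike_fold_changes(profiles, spiked_genes, design)
      prof_c <- sp$profiles
      spiked_log2fc[spiked_genes, cond] <- sp$log2fc
    }
    for (r in seq_len(design$n_replicates)) {
      s <- s + 1L
      p <- perturb_proportions(sweep_tab$cm_target[ci], design, baseline_props)
      mix <- as.vector(prof_c %*% p[types])
      bulk[, s] <- sample_bulk(mix, design$total_reads)
      props[s, ] <- p[types]
      sample_ids[s] <- sprintf("%s_r%d", cond, r)
    }
    info[[ci]] <- data.frame(
      sample = sample_ids[(s - design$n_replicates + 1L):s],
      condition = cond, cm_target = sweep_tab$cm_target[ci],
      is_baseline = sweep_tab$is_baseline[ci], stringsAsFactors = FALSE
    )
  }
  colnames(bulk) <- sample_ids
  rownames(props) <- sample_ids
  structure(
    list(bulk_counts = bulk, true_proportions = props,
         sample_info = do.call(rbind, info), spiked_genes = spiked_genes,
         spiked_log2fc = spiked_log2fc, baseline_props = baseline_props,
         design = design),
    class = "SimTruth"
  )
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf(
    "SimTruth: %d genes x %d samples (%d conditions x %d replicates), %d spiked genes\n",
    nrow(x$bulk_counts), ncol(x$bulk_counts),
    length(unique(x$sample_info$condition)), x$design$n_replicates,
    length(x$spiked_genes)
  ))
  invisible(x)
}

#' Baseline composition implied by a reference
#'
#' The major type is fixed at `design$baseline_cm`; the remaining mass is
#' split among the other cell types in proportion to their total RNA
#' (summed counts) in the reference.
#'
#' @param reference a [clustered_reference()].
#' @param design a [mixture_design()].
#' @return named proportion vector over the reference cell types.
#' @export
baseline_proportions <- function(reference, design) {
  types <- levels(reference$nucleus_meta$cluster)
  if (!design$major_type %in% types) {
    stop(sprintf("major_type '%s' is not a reference cluster", design$major_type))
  }
  tot <- vapply(types, function(ty) {
    sum(reference$counts[, reference$nucleus_meta$cluster == ty, drop = FALSE])
  }, numeric(1))
  minor <- setdiff(types, design$major_type)
  p <- stats::setNames(numeric(length(types)), types)
  p[design$major_type] <- design$baseline_cm
  p[minor] <- tot[minor] / sum(tot[minor]) * (1 - design$baseline_cm)
  p
}
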