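#' Score differential-expression calls against simulation truth
#'
#' Positives are genes with BH-adjusted p below `alpha`; ground-truth
#' positives are the spiked genes. Counts are over the tested genes (rows
#' of `de`); genes with NA adjusted p-values count as not called.
#'
#' @param de a result table from [de_results()] / [wald_contrast()] (needs
#'   columns `gene`, `padj`).
#' @param truth a `SimTruth` or a character vector of true-positive genes.
#' @param alpha FDR threshold (default 0.05).
#' @return one-row data.frame: TP, FP, FN, TN, precision, recall, F1,
#'   frac_called, n_tested.
#' @export
score_calls <- function(de, truth, alpha = 0.05) {
  if (nrow(de) == 0) stop("no tested genes to score")
  positives <- if (inherits(truth, "SimTruth")) truth$spiked_genes else truth
  called <- !is.na(de$padj) & de$padj < alpha
  is_pos <- de$gene %in% positives
  tp <- sum(called & is_pos)
  fp <- sum(called & !is_pos)
  fn <- sum(!called & is_pos)
  tn <- sum(!called & !is_pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  data.frame(TP = tp, FP = fp, FN = fn, TN = tn, precision = precision,
             recall = recall, F1 = f1,
             frac_called = mean(called), n_tested = nrow(de))
}

#' Run the composition-shift simulation benchmark
#'
#' For every seed: simulates the mixture sweep, obtains cell-type
#' proportions (deconvolved from the simulated bulk by default, or the
#' generative truth with `use_true_props = TRUE`), and fits one NB GLM per
#' covariate representation jointly over all samples with cell-means
#' coding (`~ 0 + group`, plus the compositional covariate when present).
#' The joint fit matters: the abundance coefficient is identified by
#' within-group composition variation pooled across the whole sweep, which
#' is what lets the group contrasts recover the composition-independent
#' (spiked) signal. Each non-baseline condition is then contrasted against
#' the baseline group and the calls are scored against the spiked-gene
#' truth in batches of `batch_size` genes.
#'
#' Representations: `"none"` (no compositional covariate), `"raw"` (selected
#' proportions), `"clr"` (selected centered log-ratio components), `"pca"`
#' (leading principal component of proportions). For `raw` and `clr` the
#' components used are `covariate_cells` (default: the major type and the
#' first anti-correlated type, i.e. cardiomyocyte + fibroblast).
#'
#' @param reference a [clustered_reference()].
#' @param design a [mixture_design()]; its grid should be the (possibly
#'   pruned) sweep to run.
#' @param representations subset of c("none", "raw", "clr", "pca").
#' @param seeds one simulation per seed (default: the design's seed).
#' @param alpha FDR threshold for calling.
#' @param batch_size genes per scoring batch.
#' @param use_true_props bypass deconvolution and use the generative truth.
#' @param signature optional precomputed [build_signature()]; when NULL one
#'   is built from the reference (top 15 markers per cluster, all clusters
#'   kept regardless of size — fixture clusters are intended cell types).
#' @param covariate_cells cell types whose raw/CLR components enter the
#'   model.
#' @return a `BenchmarkResult`: data.frame with one row per (seed,
#'   condition, representation, batch) carrying the confusion counts,
#'   precision/recall/F1 and fraction of genes called; attributes `design`
#'   and `alpha`.
#' @export
run_benchmark <- function(reference, design,
                          representations = c("none", "raw", "clr", "pca"),
                          seeds = design$seed, alpha = 0.05,
                          batch_size = 1000, use_true_props = FALSE,
                          signature = NULL,
                          covariate_cells = NULL) {
  representations <- match.arg(representations, several.ok = TRUE)
  if (is.null(covariate_cells)) {
    covariate_cells <- c(design$major_type, names(design$anticorr_split)[1])
  }
  if (is.null(signature) && !use_true_props) {
    panel <- select_markers(reference, k = 15, min_cluster_size = 2)
    signature <- build_signature(reference, panel)
  }
  rows <- list()
  for (sd in seeds) {
    design_s <- design
    design_s$seed <- sd
    sim <- simulate_experiment(reference, design_s)
    info <- sim$sample_info
    props <- if (use_true_props) {
      proportion_table(sim$true_proportions)
    } else {
      deconvolve_cohort(sim$bulk_counts, signature)
    }
    covsets <- build_covariate_sets(props, representations, covariate_cells)
    cnt <- filter_genes(sim$bulk_counts)
    base_cond <- unique(info$condition[info$is_baseline])
    grp <- factor(info$condition,
                  levels = c(base_cond,
                             setdiff(unique(info$condition), base_cond)))
    dsg <- data.frame(group = grp)
    for (rep_name in representations) {
      cv <- covsets[[rep_name]]
      fit <- fit_de(cnt, dsg, ~ 0 + group, covariates = cv)
      for (cond in setdiff(levels(grp), base_cond)) {
        contrast <- numeric(ncol(fit$beta))
        contrast[match(paste0("group", c(cond, base_cond)),
                       colnames(fit$beta))] <- c(1, -1)
        res <- wald_contrast(fit, contrast)
        batches <- split(seq_len(nrow(res)),
                         ceiling(seq_len(nrow(res)) / batch_size))
        for (b in seq_along(batches)) {
          sc <- score_calls(res[batches[[b]], , drop = FALSE], sim, alpha)
          cm_target <- info$cm_target[info$condition == cond][1]
          rows[[length(rows) + 1]] <- cbind(
            data.frame(seed = sd, condition = cond, cm_target = cm_target,
                       delta_cm = cm_target - design$baseline_cm,
                       representation = rep_name, batch = b,
                       stringsAsFactors = FALSE),
            sc
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "design") <- design
  attr(out, "alpha") <- alpha
  class(out) <- c("BenchmarkResult", class(out))
  out
}

# covariate matrices per representation, rows = all samples
build_covariate_sets <- function(props, representations, covariate_cells) {
  out <- list()
  for (rep_name in representations) {
    out[[rep_name]] <- switch(rep_name,
      none = NULL,
      raw = {
        v <- raw_covariates(props, covariate_cells)$values
        colnames(v) <- paste0("raw_", colnames(v))
        v
      },
      clr = {
        v <- clr_transform(props)$values[, covariate_cells, drop = FALSE]
        colnames(v) <- paste0("clr_", colnames(v))
        v
      },
      pca = {
        v <- pca_props(props, 1)$values
        colnames(v) <- "PC1"
        v
      }
    )
  }
  out
}

#' Summarize a benchmark run
#'
#' Aggregates F1 and fraction-called over batches and seeds, overall and
#' split by magnitude of the compositional shift (major: |shift| >= 10
#' percentage points; minor: smaller non-zero shifts).
#'
#' @param bench a [run_benchmark()] result.
#' @return list with `by_condition` (per condition x representation mean/sd
#'   F1, mean fraction called) and `by_shift_class` (same, pooled over
#'   major/minor shifts).
#' @export
summarize_benchmark <- function(bench) {
  stopifnot(inherits(bench, "BenchmarkResult"))
  agg <- function(df, keys) {
    sp <- split(df, df[keys], drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(d) {
      cbind(d[1, keys, drop = FALSE],
            data.frame(mean_F1 = mean(d$F1), sd_F1 = stats::sd(d$F1),
                       mean_frac_called = mean(d$frac_called),
                       n = nrow(d)))
    }))
    rownames(out) <- NULL
    out[do.call(order, out[keys]), , drop = FALSE]
  }
  bench <- as.data.frame(bench)
  bench$shift_class <- ifelse(abs(bench$delta_cm) >= 0.10, "major", "minor")
  list(
    by_condition = agg(bench, c("condition", "representation")),
    by_shift_class = agg(bench, c("shift_class", "representation"))
  )
}
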