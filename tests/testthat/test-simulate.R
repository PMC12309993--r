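test_that("fixture generation is deterministic and validates inputs", {
  a <- small_fixture(seed = 3)
  b <- small_fixture(seed = 3)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$nucleus_meta, b$nucleus_meta)
  expect_error(make_fixture_reference(n_cell_types = 1), "at least 2")
})

test_that("single-subject fixture gives all-zero cross-subject variance", {
  ref <- make_fixture_reference(n_genes = 200, n_cell_types = 2,
                                n_subjects = 1, n_nuclei_per_type = 30,
                                seed = 4)
  panel <- select_markers(ref, k = 5, min_cluster_size = 2)
  sig <- suppressWarnings(build_signature(ref, panel))
  expect_equal(max(sig$sigma2), 0)
})

test_that("cluster_profile normalizes summed counts and matches brute force", {
  counts <- matrix(c(1, 1, 2, 0, 5, 5), 3, 2)
  rownames(counts) <- c("g1", "g2", "g3")
  colnames(counts) <- c("N1", "N2")
  ref <- clustered_reference(counts, c("A", "B"), c("S1", "S1"))
  expect_equal(unname(cluster_profile(ref, "A")), c(0.25, 0.25, 0.5))
  expect_error(cluster_profile(ref, "missing"), "empty or absent")

  # degenerate: single expressed gene
  counts2 <- matrix(c(7, 0, 0), 3, 1, dimnames = list(c("a", "b", "c"), "N1"))
  ref2 <- suppressWarnings(clustered_reference(cbind(counts2, N2 = c(1, 1, 1)),
                                               c("A", "B"), c("S1", "S1")))
  expect_equal(unname(cluster_profile(ref2, "A")), c(1, 0, 0))

  # brute force on a random fixture
  ref3 <- small_fixture(seed = 6)
  sel <- ref3$nucleus_meta$cluster == "FB"
  manual <- rowSums(as.matrix(ref3$counts[, sel]))
  manual <- manual / sum(manual)
  expect_equal(unname(cluster_profile(ref3, "FB")), unname(manual))
})

test_that("design_sweep enumerates the grid with one baseline", {
  sweep81 <- design_sweep(mixture_design())
  expect_equal(nrow(sweep81), 81)
  expect_equal(sum(sweep81$is_baseline), 1)
  expect_equal(sweep81$cm_target[sweep81$is_baseline], 0.5)

  sweep3 <- design_sweep(mixture_design(cm_min = 0.4, cm_max = 0.6,
                                        cm_step = 0.1))
  expect_equal(sweep3$cm_target, c(0.4, 0.5, 0.6))

  expect_error(mixture_design(cm_min = 0.3, cm_max = 0.7, cm_step = 0.15),
               "does not divide")
  expect_error(design_sweep(mixture_design(cm_grid = c(0.4, 0.6))),
               "baseline")
})

test_that("perturb_proportions applies the anti-correlated shift rule", {
  base <- c(CM = 0.50, FB = 0.20, EC = 0.15, Peri = 0.09, Mac = 0.06)
  des0 <- mixture_design(noise_sd = 0)

  expect_equal(perturb_proportions(0.50, des0, base), base)

  shifted <- perturb_proportions(0.40, des0, base)
  expect_equal(unname(shifted["CM"]), 0.40)
  expect_equal(unname(shifted["FB"]), 0.26)   # +0.10 * 0.6
  expect_equal(unname(shifted["Mac"]), 0.10)  # +0.10 * 0.4
  expect_equal(unname(shifted[c("EC", "Peri")]), c(0.15, 0.09))

  des <- mixture_design(noise_sd = 0.02)
  set.seed(1)
  for (tgt in c(0.3, 0.45, 0.7)) {
    # extreme gains can push an anti-correlated type below zero: clipped
    p <- suppressWarnings(perturb_proportions(tgt, des, base))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("spike_fold_changes renormalizes profiles and draws the stated distribution", {
  des <- mixture_design()
  profiles <- cbind(A = c(0.5, 0.5), B = c(0.9, 0.1))
  rownames(profiles) <- c("g1", "g2")

  none <- spike_fold_changes(profiles, character(0), des)
  expect_identical(none$profiles, profiles)

  sp <- spike_fold_changes(profiles, "g1", des, log2fc = 1)
  expect_equal(unname(sp$profiles[, "A"]), c(2 / 3, 1 / 3))
  expect_equal(colSums(sp$profiles), c(A = 1, B = 1))

  set.seed(8)
  z <- replicate(10000, spike_fold_changes(profiles, "g1", des)$log2fc)
  expect_lt(abs(mean(z) - 0.58), 3 * 0.5 / sqrt(10000))
  expect_equal(sd(z), 0.5, tolerance = 0.05)
})

test_that("sample_bulk draws exact-total multinomial counts", {
  prof <- c(g1 = 1, g2 = 0, g3 = 0)
  expect_equal(unname(sample_bulk(prof, 100)), c(100, 0, 0))
  expect_error(sample_bulk(prof, 0), "positive")

  set.seed(9)
  pi <- c(a = 0.6, b = 0.3, c = 0.1)
  draws <- replicate(1000, sample_bulk(pi, 500))
  expect_true(all(colSums(draws) == 500))
  se <- sqrt(500 * pi * (1 - pi)) / sqrt(1000)
  expect_true(all(abs(rowMeans(draws) - 500 * pi) < 3 * se))
})

test_that("simulate_experiment bookkeeping, determinism and noiseless identity", {
  ref <- small_fixture(seed = 12)
  des <- mixture_design(cm_grid = c(0.45, 0.50, 0.55), n_replicates = 3,
                        total_reads = 5e4, seed = 21)
  sim <- simulate_experiment(ref, des)
  expect_equal(ncol(sim$bulk_counts), 9)
  expect_true(all(colSums(sim$bulk_counts) == 5e4))
  expect_equal(unname(rowSums(sim$true_proportions)), rep(1, 9),
               tolerance = 1e-12)
  expect_equal(length(sim$spiked_genes), round(0.1 * 500))
  # spiked log2fc defined exactly on spiked genes, only off-baseline
  fc <- sim$spiked_log2fc
  expect_false("cm_0.500" %in% colnames(fc))
  expect_true(all(is.finite(fc[sim$spiked_genes, ])))
  expect_true(all(is.na(fc[setdiff(rownames(fc), sim$spiked_genes), ])))

  sim2 <- simulate_experiment(ref, des)
  expect_identical(sim$bulk_counts, sim2$bulk_counts)
  expect_identical(sim$true_proportions, sim2$true_proportions)

  des0 <- mixture_design(cm_grid = c(0.45, 0.50), n_replicates = 3,
                         noise_sd = 0, spike_fraction = 0, seed = 22)
  sim0 <- simulate_experiment(ref, des0)
  pr <- sim0$true_proportions
  for (cond in unique(sim0$sample_info$condition)) {
    rows <- pr[sim0$sample_info$condition == cond, , drop = FALSE]
    expect_equal(max(apply(rows, 2, sd)), 0)
  }
})

test_that("spiked genes shift the mixture by the drawn fold change", {
  ref <- small_fixture(seed = 13)
  types <- levels(ref$nucleus_meta$cluster)
  profiles <- sapply(types, function(ty) cluster_profile(ref, ty))
  des <- mixture_design()
  base <- baseline_proportions(ref, des)
  set.seed(3)
  spiked <- sample(ref$gene_ids, 5)
  sp <- spike_fold_changes(profiles, spiked, des)
  mix0 <- drop(profiles %*% base[types])
  mix1 <- drop(sp$profiles %*% base[types])
  # ratio approx 2^z up to the per-profile renormalization (small spike mass)
  ratio <- mix1[spiked] / mix0[spiked]
  expect_equal(unname(log2(ratio)), unname(sp$log2fc), tolerance = 0.05)
})
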