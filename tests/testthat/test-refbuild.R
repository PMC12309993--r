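test_that("dedupe_genes keeps the highest-mean row per duplicated symbol", {
  counts <- rbind(10, 5, 7)[, rep(1, 4)] * 1  # 3 rows, 4 nuclei
  counts <- matrix(c(10, 5, 7), 3, 4)
  rownames(counts) <- c("GeneA", "GeneA", "GeneB")
  colnames(counts) <- paste0("N", 1:4)
  ref <- clustered_reference(counts, rep(c("X", "Y"), 2), rep("S1", 4))
  dd <- dedupe_genes(ref)
  expect_equal(dd$gene_ids, c("GeneA", "GeneB"))
  expect_equal(as.numeric(dd$counts["GeneA", ]), rep(10, 4))

  # all-unique symbols: identity
  rownames(counts) <- c("g1", "g2", "g3")
  ref2 <- clustered_reference(counts, rep(c("X", "Y"), 2), rep("S1", 4))
  expect_identical(dedupe_genes(ref2)$counts, ref2$counts)

  # three-way duplicate, means 1/2/3: highest retained, row count drops by 2
  counts3 <- matrix(c(1, 2, 3, 9), 4, 2)
  rownames(counts3) <- c("dup", "dup", "dup", "other")
  colnames(counts3) <- c("N1", "N2")
  ref3 <- clustered_reference(counts3, c("X", "Y"), c("S1", "S1"))
  dd3 <- dedupe_genes(ref3)
  expect_equal(nrow(dd3$counts), 2)
  expect_equal(as.numeric(dd3$counts["dup", ]), c(3, 3))
})

test_that("intersect_genes returns the sorted intersection and errors when empty", {
  expect_equal(intersect_genes(c("A", "B", "C"), c("C", "B", "D")), c("B", "C"))
  expect_equal(intersect_genes(c("b", "a"), c("b", "a")), c("a", "b"))
  expect_error(intersect_genes(c("A", "B"), c("C", "D")), "no genes shared.*2 genes")
  expect_error(intersect_genes(c("A", "A"), c("A")), "deduplicated")
})

test_that("a perfectly separating gene ranks first in its cluster", {
  set.seed(5)
  n <- 40
  counts <- matrix(rpois(20 * 2 * n, 5), 20, 2 * n)
  rownames(counts) <- sprintf("g%02d", 1:20)
  colnames(counts) <- paste0("N", seq_len(2 * n))
  counts["g07", ] <- c(rep(10, n), rep(0, n))  # exclusive to cluster X
  ref <- clustered_reference(counts, rep(c("X", "Y"), each = n),
                             rep(c("S1", "S2"), times = n))
  panel <- select_markers(ref, k = 3, min_cluster_size = 2)
  expect_equal(panel$markers$X[1], "g07")
})

test_that("well-separated clusters yield k markers each with perfect precision", {
  # low-background fixture: only planted genes are cluster-exclusive
  ref <- make_fixture_reference(n_genes = 1000, n_cell_types = 5,
                                n_subjects = 2, n_nuclei_per_type = 60,
                                marker_frac = 0.05, type_sdlog = 0.3,
                                seed = 9)
  panel <- select_markers(ref, k = 15, min_cluster_size = 2)
  planted <- attr(ref, "planted_markers")
  expect_length(unlist(panel$markers), 75)
  for (cl in names(panel$markers)) {
    expect_length(panel$markers[[cl]], 15)
    expect_true(all(planted[panel$markers[[cl]]] == cl))
    # ordered by adjusted p-value
    st <- panel$statistics[panel$statistics$cluster == cl, ]
    expect_true(!is.unsorted(st$padj))
  }
  # marker lists are disjoint
  expect_equal(anyDuplicated(unlist(panel$markers)), 0L)
})

test_that("exchangeable clusters give approximately uniform p-values", {
  set.seed(11)
  n <- 120
  lambda <- runif(300, 5, 50)
  counts <- matrix(rpois(300 * 2 * n, lambda), 300, 2 * n)
  rownames(counts) <- sprintf("g%03d", 1:300)
  colnames(counts) <- paste0("N", seq_len(2 * n))
  ref <- clustered_reference(counts, rep(c("X", "Y"), each = n),
                             rep("S1", 2 * n))
  panel <- select_markers(ref, k = 5, min_cluster_size = 2)
  pv <- panel$all_statistics$pvalue[panel$all_statistics$cluster == "X"]
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
  expect_gt(min(panel$statistics$padj), 0.2)  # nothing materially significant
})

test_that("marker selection is invariant to nucleus order and per-nucleus scaling", {
  ref <- small_fixture(seed = 31)
  panel <- select_markers(ref, k = 10, min_cluster_size = 2)

  perm <- sample(ncol(ref$counts))
  ref_perm <- clustered_reference(ref$counts[, perm],
                                  ref$nucleus_meta$cluster[perm],
                                  ref$nucleus_meta$subject[perm])
  panel_perm <- select_markers(ref_perm, k = 10, min_cluster_size = 2)
  expect_identical(panel$markers, panel_perm$markers)

  # scaling all counts of a nucleus cancels in counts-per-10k normalization
  scales <- rep(c(1, 2, 5), length.out = ncol(ref$counts))
  scaled <- ref$counts %*% Matrix::Diagonal(ncol(ref$counts), scales)
  dimnames(scaled) <- dimnames(ref$counts)
  ref_scaled <- clustered_reference(scaled, ref$nucleus_meta$cluster,
                                    ref$nucleus_meta$subject)
  panel_scaled <- select_markers(ref_scaled, k = 10, min_cluster_size = 2)
  expect_identical(panel$markers, panel_scaled$markers)
})

test_that("small clusters are dropped and too-few clusters error", {
  ref <- small_fixture(seed = 32)
  expect_error(select_markers(ref, min_cluster_size = 1e6), ">= 2 clusters")
})

test_that("signature theta and sigma2 match hand arithmetic", {
  # single subject, one cell type of interest: theta = counts / total
  counts <- matrix(c(2, 3, 5, 1, 1, 1), 3, 2)
  rownames(counts) <- c("g1", "g2", "g3")
  colnames(counts) <- c("N1", "N2")
  ref <- clustered_reference(counts, c("A", "B"), c("S1", "S1"))
  panel <- manual_panel(list(A = c("g1", "g2", "g3"), B = character(0)))
  ws <- capture_warnings(sig <- build_signature(ref, panel))
  expect_true(any(grepl("< 2 subjects", ws)))
  expect_equal(unname(sig$theta[, "A"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(sig$sigma2[, "A"]), c(0, 0, 0))
  expect_equal(unname(sig$cell_sizes["A"]), 10)

  # two subjects with identical profiles: sigma2 exactly 0
  counts2 <- cbind(counts[, 1], counts[, 1], counts[, 2], counts[, 2])
  rownames(counts2) <- rownames(counts)
  colnames(counts2) <- paste0("N", 1:4)
  ref2 <- clustered_reference(counts2, c("A", "A", "B", "B"),
                              c("S1", "S2", "S1", "S2"))
  sig2 <- build_signature(ref2, panel)
  expect_equal(max(sig2$sigma2), 0)

  # two subjects, per-subject theta 0.2 vs 0.4: mean 0.3, sample var 0.02
  c3 <- cbind(S1 = c(2, 8), S2 = c(4, 6))
  rownames(c3) <- c("g1", "g2")
  c3 <- cbind(c3, B1 = c(1, 1))
  ref3 <- clustered_reference(c3, c("A", "A", "B"), c("S1", "S2", "S1"))
  panel3 <- manual_panel(list(A = c("g1", "g2"), B = character(0)))
  sig3 <- suppressWarnings(build_signature(ref3, panel3))
  expect_equal(unname(sig3$theta["g1", "A"]), 0.3)
  expect_equal(unname(sig3$sigma2["g1", "A"]), 0.02)
})

test_that("full-universe theta columns sum to one per subject", {
  ref <- tiny_reference()
  panel <- manual_panel(list(X = ref$gene_ids, Y = ref$gene_ids[1]))
  sig <- build_signature(ref, panel)
  # X's markers span the whole universe, so its theta column must close to 1
  expect_equal(sum(sig$theta[, "X"]), 1, tolerance = 1e-12)
})

test_that("a cell type absent from one subject omits that subject", {
  counts <- matrix(c(5, 5, 3, 7, 2, 8), 2, 3)
  rownames(counts) <- c("g1", "g2")
  colnames(counts) <- paste0("N", 1:3)
  # type A in subjects S1+S2, type B only in S1
  ref <- clustered_reference(counts, c("A", "A", "B"), c("S1", "S2", "S1"))
  panel <- manual_panel(list(A = c("g1", "g2"), B = c("g1")))
  expect_warning(sig <- build_signature(ref, panel), "'B'.*< 2 subjects")
  expect_equal(unname(sig$sigma2[, "B"]), c(0, 0))
  expect_equal(unname(sig$theta["g1", "B"]), 0.2)
})
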