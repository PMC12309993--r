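# Fixtures are built in code at test time; nothing is read from disk.

# Tiny hand-specified reference for arithmetic checks. Two clusters, two
# subjects, three genes; counts chosen so per-subject theta is easy to
# verify by hand.
tiny_reference <- function() {
  counts <- rbind(
    gA = c(2, 2, 1, 1, 10, 10, 4, 4),
    gB = c(3, 3, 2, 2, 0, 0, 1, 1),
    gC = c(5, 5, 7, 7, 0, 0, 5, 5)
  )
  colnames(counts) <- paste0("N", 1:8)
  clustered_reference(
    counts,
    cluster_label = rep(c("X", "Y"), each = 4),
    subject_id = rep(rep(c("S1", "S2"), each = 2), times = 2)
  )
}

# A MarkerPanel built directly (bypassing selection) so signature
# arithmetic can be tested on hand-chosen genes.
manual_panel <- function(markers) {
  structure(
    list(markers = markers, statistics = NULL, all_statistics = NULL,
         k = max(lengths(markers))),
    class = "MarkerPanel"
  )
}

# Small, fast synthetic reference shared across tests.
small_fixture <- function(seed = 101, ...) {
  make_fixture_reference(
    n_genes = 500, n_cell_types = 5, n_subjects = 2,
    n_nuclei_per_type = 60, marker_frac = 0.04, seed = seed, ...
  )
}

# Exhaustive step-up BH oracle: adjusted p_i = min over j >= rank(i) of
# m * p_(j) / j, capped at 1. Independent of stats::p.adjust.
bh_oracle <- function(p) {
  keep <- !is.na(p)
  pv <- p[keep]
  m <- length(pv)
  ord <- order(pv)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cands <- vapply(rank_i:m, function(j) m * pv[ord[j]] / j, numeric(1))
    adj[i] <- min(1, min(cands))
  }
  out <- rep(NA_real_, length(p))
  out[keep] <- adj
  out
}
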