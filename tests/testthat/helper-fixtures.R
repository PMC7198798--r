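## Shared in-code fixtures for the test suite.

## Minimal valid panel: n_subjects per group, all 16 cytokines, 8 draws,
## concentrations strictly positive unless zeros injected by the caller.
toy_panel <- function(n_hc = 2, n_gwi = 2, base = 10) {
  subj <- c(sprintf("HC%02d", seq_len(n_hc)), sprintf("GW%02d", seq_len(n_gwi)))
  grp <- c(rep("HC", n_hc), rep("GWI", n_gwi))
  rows <- list()
  for (s in seq_along(subj)) {
    for (ci in seq_along(PANEL_CYTOKINES)) {
      conc <- base + ci + seq_len(8) / 4 + s / 10
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subj[s], group = grp[s],
        cytokine = PANEL_CYTOKINES[ci],
        timepoint_label = TIMEPOINT_LABELS,
        minutes_from_T1 = unname(NOMINAL_MINUTES),
        concentration = conc, stringsAsFactors = FALSE)
    }
  }
  cytokine_panel(do.call(rbind, rows), units = "pg_ml")
}

## Small signed adjacency with named nodes (target rows, source columns).
toy_adjacency <- function(edges, nodes = AGGREGATE_NODES) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) A[e[[2]], e[[1]]] <- e[[3]]
  A
}

## Random signed sparse matrix for metric/motif property tests.
random_signed_matrix <- function(n = 9, density = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  off <- which(row(A) != col(A))
  pick <- off[runif(length(off)) < density]
  A[pick] <- sample(c(-1, 1), length(pick), replace = TRUE) *
    runif(length(pick), 0.2, 1)
  dimnames(A) <- list(AGGREGATE_NODES[seq_len(n)], AGGREGATE_NODES[seq_len(n)])
  A
}

expect_near <- function(object, expected, tol = 1e-9) {
  expect_true(max(abs(object - expected)) < tol)
}
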