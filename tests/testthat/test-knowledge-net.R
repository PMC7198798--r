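test_that("cell intermediates collapse with sign products, length 2 only", {
  e <- signed_edges(
    source = c("MK2", "DC1", "MK6", "DC1", "DC2", "CK1"),
    target = c("DC1", "MK15", "MK2", "DC2", "CK17", "MK6"),
    sign   = c(-1, 1, 1, 1, 1, -1))
  out <- collapse_intermediates(e, cell_nodes = c("DC1", "DC2"))
  key <- paste(out$source, out$target, out$sign)
  ## inhibition of the cell propagates: MK2 -| DC1 -> MK15 gives MK2 -| MK15
  expect_true("MK2 MK15 -1" %in% key)
  ## direct cytokine edges survive untouched
  expect_true("MK6 MK2 1" %in% key)
  expect_true("CK1 MK6 -1" %in% key)
  ## cell -> cell -> cytokine paths are NOT traversed
  expect_false(any(out$source == "MK2" & out$target == "CK17"))
  ## no cell nodes remain
  expect_false(any(c(out$source, out$target) %in% c("DC1", "DC2")))
  ## two negatives make a positive
  e2 <- signed_edges(c("MK2", "NK"), c("NK", "CK17"), c(-1, -1))
  out2 <- collapse_intermediates(e2, "NK")
  expect_equal(out2$sign[out2$source == "MK2" & out2$target == "CK17"], 1)
})

test_that("collapse agrees with a brute-force two-step path enumerator", {
  set.seed(14)
  nodes <- c(AGGREGATE_NODES[1:5], "C1", "C2", "C3")
  cells <- c("C1", "C2", "C3")
  for (rep in 1:10) {
    pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$s != pairs$t, ]
    pick <- pairs[runif(nrow(pairs)) < 0.25, ]
    if (nrow(pick) == 0) next
    e <- signed_edges(pick$s, pick$t, sample(c(-1, 1), nrow(pick), TRUE))
    out <- collapse_intermediates(e, cells)
    ## oracle: direct edges plus all cytokine-cell-cytokine sign products
    expected <- character(0)
    for (i in seq_len(nrow(e))) {
      if (!e$source[i] %in% cells && !e$target[i] %in% cells) {
        expected <- c(expected, paste(e$source[i], e$target[i], e$sign[i]))
      }
    }
    for (cell in cells) {
      into <- e[e$target == cell & !e$source %in% cells, ]
      outof <- e[e$source == cell & !e$target %in% cells, ]
      for (i in seq_len(nrow(into))) for (j in seq_len(nrow(outof))) {
        if (into$source[i] != outof$target[j]) {
          expected <- c(expected, paste(into$source[i], outof$target[j],
                                        into$sign[i] * outof$sign[j]))
        }
      }
    }
    expect_setequal(paste(out$source, out$target, out$sign), unique(expected))
  }
})

test_that("cytokine edges map onto aggregate sets with MK1 propagation", {
  e <- signed_edges(
    source = c("IL-6", "IL-1b", "IL-1a", "IL-10"),
    target = c("IL-10", "IL-17", "IL-8", "IL-15"),
    sign = c(1, 1, 1, -1))
  out <- map_to_aggregate_sets(e)
  key <- paste(out$source, out$target, out$sign)
  expect_true("MK6 MK2 1" %in% key)
  ## MK1-block edges propagate to both MK1A and MK1B
  expect_true("MK1A CK17 1" %in% key)
  expect_true("MK1B CK17 1" %in% key)
  ## within-block edges are dropped
  expect_false(any(grepl("^MK1. MK1.", key)))
  expect_true("MK2 MK15 -1" %in% key)
  ## idempotent on already-aggregated networks
  again <- map_to_aggregate_sets(out)
  expect_equal(sort(paste(again$source, again$target, again$sign)), sort(key))
})

test_that("conflicting signs resolve by summed confidence with tie flagging", {
  e <- signed_edges(c("IL-6", "IL-6"), c("IL-10", "IL-10"), c(1, -1),
                    confidence = c(0.9, 0.5))
  out <- map_to_aggregate_sets(e)
  expect_equal(out$sign, 1)
  tie <- signed_edges(c("IL-6", "IL-6"), c("IL-10", "IL-10"), c(1, -1),
                      confidence = c(0.7, 0.7))
  out2 <- map_to_aggregate_sets(tie)
  expect_true(is.na(out2$sign))
  expect_match(out2$provenance, "ambiguous")
})

test_that("confidence filtering keeps the boundary and counts edges", {
  e <- signed_edges(c("MK6", "MK2", "CK1"), c("MK2", "MK15", "MK6"),
                    c(1, -1, 1), confidence = c(0.79, 0.80, 0.95))
  kept <- filter_by_confidence(e, 0.80)
  expect_equal(nrow(kept), 2)
  expect_equal(nrow(filter_by_confidence(e, 0)), 3)
  empty <- e[0, ]
  expect_equal(nrow(filter_by_confidence(empty, 0.8)), 0)
  e$confidence[2] <- NA
  expect_error(filter_by_confidence(e), "missing")
})

test_that("network union accounts overlap exactly", {
  a <- signed_edges(c("MK6", "MK2", "CK1"), c("MK2", "MK15", "MK6"),
                    c(1, -1, 1))
  b <- signed_edges(c("MK6", "CK17"), c("MK2", "MK6"), c(1, 1))
  m <- merge_networks(a, b)
  expect_equal(m$report$n_overlap, 1)
  expect_equal(m$report$n_union, 4)
  expect_equal(m$report$n_union,
               m$report$n_a + m$report$n_b - m$report$n_overlap)
  expect_equal(m$network$origin[m$network$source == "MK6"], "both")
  ## identical networks: union = overlap = |a|
  m2 <- merge_networks(a, a)
  expect_equal(m2$report$n_union, 3)
  expect_equal(m2$report$n_overlap, 3)
  ## an opposite-sign shared edge is counted as a conflict
  b2 <- signed_edges("MK6", "MK2", -1)
  m3 <- merge_networks(a, b2)
  expect_equal(m3$report$n_sign_conflicts, 1)
  ## random instances satisfy the inclusion-exclusion identity
  set.seed(3)
  for (rep in 1:5) {
    mk <- function() {
      p <- expand.grid(s = AGGREGATE_NODES, t = AGGREGATE_NODES,
                       stringsAsFactors = FALSE)
      p <- p[p$s != p$t & runif(nrow(p)) < 0.2, ]
      signed_edges(p$s, p$t, sample(c(-1, 1), nrow(p), TRUE))
    }
    x <- mk(); y <- mk()
    r <- merge_networks(x, y)$report
    expect_equal(r$n_union, r$n_a + r$n_b - r$n_overlap)
  }
})

test_that("the packaged synthetic reference network is well formed", {
  ref <- reference_network()
  expect_equal(nrow(ref), 50)
  expect_true(all(ref$sign %in% c(-1, 1)))
  expect_true(all(ref$confidence >= 0.80))
  expect_setequal(unique(c(ref$source, ref$target)), AGGREGATE_NODES)
  ## MK1A/MK1B carry identical connectivity outside the block
  key <- paste(ref$source, ref$target, ref$sign)
  a_edges <- ref[ref$source == "MK1A" | ref$target == "MK1A", ]
  swapped <- paste(sub("MK1A", "MK1B", a_edges$source),
                   sub("MK1A", "MK1B", a_edges$target), a_edges$sign)
  expect_true(all(swapped %in% key))
  ## adjacency round trip preserves the edge set
  A <- edges_to_adjacency(ref)
  back <- adjacency_to_edges(A)
  expect_setequal(paste(back$source, back$target, back$sign), key)
})
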