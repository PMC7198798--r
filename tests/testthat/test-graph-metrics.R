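test_that("graph edit distance matches the elementwise oracle", {
  a <- toy_adjacency(list(list("MK1A", "MK1B", 1)), nodes = c("MK1A", "MK1B"))
  b <- toy_adjacency(list(list("MK1B", "MK1A", 1)), nodes = c("MK1A", "MK1B"))
  expect_equal(graph_edit_distance(a, a, normalize = FALSE), 0)
  expect_equal(graph_edit_distance(a, b, normalize = FALSE), 2)
  ## random 9 x 9 pairs: raw mode equals a double-loop sum; normalized mode
  ## equals the same sum after max-abs scaling and the N(N-1) divisor
  for (s in 1:25) {
    x <- random_signed_matrix(9, 0.4, seed = s)
    y <- random_signed_matrix(9, 0.4, seed = 1000 + s)
    oracle <- 0
    for (i in 1:9) for (j in 1:9) {
      if (i != j) oracle <- oracle + abs(x[i, j] - y[i, j])
    }
    expect_equal(graph_edit_distance(x, y, normalize = FALSE), oracle)
    xs <- x / max(abs(x[row(x) != col(x)]))
    ys <- y / max(abs(y[row(y) != col(y)]))
    oracle_n <- 0
    for (i in 1:9) for (j in 1:9) {
      if (i != j) oracle_n <- oracle_n + abs(xs[i, j] - ys[i, j])
    }
    expect_equal(graph_edit_distance(x, y), oracle_n / 72)
  }
  expect_error(graph_edit_distance(a, random_signed_matrix(3, 1, 1)),
               "mismatch")
})

test_that("normalized edit distance is a metric on random instances", {
  mats <- lapply(1:6, function(s) {
    m <- random_signed_matrix(9, 0.3, seed = 40 + s)
    m / max(abs(m[row(m) != col(m)]))          # pre-normalized weights
  })
  for (i in 1:6) for (j in 1:6) {
    dij <- graph_edit_distance(mats[[i]], mats[[j]])
    expect_equal(dij, graph_edit_distance(mats[[j]], mats[[i]]))
    if (i == j) expect_equal(dij, 0)
    for (k in 1:6) {
      expect_lte(dij, graph_edit_distance(mats[[i]], mats[[k]]) +
                   graph_edit_distance(mats[[k]], mats[[j]]) + 1e-12)
    }
  }
})

test_that("edit-distance resampling separates distinct ensembles only", {
  set.seed(9)
  base1 <- random_signed_matrix(9, 0.3, seed = 3)
  base2 <- random_signed_matrix(9, 0.3, seed = 4)
  wiggle <- function(A, s) {
    set.seed(s); A * (1 + matrix(rnorm(81, 0, 0.1), 9, 9))
  }
  ens1 <- lapply(1:8, function(s) wiggle(base1, s))
  ens2 <- lapply(1:8, function(s) wiggle(base2, 100 + s))
  g <- ged_significance(ens1, ens2, seed = 1)
  expect_lt(g$inter_p[["ranksum_p"]], 0.01)
  expect_identical(g$inter_direction, "inter>intra")
  ## copies of one ensemble: indistinguishable
  g0 <- ged_significance(ens1, lapply(1:8, function(s) wiggle(base1, 200 + s)),
                         seed = 2)
  expect_gt(g0$inter_p[["ranksum_p"]], 0.01)
  ## deterministic under the seed
  g2 <- ged_significance(ens1, ens2, seed = 1)
  expect_identical(g$inter, g2$inter)
  expect_error(ged_significance(ens1[1], ens2, seed = 1), "singleton")
})

test_that("centralities match hand-computed values on a path", {
  ## X -> Y -> Z with unit weights
  A <- toy_adjacency(list(list("MK1A", "MK1B", 1), list("MK1B", "MK2", 1)),
                     nodes = c("MK1A", "MK1B", "MK2"))
  ct <- node_centralities(A)
  rownames(ct) <- ct$node
  ## only Y lies between one ordered pair: 1 / ((3-1)(3-2)) = 0.5
  expect_equal(ct["MK1B", "betweenness"], 0.5)
  expect_equal(ct["MK1A", "betweenness"], 0)
  ## harmonic out-closeness of X: 1/d(X,Y) + 1/d(X,Z) = 1 + 1/2
  expect_equal(ct["MK1A", "outcloseness"], 1.5)
  expect_equal(ct["MK2", "incloseness"], 1.5)
  expect_equal(ct["MK1A", "outdegree"], 1)
  expect_equal(ct["MK2", "indegree"], 1)
  ## doubling all weights halves lengths but not shortest-path structure
  ct2 <- node_centralities(2 * A)
  expect_equal(ct2$betweenness, ct$betweenness)
  ## isolated node scores zero everywhere
  iso <- toy_adjacency(list(list("MK1A", "MK1B", 1)),
                       nodes = c("MK1A", "MK1B", "MK2"))
  cti <- node_centralities(iso)
  expect_true(all(cti[cti$node == "MK2", -1] == 0))
})

test_that("path metrics agree with a Dijkstra + counting oracle", {
  dijkstra <- function(L, s) {            # L: length matrix, Inf = no edge
    n <- nrow(L); dist <- rep(Inf, n); dist[s] <- 0; done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which(!done & dist == min(dist[!done]))[1]
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (v in which(is.finite(L[u, ]))) {
        if (dist[u] + L[u, v] < dist[v]) dist[v] <- dist[u] + L[u, v]
      }
    }
    dist
  }
  for (s in 1:5) {
    A <- random_signed_matrix(7, 0.35, seed = 70 + s)
    W <- abs(A); diag(W) <- 0
    L <- ifelse(t(W) > 0, 1 / t(W), Inf)   # L[u, v]: length of u -> v
    ct <- node_centralities(A)
    n <- nrow(W)
    outclo <- inclo <- numeric(n)
    D <- t(sapply(seq_len(n), function(u) dijkstra(L, u)))
    for (u in seq_len(n)) {
      outclo[u] <- sum(1 / D[u, -u][is.finite(D[u, -u])])
      inclo[u] <- sum(1 / D[-u, u][is.finite(D[-u, u])])
    }
    expect_near(ct$outcloseness, outclo, tol = 1e-9)
    expect_near(ct$incloseness, inclo, tol = 1e-9)
  }
})

test_that("hub and authority scores match eigenvector oracles", {
  ## star: X points at Y and Z
  A <- toy_adjacency(list(list("MK1A", "MK1B", 1), list("MK1A", "MK2", 1)),
                     nodes = c("MK1A", "MK1B", "MK2"))
  h <- hits_scores(A)
  expect_near(h$hub, c(MK1A = 1, MK1B = 0, MK2 = 0))
  expect_near(h$authority, c(MK1A = 0, MK1B = 0.5, MK2 = 0.5))
  ## symmetric 2-cycle
  A2 <- toy_adjacency(list(list("MK1A", "MK1B", 1), list("MK1B", "MK1A", 1)),
                      nodes = c("MK1A", "MK1B"))
  h2 <- hits_scores(A2)
  expect_near(h2$hub, c(MK1A = 0.5, MK1B = 0.5))
  expect_near(h2$authority, c(MK1A = 0.5, MK1B = 0.5))
  ## random graphs: dominant eigenvectors of M'M and MM'
  for (s in 1:5) {
    A <- random_signed_matrix(8, 0.4, seed = 30 + s)
    M <- t(abs(A)); diag(M) <- 0
    h <- hits_scores(A, tol = 1e-13)
    ea <- eigen(crossprod(M))$vectors[, 1]; ea <- abs(ea) / sum(abs(ea))
    eh <- eigen(tcrossprod(M))$vectors[, 1]; eh <- abs(eh) / sum(abs(eh))
    expect_near(unname(h$authority), ea, tol = 1e-6)
    expect_near(unname(h$hub), eh, tol = 1e-6)
  }
  ## relabeling permutes scores identically
  A <- random_signed_matrix(6, 0.5, seed = 77)
  perm <- c(3, 1, 6, 2, 5, 4)
  hp <- hits_scores(A[perm, perm])
  h0 <- hits_scores(A)
  expect_near(unname(hp$hub), unname(h0$hub[perm]), tol = 1e-9)
  expect_warning(hits_scores(matrix(0, 3, 3)), "no edges")
})

test_that("feedforward loops classify by the sign-triple table", {
  mk_ffl <- function(s1, s2, s3) {
    toy_adjacency(list(list("MK1A", "MK1B", s1), list("MK1B", "MK2", s2),
                       list("MK1A", "MK2", s3)),
                  nodes = c("MK1A", "MK1B", "MK2"))
  }
  expected <- list(
    list(c(1, 1, 1), "C1", TRUE), list(c(-1, 1, -1), "C2", TRUE),
    list(c(1, -1, -1), "C3", TRUE), list(c(-1, -1, 1), "C4", TRUE),
    list(c(1, -1, 1), "I1", FALSE), list(c(-1, 1, 1), "I2", FALSE),
    list(c(1, 1, -1), "I3", FALSE), list(c(-1, -1, -1), "I4", FALSE))
  for (e in expected) {
    m <- classify_ffls(mk_ffl(e[[1]][1], e[[1]][2], e[[1]][3]))
    expect_equal(nrow(m), 1)
    expect_identical(m$type, e[[2]])
    expect_identical(m$coherent, e[[3]])
    ## coherence always equals the sign-product rule
    expect_identical(m$coherent, m$sign_xy * m$sign_yz == m$sign_xz)
  }
  ## brute-force triad scan on random signed digraphs
  for (s in 1:8) {
    A <- random_signed_matrix(9, 0.35, seed = 500 + s)
    m <- classify_ffls(A)
    count <- 0
    for (x in 1:9) for (y in 1:9) for (z in 1:9) {
      if (length(unique(c(x, y, z))) == 3 &&
          A[y, x] != 0 && A[z, y] != 0 && A[z, x] != 0) count <- count + 1
    }
    expect_equal(nrow(m), count)
    if (nrow(m) > 0) {
      expect_true(all(m$coherent == (m$sign_xy * m$sign_yz == m$sign_xz)))
    }
  }
})

test_that("feedback loops carry the sign product of their edges", {
  ## reciprocal activation: a positive 2-cycle (self-sustaining signaling)
  A <- toy_adjacency(list(list("MK2", "MK23", 1), list("MK23", "MK2", 1)),
                     nodes = AGGREGATE_NODES)
  fb <- find_feedback_loops(A)
  expect_equal(nrow(fb), 1)
  expect_identical(fb$polarity, "positive")
  ## mixed signs make a negative loop
  A["MK2", "MK23"] <- -1
  fb2 <- find_feedback_loops(A)
  expect_identical(fb2$polarity, "negative")
  ## acyclic graph has none
  dag <- toy_adjacency(list(list("MK1A", "MK1B", 1), list("MK1B", "MK2", 1)),
                       nodes = c("MK1A", "MK1B", "MK2"))
  expect_equal(nrow(find_feedback_loops(dag)), 0)
  ## 3-cycles: sign product oracle on random graphs
  for (s in 1:5) {
    A <- random_signed_matrix(6, 0.4, seed = 600 + s)
    fb <- find_feedback_loops(A, max_len = 3)
    tri <- fb[fb$length == 3, ]
    ## enumerate directed 3-cycles independently
    cnt <- 0
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      if (i < j && i < k && j != k &&
          A[j, i] != 0 && A[k, j] != 0 && A[i, k] != 0) cnt <- cnt + 1
    }
    expect_equal(nrow(tri), cnt)
    if (nrow(tri) > 0) expect_true(all(tri$sign %in% c(-1, 1)))
  }
})

test_that("ensemble centrality medians summarize per-node distributions", {
  nets <- lapply(1:5, function(s) random_signed_matrix(9, 0.3, seed = s))
  med <- ensemble_centrality_medians(nets)
  expect_equal(nrow(med), 9)
  one <- node_centralities(nets[[1]])
  expect_setequal(names(med), names(one))
  ## medians bracketed by the per-network extremes
  tabs <- lapply(nets, node_centralities)
  bt <- sapply(tabs, function(t) t$betweenness)
  expect_true(all(med$betweenness >= apply(bt, 1, min) - 1e-12))
  expect_true(all(med$betweenness <= apply(bt, 1, max) + 1e-12))
})
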