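## Topological comparison and characterization: weighted graph edit
## distance with resampled significance, centralities (weighted degree,
## betweenness, harmonic in/out-closeness), HITS hub/authority scores, and
## signed motif analysis (feedforward loops, feedback cycles).

#' Weighted graph edit distance between two adjacency matrices
#'
#' The edit cost sum `sum_ij |a_ij - b_ij|` over off-diagonal entries. In
#' normalized mode (default) each matrix is first divided by its largest
#' off-diagonal magnitude and the sum is divided by `N (N - 1)`, so values
#' are comparable across networks of different weight scales and lie in
#' `[0, 2]`. Raw mode is the literal edit-cost sum.
#'
#' @param a,b square matrices with identical node order.
#' @param normalize apply per-network max-abs scaling and the `N (N - 1)`
#'   divisor.
#' @param include_diagonal include self-terms in the sum (default FALSE).
#' @return non-negative distance.
#' @export
graph_edit_distance <- function(a, b, normalize = TRUE,
                                include_diagonal = FALSE) {
  a <- as_adjacency_input(a); b <- as_adjacency_input(b)
  if (!identical(dim(a), dim(b))) stopf("dimension mismatch")
  n <- nrow(a)
  off <- if (include_diagonal) matrix(TRUE, n, n) else row(a) != col(a)
  if (normalize) {
    ma <- max(abs(a[off])); mb <- max(abs(b[off]))
    if (ma > 0) a <- a / ma
    if (mb > 0) b <- b / mb
    sum(abs(a[off] - b[off])) / (n * (n - 1))
  } else {
    sum(abs(a[off] - b[off]))
  }
}

#' Resampled significance of inter- vs intra-group edit distances
#'
#' Computes all pairwise GEDs within each ensemble and across ensembles
#' (subsampled to at most `n_draws` pairs per list), then two-sample tests
#' (Student t and Wilcoxon rank-sum) of inter vs pooled intra and of
#' intra-1 vs intra-2.
#'
#' @param ensemble1,ensemble2 lists of adjacency matrices (or
#'   `network_ensemble` objects, whose consensus networks are used).
#' @param n_draws cap on pairs per distance list.
#' @param normalize,include_diagonal passed to [graph_edit_distance()].
#' @param seed integer seed for pair subsampling.
#' @return list with the four distance vectors, `inter_p` (t and ranksum),
#'   `intra_p`, and direction labels.
#' @export
ged_significance <- function(ensemble1, ensemble2, n_draws = 2000,
                             normalize = TRUE, include_diagonal = FALSE,
                             seed = 1) {
  nets1 <- ensemble_networks(ensemble1)
  nets2 <- ensemble_networks(ensemble2)
  if (length(nets1) < 2 || length(nets2) < 2) {
    stopf("intra-group distances undefined for singleton ensembles")
  }
  with_seed(seed, {
    intra_pairs <- function(nets) {
      m <- length(nets)
      pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
      if (nrow(pairs) > n_draws) {
        pairs <- pairs[sample(nrow(pairs), n_draws), , drop = FALSE]
      }
      vapply(seq_len(nrow(pairs)), function(k) {
        graph_edit_distance(nets[[pairs[k, 1]]], nets[[pairs[k, 2]]],
                            normalize = normalize,
                            include_diagonal = include_diagonal)
      }, numeric(1))
    }
    cross_pairs <- function(na, nb) {
      grid <- expand.grid(i = seq_along(na), j = seq_along(nb))
      if (nrow(grid) > n_draws) {
        grid <- grid[sample(nrow(grid), n_draws), , drop = FALSE]
      }
      vapply(seq_len(nrow(grid)), function(k) {
        graph_edit_distance(na[[grid$i[k]]], nb[[grid$j[k]]],
                            normalize = normalize,
                            include_diagonal = include_diagonal)
      }, numeric(1))
    }
    intra1 <- intra_pairs(nets1)
    intra2 <- intra_pairs(nets2)
    inter <- cross_pairs(nets1, nets2)
    pooled <- c(intra1, intra2)
    two_tests <- function(x, y) {
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        return(c(t_p = 1, ranksum_p = 1))
      }
      c(t_p = tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1),
        ranksum_p = stats::wilcox.test(x, y, exact = FALSE,
                                       correct = FALSE)$p.value)
    }
    list(intra1 = intra1, intra2 = intra2, pooled_intra = pooled,
         inter = inter,
         inter_p = two_tests(inter, pooled),
         intra_p = two_tests(intra1, intra2),
         inter_direction = if (mean(inter) >= mean(pooled))
           "inter>intra" else "inter<intra",
         intra_direction = if (mean(intra1) >= mean(intra2))
           "intra1>intra2" else "intra1<intra2")
  })
}

ensemble_networks <- function(x) {
  if (inherits(x, "network_ensemble")) x$consensus_networks
  else if (inherits(x, "rate_network")) list(x$A)
  else if (is.list(x)) lapply(x, as_adjacency_input)
  else list(as_adjacency_input(x))
}

#' Node centralities of a signed weighted digraph
#'
#' Weighted in/out-degree (sums of magnitudes), betweenness normalized by
#' `(N - 1)(N - 2)`, and unnormalized harmonic in/out-closeness, with edge
#' length `1 / |weight|` for all shortest-path metrics (signs are ignored
#' for path metrics), plus L1-normalized HITS hub/authority scores.
#'
#' @param A adjacency matrix (target rows, source columns).
#' @return data.frame, one row per node.
#' @export
node_centralities <- function(A) {
  A <- as_adjacency_input(A)
  n <- nrow(A)
  nodes <- rownames(A) %||% as.character(seq_len(n))
  W <- abs(A); diag(W) <- 0
  indeg <- rowSums(W)           # A[i, j]: j -> i
  outdeg <- colSums(W)
  g <- igraph_from_adjacency(A)
  if (igraph::ecount(g) > 0) {
    len <- 1 / igraph::E(g)$weight
    btw <- igraph::betweenness(g, weights = len, directed = TRUE,
                               normalized = TRUE)
    outclo <- igraph::harmonic_centrality(g, weights = len, mode = "out",
                                          normalized = FALSE)
    inclo <- igraph::harmonic_centrality(g, weights = len, mode = "in",
                                         normalized = FALSE)
    h <- hits_scores(A)
  } else {
    btw <- outclo <- inclo <- stats::setNames(rep(0, n), nodes)
    h <- list(hub = stats::setNames(rep(0, n), nodes),
              authority = stats::setNames(rep(0, n), nodes))
  }
  data.frame(node = nodes, indegree = unname(indeg[nodes]),
             outdegree = unname(outdeg[nodes]),
             betweenness = unname(btw[nodes]),
             incloseness = unname(inclo[nodes]),
             outcloseness = unname(outclo[nodes]),
             hub = unname(h$hub[nodes]),
             authority = unname(h$authority[nodes]),
             stringsAsFactors = FALSE)
}

igraph_from_adjacency <- function(A) {
  W <- abs(A); diag(W) <- 0
  ## igraph adjacency: entry [u, v] = edge u -> v; our A[i, j] = j -> i
  igraph::graph_from_adjacency_matrix(t(W), mode = "directed",
                                      weighted = TRUE)
}

#' Per-node medians of centralities across an ensemble
#'
#' @param networks list of adjacency matrices or a `network_ensemble`.
#' @return data.frame of per-node medians for every centrality.
#' @export
ensemble_centrality_medians <- function(networks) {
  nets <- ensemble_networks(networks)
  tabs <- lapply(nets, node_centralities)
  nodes <- tabs[[1]]$node
  metrics <- setdiff(names(tabs[[1]]), "node")
  out <- data.frame(node = nodes, stringsAsFactors = FALSE)
  for (m in metrics) {
    M <- vapply(tabs, function(t) t[[m]], numeric(length(nodes)))
    out[[m]] <- apply(matrix(M, nrow = length(nodes)), 1, stats::median)
  }
  out
}

#' HITS hub and authority scores
#'
#' Power iteration on the magnitude adjacency with L1 normalization at each
#' step, from a uniform start: hubs point to good authorities, authorities
#' are pointed to by good hubs. Deterministic.
#'
#' @param A adjacency matrix (target rows, source columns).
#' @param tol convergence tolerance on successive iterates.
#' @param max_iter iteration cap.
#' @return list with unit-L1 `hub` and `authority` vectors (zeros with a
#'   warning for an edgeless graph).
#' @export
hits_scores <- function(A, tol = 1e-9, max_iter = 1000) {
  A <- as_adjacency_input(A)
  n <- nrow(A)
  nodes <- rownames(A) %||% as.character(seq_len(n))
  W <- abs(A); diag(W) <- 0
  if (all(W == 0)) {
    warnf("graph has no edges; zero hub/authority scores")
    z <- stats::setNames(rep(0, n), nodes)
    return(list(hub = z, authority = z))
  }
  M <- t(W)                      # M[u, v] = weight of u -> v
  h <- rep(1 / n, n); a <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    a_new <- as.vector(crossprod(M, h)); a_new <- a_new / sum(a_new)
    h_new <- as.vector(M %*% a_new); h_new <- h_new / sum(h_new)
    if (max(abs(a_new - a)) < tol && max(abs(h_new - h)) < tol) {
      a <- a_new; h <- h_new
      break
    }
    a <- a_new; h <- h_new
  }
  list(hub = stats::setNames(h, nodes),
       authority = stats::setNames(a, nodes))
}

## Mangan-Alon sign-triple table for feedforward loops:
## key = signs of (X->Y, Y->Z, X->Z)
FFL_TYPES <- c(
  "+ + +" = "C1", "- + -" = "C2", "+ - -" = "C3", "- - +" = "C4",
  "+ - +" = "I1", "- + +" = "I2", "+ + -" = "I3", "- - -" = "I4"
)

#' Enumerate and classify feedforward loops
#'
#' Enumerates ordered triples (X, Y, Z) with edges X->Y, Y->Z and X->Z;
#' a loop is coherent iff the indirect sign product `sign(X->Y) sign(Y->Z)`
#' equals the direct sign `sign(X->Z)`, and typed C1-C4 / I1-I4 by the
#' standard sign-triple table.
#'
#' @param A signed adjacency matrix (target rows, source columns).
#' @return data.frame: X, Y, Z, the three signs, `coherent`, `type`.
#' @export
classify_ffls <- function(A) {
  A <- as_adjacency_input(A)
  nodes <- rownames(A) %||% as.character(seq_len(nrow(A)))
  n <- nrow(A)
  has <- function(from, to) A[to, from] != 0
  sgn <- function(from, to) sign(A[to, from])
  rows <- list()
  for (x in seq_len(n)) for (y in seq_len(n)) for (z in seq_len(n)) {
    if (x == y || y == z || x == z) next
    if (has(x, y) && has(y, z) && has(x, z)) {
      s1 <- sgn(x, y); s2 <- sgn(y, z); s3 <- sgn(x, z)
      key <- paste(ifelse(c(s1, s2, s3) > 0, "+", "-"), collapse = " ")
      rows[[length(rows) + 1]] <- data.frame(
        X = nodes[x], Y = nodes[y], Z = nodes[z],
        sign_xy = s1, sign_yz = s2, sign_xz = s3,
        coherent = s1 * s2 == s3, type = unname(FFL_TYPES[key]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(X = character(0), Y = character(0), Z = character(0),
                      sign_xy = numeric(0), sign_yz = numeric(0),
                      sign_xz = numeric(0), coherent = logical(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Enumerate simple feedback cycles up to a maximum length
#'
#' Finds 2-cycles and (by default) 3-cycles; the loop sign is the product
#' of member-edge signs, labeling the cycle positive (self-reinforcing) or
#' negative (self-limiting).
#'
#' @param A signed adjacency matrix (target rows, source columns).
#' @param max_len maximum cycle length (2 or 3).
#' @return data.frame: `nodes` (cycle as "a->b->a"), `length`, `sign`,
#'   `polarity`.
#' @export
find_feedback_loops <- function(A, max_len = 3) {
  A <- as_adjacency_input(A)
  stopifnot(max_len >= 2)
  nodes <- rownames(A) %||% as.character(seq_len(nrow(A)))
  n <- nrow(A)
  has <- function(from, to) A[to, from] != 0
  sgn <- function(from, to) sign(A[to, from])
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && has(i, j) && has(j, i)) {
      s <- sgn(i, j) * sgn(j, i)
      rows[[length(rows) + 1]] <- data.frame(
        nodes = sprintf("%s->%s->%s", nodes[i], nodes[j], nodes[i]),
        length = 2L, sign = s,
        polarity = if (s > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  if (max_len >= 3) {
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (i >= j || j >= k) next     # canonical: i < j < k, orientations below
      for (ord in list(c(i, j, k), c(i, k, j))) {
        a <- ord[1]; b <- ord[2]; cc <- ord[3]
        if (has(a, b) && has(b, cc) && has(cc, a)) {
          s <- sgn(a, b) * sgn(b, cc) * sgn(cc, a)
          rows[[length(rows) + 1]] <- data.frame(
            nodes = sprintf("%s->%s->%s->%s", nodes[a], nodes[b],
                            nodes[cc], nodes[a]),
            length = 3L, sign = s,
            polarity = if (s > 0) "positive" else "negative",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(nodes = character(0), length = integer(0),
                      sign = numeric(0), polarity = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
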