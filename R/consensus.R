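## Two-level consensus over per-subject networks: majority-rule consensus
## networks on repeated subject subsamples, then the unanimity
## "characteristic" network across all consensus networks, with
## recall/PPV distributions against a reference.

#' Draw repeated subject subsamples
#'
#' Each subset is drawn without replacement within itself; distinct draws
#' may coincide (with 11 subjects and size 10 there are only 11 possible
#' subsets). Deterministic per seed.
#'
#' @param subject_ids character vector.
#' @param subset_size subjects per subsample (default 10).
#' @param n_subsamples number of draws (default 100).
#' @param seed integer seed.
#' @return list of sorted id vectors.
#' @export
subject_subsamples <- function(subject_ids, subset_size = 10,
                               n_subsamples = 100, seed = 1) {
  if (subset_size > length(subject_ids)) {
    stopf("subset_size %d exceeds group size %d", subset_size,
          length(subject_ids))
  }
  with_seed(seed, {
    lapply(seq_len(n_subsamples), function(i) {
      sort(sample(subject_ids, subset_size))
    })
  })
}

#' Majority-rule consensus of a set of signed networks
#'
#' An edge is retained iff present (nonzero, same direction) in at least
#' `quorum` networks. The consensus sign is the majority sign among
#' supporters (a tie drops the edge); the consensus weight is the median
#' magnitude among supporters carrying the majority sign, signed.
#'
#' @param networks list of adjacency matrices (same node order).
#' @param quorum minimum support (default 6 of 10).
#' @return consensus adjacency matrix.
#' @export
majority_consensus <- function(networks, quorum = 6) {
  check_same_nodes(networks)
  A1 <- networks[[1]]
  n <- nrow(A1)
  out <- matrix(0, n, n, dimnames = dimnames(A1))
  stack <- simplify2array(networks)        # n x n x m
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      w <- stack[i, j, ]
      w <- w[w != 0]
      if (length(w) < quorum) next
      n_pos <- sum(w > 0); n_neg <- sum(w < 0)
      if (n_pos == n_neg) {
        log_info("sign tie on consensus edge %s -> %s; dropped",
                 colnames(A1)[j], rownames(A1)[i])
        next
      }
      s <- if (n_pos > n_neg) 1 else -1
      out[i, j] <- s * stats::median(abs(w[sign(w) == s]))
    }
  }
  out
}

#' Unanimity characteristic network of an ensemble
#'
#' Retains edges present in every consensus network of the ensemble; signs
#' by majority across them (tie drops), weights by median magnitude among
#' majority-sign supporters.
#'
#' @param networks non-empty list of consensus adjacency matrices.
#' @return characteristic adjacency matrix (empty with a warning when the
#'   intersection is empty).
#' @export
unanimity_characteristic <- function(networks) {
  if (length(networks) == 0) stopf("empty ensemble")
  out <- majority_consensus(networks, quorum = length(networks))
  if (all(out == 0)) warnf("unanimity network is empty")
  out
}

check_same_nodes <- function(networks) {
  if (length(networks) == 0) stopf("no networks supplied")
  d <- dim(networks[[1]])
  nm <- rownames(networks[[1]])
  for (g in networks) {
    if (!identical(dim(g), d) ||
        (!is.null(nm) && !identical(rownames(g), nm))) {
      stopf("networks must share one node universe")
    }
  }
  invisible(TRUE)
}

#' Build the group consensus ensemble from per-subject networks
#'
#' Infers (or accepts precomputed) per-subject networks once — a subject's
#' network does not depend on the subsample — and assembles the
#' majority-rule consensus network of each subject subsample.
#'
#' @param subject_networks named list of adjacency matrices, one per subject.
#' @param subset_size,n_subsamples,seed see [subject_subsamples()].
#' @param quorum majority quorum (default 6).
#' @param group label carried in the result.
#' @return a `network_ensemble`: list with `consensus_networks`,
#'   `characteristic` (unanimity network), `subsamples`, `support`
#'   (per-edge count of consensus networks containing it), `group`.
#' @export
consensus_ensemble <- function(subject_networks, subset_size = 10,
                               n_subsamples = 100, quorum = 6, seed = 1,
                               group = NA_character_) {
  ids <- names(subject_networks)
  if (is.null(ids)) stopf("subject_networks must be a named list")
  subs <- subject_subsamples(ids, subset_size, n_subsamples, seed)
  consensus <- lapply(subs, function(s) {
    majority_consensus(subject_networks[s], quorum = quorum)
  })
  support <- Reduce(`+`, lapply(consensus, function(A) (A != 0) * 1))
  structure(list(consensus_networks = consensus,
                 characteristic = suppressWarnings(
                   unanimity_characteristic(consensus)),
                 subsamples = subs, support = support, group = group),
            class = "network_ensemble")
}

#' @export
print.network_ensemble <- function(x, ...) {
  ne <- vapply(x$consensus_networks,
               function(A) sum(A != 0 & row(A) != col(A)), numeric(1))
  cat(sprintf(
    "<network_ensemble> %s: %d consensus networks (median %d edges), %d characteristic edges\n",
    x$group, length(x$consensus_networks), as.integer(stats::median(ne)),
    sum(x$characteristic != 0 & row(x$characteristic) != col(x$characteristic))))
  invisible(x)
}

#' Recall/PPV distributions against a reference at rising consensus levels
#'
#' Scores every network of a list (per-subject or consensus) against the
#' reference via [edge_fscore()] and summarizes the distributions, plus the
#' single characteristic network when an ensemble is supplied.
#'
#' @param networks a `network_ensemble` or list of adjacency matrices.
#' @param reference reference network (matrix or [signed_edges()]).
#' @param sign_sensitive match signs.
#' @return data.frame with one row per level (`consensus`,
#'   `characteristic`): median/mean recall and PPV and median edge count,
#'   with the full per-network distributions in `attr(, "distributions")`.
#' @export
ensemble_concordance <- function(networks, reference,
                                 sign_sensitive = FALSE) {
  Ar <- as_adjacency_input(reference)
  levels <- list()
  if (inherits(networks, "network_ensemble")) {
    levels$consensus <- networks$consensus_networks
    levels$characteristic <- list(networks$characteristic)
  } else {
    levels$consensus <- networks
  }
  dists <- list()
  rows <- lapply(names(levels), function(lv) {
    sc <- lapply(levels[[lv]], function(A) {
      fs <- edge_fscore(A, Ar, sign_sensitive = sign_sensitive)
      c(recall = fs$recall, ppv = fs$ppv, f = fs$f,
        n_edges = fs$n_inferred)
    })
    M <- do.call(rbind, sc)
    dists[[lv]] <<- M
    data.frame(level = lv,
               median_recall = stats::median(M[, "recall"]),
               mean_recall = mean(M[, "recall"]),
               median_ppv = stats::median(M[, "ppv"]),
               mean_ppv = mean(M[, "ppv"]),
               median_edges = stats::median(M[, "n_edges"]),
               n_networks = nrow(M), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "distributions") <- dists
  out
}
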