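## Literature-informed reference network construction: collapse of
## cytokine-cell-cytokine paths with sign products, mapping of cytokines to
## aggregate functional sets, confidence filtering of imported interaction
## tables, and union merging with overlap accounting.

#' Construct a signed edge table
#'
#' @param source,target node names.
#' @param sign +1 (activation) or -1 (inhibition); NA marks an edge whose
#'   sign is ambiguous (excluded from sign-sensitive scoring).
#' @param weight optional edge weight (default 1).
#' @param confidence optional confidence score in `[0, 1]`.
#' @param provenance free-text origin.
#' @return data.frame of class `signed_edges`.
#' @export
signed_edges <- function(source, target, sign, weight = 1,
                         confidence = NA_real_, provenance = "") {
  n <- length(source)
  stopifnot(length(target) == n, length(sign) == n)
  if (any(!is.na(sign) & !sign %in% c(-1, 1))) {
    stopf("edge signs must be +1, -1 or NA")
  }
  if (any(source == target)) stopf("self-loops are not allowed")
  out <- data.frame(source = as.character(source),
                    target = as.character(target),
                    sign = as.numeric(sign),
                    weight = rep_len(as.numeric(weight), n),
                    confidence = rep_len(as.numeric(confidence), n),
                    provenance = rep_len(as.character(provenance), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("signed_edges", "data.frame")
  out
}

#' Collapse immune-cell intermediates out of a mixed signed digraph
#'
#' Keeps direct cytokine-to-cytokine edges and, for every length-2 path
#' cytokine -> cell -> cytokine, adds a cytokine edge whose sign is the
#' product of the two path signs. Longer paths (e.g. through two cells) are
#' not traversed. Cell nodes are removed.
#'
#' @param edges a [signed_edges()] table over cytokine and cell nodes.
#' @param cell_nodes names of the intermediate cell nodes.
#' @return cytokine-only [signed_edges()] (duplicates with identical sign
#'   collapsed; opposite-sign duplicates kept for later resolution).
#' @export
collapse_intermediates <- function(edges, cell_nodes) {
  nodes <- unique(c(edges$source, edges$target))
  unlabeled <- character(0)
  is_cell <- nodes %in% cell_nodes
  cyt_nodes <- nodes[!is_cell]
  direct <- edges[!edges$source %in% cell_nodes &
                    !edges$target %in% cell_nodes, , drop = FALSE]
  via <- list()
  for (cell in intersect(cell_nodes, nodes)) {
    into <- edges[edges$target == cell & !edges$source %in% cell_nodes, ,
                  drop = FALSE]
    outof <- edges[edges$source == cell & !edges$target %in% cell_nodes, ,
                   drop = FALSE]
    if (nrow(into) == 0 || nrow(outof) == 0) next
    for (i in seq_len(nrow(into))) {
      for (j in seq_len(nrow(outof))) {
        if (into$source[i] == outof$target[j]) next  # would be a self-loop
        via[[length(via) + 1]] <- data.frame(
          source = into$source[i], target = outof$target[j],
          sign = into$sign[i] * outof$sign[j],
          weight = min(into$weight[i], outof$weight[j]),
          confidence = suppressWarnings(
            min(into$confidence[i], outof$confidence[j])),
          provenance = sprintf("via %s", cell),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind(direct, do.call(rbind, via))
  if (is.null(out) || nrow(out) == 0) {
    return(signed_edges(character(0), character(0), numeric(0)))
  }
  key <- paste(out$source, out$target, out$sign)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signed_edges", "data.frame")
  out
}

#' Map a cytokine-level digraph onto the aggregate functional sets
#'
#' Each edge (c1 -> c2) becomes (set(c1) -> set(c2)); within-set edges are
#' dropped; duplicate aggregate edges are collapsed by union. Any edge
#' incident to the shared MK1 block is emitted for both MK1A and MK1B.
#' Opposite signs collapsing onto one aggregate edge are resolved in favor
#' of the larger summed confidence; ties yield sign NA (ambiguous), flagged
#' in `provenance`.
#'
#' @param edges cytokine-level [signed_edges()].
#' @param map result of [functional_set_map()] (default).
#' @return aggregate-level [signed_edges()] over [AGGREGATE_NODES].
#' @export
map_to_aggregate_sets <- function(edges, map = functional_set_map()) {
  expand_node <- function(nm) {
    if (nm %in% AGGREGATE_NODES) return(nm)            # already aggregated
    if (nm == "MK1") return(c("MK1A", "MK1B"))
    s <- map$set_of[nm]
    if (is.na(s)) stopf("node %s is neither a panel cytokine nor an aggregate set", nm)
    if (s == "MK1") c("MK1A", "MK1B") else unname(s)
  }
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    for (s in expand_node(edges$source[i])) {
      for (t in expand_node(edges$target[i])) {
        if (s == t) next                               # within-set dropped
        if (all(c(s, t) %in% c("MK1A", "MK1B")) &&
            !all(c(edges$source[i], edges$target[i]) %in% c("MK1A", "MK1B"))) {
          next  # both endpoints inside the shared MK1 block
        }
        rows[[length(rows) + 1]] <- data.frame(
          source = s, target = t, sign = edges$sign[i],
          weight = edges$weight[i], confidence = edges$confidence[i],
          provenance = edges$provenance[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(signed_edges(character(0), character(0), numeric(0)))
  }
  out <- do.call(rbind, rows)
  resolve_sign_conflicts(out)
}

## Collapse duplicate (source, target) rows: same sign -> union (max weight,
## max confidence); opposite signs -> larger summed confidence wins, tie ->
## sign NA flagged "ambiguous".
resolve_sign_conflicts <- function(out) {
  key <- paste(out$source, out$target, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(out)), key), function(idx) {
    sub <- out[idx, , drop = FALSE]
    if (length(unique(stats::na.omit(sub$sign))) <= 1) {
      r <- sub[1, , drop = FALSE]
      r$sign <- stats::na.omit(sub$sign)[1]
      r$weight <- max(sub$weight)
      r$confidence <- suppressWarnings(max(sub$confidence))
      return(r)
    }
    conf <- ifelse(is.na(sub$confidence), 1, sub$confidence)
    pos <- sum(conf[sub$sign == 1]); neg <- sum(conf[sub$sign == -1])
    r <- sub[1, , drop = FALSE]
    if (pos == neg) {
      r$sign <- NA_real_
      r$provenance <- "ambiguous sign"
      log_info("sign conflict tie on %s -> %s; marked ambiguous",
               r$source, r$target)
    } else {
      r$sign <- if (pos > neg) 1 else -1
      r$provenance <- paste0(r$provenance, " [sign conflict resolved]")
      log_info("sign conflict on %s -> %s resolved to %+d",
               r$source, r$target, r$sign)
    }
    r$weight <- max(sub$weight)
    r$confidence <- suppressWarnings(max(sub$confidence))
    r
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$source, res$target), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("signed_edges", "data.frame")
  res
}

#' Filter an imported interaction table by confidence
#'
#' @param edges [signed_edges()] with a populated `confidence` column.
#' @param min_conf minimum confidence retained (inclusive; default 0.80).
#' @return filtered [signed_edges()].
#' @export
filter_by_confidence <- function(edges, min_conf = 0.80) {
  if (anyNA(edges$confidence)) {
    stopf("confidence missing for %d edge(s)", sum(is.na(edges$confidence)))
  }
  keep <- edges$confidence >= min_conf
  log_info("confidence filter >= %.2f kept %d of %d edges",
           min_conf, sum(keep), length(keep))
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two aggregate networks by union with overlap accounting
#'
#' Overlap counts edges sharing source, target and direction in both inputs.
#' Sign conflicts on shared edges are resolved via the summed-confidence
#' rule and counted.
#'
#' @param a,b aggregate-level [signed_edges()] over the same node universe.
#' @return list with `network` (merged [signed_edges()], per-edge
#'   `origin` column: "a", "b" or "both") and `report`
#'   (`n_a`, `n_b`, `n_overlap`, `n_union`, `n_sign_conflicts`).
#' @export
merge_networks <- function(a, b) {
  nodes_a <- unique(c(a$source, a$target))
  nodes_b <- unique(c(b$source, b$target))
  if (length(union(setdiff(nodes_a, AGGREGATE_NODES),
                   setdiff(nodes_b, AGGREGATE_NODES))) > 0) {
    stopf("merge expects aggregate-level networks over the 9 functional sets")
  }
  key_a <- paste(a$source, a$target)
  key_b <- paste(b$source, b$target)
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stopf("inputs must not contain duplicate (source, target) pairs")
  }
  shared <- intersect(key_a, key_b)
  conflicts <- 0L
  rows <- list()
  for (k in union(key_a, key_b)) {
    ia <- match(k, key_a); ib <- match(k, key_b)
    if (!is.na(ia) && !is.na(ib)) {
      both <- rbind(a[ia, ], b[ib, ])
      r <- resolve_sign_conflicts(both)
      if (!is.na(a$sign[ia]) && !is.na(b$sign[ib]) &&
          a$sign[ia] != b$sign[ib]) conflicts <- conflicts + 1L
      r$origin <- "both"
    } else if (!is.na(ia)) {
      r <- a[ia, , drop = FALSE]; r$origin <- "a"
    } else {
      r <- b[ib, , drop = FALSE]; r$origin <- "b"
    }
    rows[[length(rows) + 1]] <- r
  }
  network <- do.call(rbind, rows)
  network <- network[order(network$source, network$target), , drop = FALSE]
  rownames(network) <- NULL
  class(network) <- c("signed_edges", "data.frame")
  list(network = network,
       report = list(n_a = nrow(a), n_b = nrow(b),
                     n_overlap = length(shared),
                     n_union = nrow(network),
                     n_sign_conflicts = conflicts))
}

#' Edge table <-> adjacency matrix conversion
#'
#' Adjacency orientation follows the rate model: `A[i, j]` is the influence
#' of source j on target i, so an edge (source, target) populates
#' `A[target, source]` with `sign * weight`.
#'
#' @param edges a [signed_edges()] table.
#' @param nodes node order (default [AGGREGATE_NODES]).
#' @param signed_only drop ambiguous-sign (NA) edges when TRUE.
#' @return square matrix.
#' @export
edges_to_adjacency <- function(edges, nodes = AGGREGATE_NODES,
                               signed_only = FALSE) {
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    s <- edges$sign[i]
    if (is.na(s)) {
      if (signed_only) next
      s <- 0
    }
    w <- if (s == 0) edges$weight[i] else s * abs(edges$weight[i])
    A[edges$target[i], edges$source[i]] <- w
  }
  A
}

#' @rdname edges_to_adjacency
#' @param A adjacency matrix (target rows, source columns).
#' @export
adjacency_to_edges <- function(A) {
  nodes <- rownames(A) %||% as.character(seq_len(nrow(A)))
  idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(signed_edges(character(0), character(0), numeric(0)))
  }
  out <- signed_edges(source = nodes[idx[, "col"]],
                      target = nodes[idx[, "row"]],
                      sign = sign(A[idx]), weight = abs(A[idx]))
  out[order(out$source, out$target), , drop = FALSE]
}

#' Load the packaged synthetic 9-node reference network
#'
#' A stand-in literature-informed reference: 50 directed signed edges over
#' the 9 functional sets with plausible immune-signaling polarity,
#' clearly synthetic (the study's own unified reference table is not
#' publicly deposited). Shipped as a plain TSV in `extdata`.
#'
#' @return [signed_edges()] with 50 edges.
#' @export
reference_network <- function() {
  path <- system.file("extdata", "reference_network_synthetic.tsv",
                      package = "immunet", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  signed_edges(df$source, df$target, df$sign, df$weight, df$confidence,
               df$provenance)
}
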