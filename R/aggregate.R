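## Aggregation of the 16 panel cytokines into 9 functional sets.
##
## Multi-cytokine sets are scored by principal components of the pooled
## (both groups, all subjects, all recovery time points) mean-centered log2
## fold-change block; the MK1 block contributes two co-expression scores
## (MK1A = PC1, MK1B = PC2). Singleton sets are centered log2 fold changes.

#' The fixed cytokine-to-functional-set map
#'
#' Monokine (MK) sets originate predominantly from monocytes/dendritic
#' cells, cytokine (CK) sets from lymphocytes. The MK1 block (IL-1a, IL-1b,
#' IL-8, IL-12) is shared by MK1A and MK1B, which denote its first and
#' second pooled principal-component scores.
#'
#' @return list with `blocks` (named list: set base name -> cytokines) and
#'   `set_of` (named vector mapping each cytokine to its set base name;
#'   the MK1 block maps to `"MK1"`).
#' @export
functional_set_map <- function() {
  blocks <- list(
    MK1 = c("IL-1a", "IL-1b", "IL-8", "IL-12"),
    MK2 = "IL-10",
    MK6 = "IL-6",
    MK15 = "IL-15",
    MK23 = "IL-23",
    CK1 = c("IL-2", "IFNg", "TNFa", "TNFb"),
    CK2 = c("IL-4", "IL-5", "IL-13"),
    CK17 = "IL-17"
  )
  set_of <- stats::setNames(
    rep(names(blocks), lengths(blocks)), unlist(blocks))
  list(blocks = blocks, set_of = set_of)
}

#' Functional set of a single cytokine
#'
#' @param cytokine cytokine name(s).
#' @return set base name(s); the MK1 block returns `"MK1"` (scored as both
#'   MK1A and MK1B).
#' @export
cytokine_set <- function(cytokine) {
  m <- functional_set_map()$set_of
  unknown <- setdiff(cytokine, names(m))
  if (length(unknown) > 0) {
    stopf("cytokine(s) not in the panel: %s", paste(unknown, collapse = ", "))
  }
  unname(m[cytokine])
}

#' Per-subject aggregate score container
#'
#' @param subject_id,group identifiers.
#' @param scores node x time matrix (rows named by aggregate node).
#' @param minutes time grid (minutes from peak effort).
#' @return an `aggregate_scores` object.
#' @export
aggregate_scores <- function(subject_id, group, scores, minutes) {
  stopifnot(ncol(scores) == length(minutes))
  structure(list(subject_id = subject_id, group = group,
                 node_names = rownames(scores), scores = scores,
                 minutes = minutes),
            class = "aggregate_scores")
}

#' @export
print.aggregate_scores <- function(x, ...) {
  cat(sprintf("<aggregate_scores> %s (%s): %d nodes x %d time points\n",
              x$subject_id, x$group, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

## Long fold-change series -> per-subject time x cytokine log2 matrix on the
## common grid. Returns list(subject_id, group, minutes, L[time, cytokine]).
series_log2_blocks <- function(series) {
  if (attr(series, "units", exact = TRUE) != "fold_change") {
    stopf("aggregation expects fold-change series")
  }
  out <- list()
  for (sid in unique(series$subject_id)) {
    sub <- series[series$subject_id == sid, , drop = FALSE]
    minutes <- sort(unique(sub$minutes))
    cyts <- sort(unique(sub$cytokine))
    L <- matrix(NA_real_, length(minutes), length(cyts),
                dimnames = list(NULL, cyts))
    for (cy in cyts) {
      rows <- sub[sub$cytokine == cy, , drop = FALSE]
      L[match(rows$minutes, minutes), cy] <- log2(rows$value)
    }
    if (anyNA(L)) stopf("subject %s has an incomplete time grid", sid)
    out[[sid]] <- list(subject_id = sid, group = sub$group[1],
                       minutes = minutes, L = L)
  }
  out
}

#' Fit the pooled principal-component model for multi-cytokine sets
#'
#' Per multi-cytokine set, principal components of the mean-centered (not
#' variance-scaled) log2 fold-change block pooled over all subjects of both
#' groups and all time points — one common coordinate system for cross-group
#' comparison. Component signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param series recovery-phase fold-change `uniform_series_set` for the
#'   whole cohort.
#' @param second_pc_threshold a second component is retained only when PC1
#'   explains less than this fraction of the block variance (default 0.80).
#' @param layout `"fixed"` (default): the MK1 block always contributes
#'   MK1A/MK1B (PC1/PC2) and other sets one component, the established
#'   9-node layout; `"auto"`: the threshold rule decides for every block.
#' @return an `aggregate_model`: per-set loadings, centers, and variance
#'   fractions, plus the resulting node-name order.
#' @export
fit_pooled_pca <- function(series, second_pc_threshold = 0.80,
                           layout = c("fixed", "auto")) {
  layout <- match.arg(layout)
  blocks <- functional_set_map()$blocks
  pooled <- series_log2_blocks(series)
  L_all <- do.call(rbind, lapply(pooled, `[[`, "L"))
  sets <- list()
  node_names <- character(0)
  for (bn in names(blocks)) {
    cyts <- blocks[[bn]]
    if (length(cyts) == 1) {
      center <- mean(L_all[, cyts])
      sets[[bn]] <- list(kind = "singleton", cytokines = cyts,
                         center = center, var_fractions = 1)
      node_names <- c(node_names, bn)
      next
    }
    X <- L_all[, cyts, drop = FALSE]
    if (max(apply(X, 2, stats::sd)) < 1e-12) {
      stopf("set %s has (near-)constant expression; components degenerate", bn)
    }
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    vf <- pc$sdev^2 / sum(pc$sdev^2)
    n_keep <- if (vf[1] < second_pc_threshold && length(vf) > 1) 2L else 1L
    if (layout == "fixed") n_keep <- if (bn == "MK1") 2L else 1L
    W <- pc$rotation[, seq_len(n_keep), drop = FALSE]
    for (k in seq_len(n_keep)) {          # sign: largest |loading| positive
      j <- which.max(abs(W[, k]))
      if (W[j, k] < 0) W[, k] <- -W[, k]
    }
    comp_names <- if (bn == "MK1") {
      c("MK1A", "MK1B")[seq_len(n_keep)]
    } else if (n_keep == 1) bn else paste0(bn, c("A", "B"))
    colnames(W) <- comp_names
    sets[[bn]] <- list(kind = "pca", cytokines = cyts, center = pc$center,
                       loadings = W, var_fractions = vf)
    node_names <- c(node_names, comp_names)
  }
  canonical <- intersect(AGGREGATE_NODES, node_names)
  node_names <- c(canonical, setdiff(node_names, canonical))
  structure(list(sets = sets, node_names = node_names,
                 second_pc_threshold = second_pc_threshold, layout = layout),
            class = "aggregate_model")
}

#' @export
print.aggregate_model <- function(x, ...) {
  cat(sprintf("<aggregate_model> %d nodes: %s\n", length(x$node_names),
              paste(x$node_names, collapse = ", ")))
  for (bn in names(x$sets)) {
    s <- x$sets[[bn]]
    if (s$kind == "pca") {
      cat(sprintf("  %s: PC variance fractions %s\n", bn,
                  paste(sprintf("%.3f", s$var_fractions), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Project subject series onto the pooled aggregate model
#'
#' Singleton sets score as centered log2 fold change; multi-cytokine sets as
#' projections of the centered block onto the pooled loadings.
#'
#' @param series recovery-phase fold-change `uniform_series_set`.
#' @param model an `aggregate_model` from [fit_pooled_pca()].
#' @return list of [aggregate_scores()] per subject (node x time matrices in
#'   the model's node order).
#' @export
score_aggregates <- function(series, model) {
  pooled <- series_log2_blocks(series)
  lapply(pooled, function(sub) {
    S <- matrix(NA_real_, length(model$node_names), length(sub$minutes),
                dimnames = list(model$node_names, NULL))
    for (bn in names(model$sets)) {
      s <- model$sets[[bn]]
      missing <- setdiff(s$cytokines, colnames(sub$L))
      if (length(missing) > 0) {
        stopf("subject %s lacks cytokine(s) %s for set %s",
              sub$subject_id, paste(missing, collapse = ", "), bn)
      }
      if (s$kind == "singleton") {
        S[bn, ] <- sub$L[, s$cytokines] - s$center
      } else {
        X <- sweep(sub$L[, s$cytokines, drop = FALSE], 2, s$center)
        S[colnames(s$loadings), ] <- t(X %*% s$loadings)
      }
    }
    aggregate_scores(sub$subject_id, sub$group, S, sub$minutes)
  })
}
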