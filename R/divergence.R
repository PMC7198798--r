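## Per-cytokine divergence between subjects' recovery trajectories, with the
## leave-one/two-out resampled comparison of intra- vs inter-group distance
## distributions.

#' Semi-metric distance between two time series
#'
#' Default `"envelope"` method: both series are linearly re-interpolated on
#' the union of their time grids restricted to the overlapping time span;
#' the distance is the mean absolute difference divided by the joint
#' envelope range (max minus min over both curves), giving a value in
#' `[0, 1]` that is 0 iff the curves coincide on the overlap, symmetric,
#' and tolerant of unequal lengths. `"dtw_norm"` is a normalized dynamic
#' time warping band-free alignment distance under the same contract.
#' Both are semi-metrics: the triangle inequality is not guaranteed.
#'
#' @param x,y lists with components `minutes` and `value` (or two-column
#'   matrices/data.frames), each of length >= 2.
#' @param method `"envelope"` (default) or `"dtw_norm"`.
#' @return distance in `[0, 1]`.
#' @export
series_distance <- function(x, y, method = c("envelope", "dtw_norm")) {
  method <- match.arg(method)
  x <- as_series(x); y <- as_series(y)
  if (length(x$minutes) < 2 || length(y$minutes) < 2) {
    stopf("series must have length >= 2")
  }
  if (method == "envelope") {
    lo <- max(min(x$minutes), min(y$minutes))
    hi <- min(max(x$minutes), max(y$minutes))
    if (hi <= lo) return(1)
    grid <- sort(unique(c(x$minutes[x$minutes >= lo & x$minutes <= hi],
                          y$minutes[y$minutes >= lo & y$minutes <= hi],
                          lo, hi)))
    xi <- stats::approx(x$minutes, x$value, xout = grid)$y
    yi <- stats::approx(y$minutes, y$value, xout = grid)$y
    env <- max(xi, yi) - min(xi, yi)
    if (env < 1e-12) return(0)
    mean(abs(xi - yi)) / env
  } else {
    dtw_norm_distance(x$value, y$value)
  }
}

as_series <- function(s) {
  if (is.list(s) && !is.null(s$minutes) && !is.null(s$value)) {
    list(minutes = as.numeric(s$minutes), value = as.numeric(s$value))
  } else {
    s <- as.matrix(s)
    list(minutes = as.numeric(s[, 1]), value = as.numeric(s[, 2]))
  }
}

## Plain DP dynamic time warping on values, normalized by path length and
## joint envelope range so the result lies in [0, 1].
dtw_norm_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  env <- max(a, b) - min(a, b)
  if (env < 1e-12) return(0)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- abs(a[i] - b[j])
      D[i + 1, j + 1] <- cost + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  (D[n + 1, m + 1] / (n + m)) / env
}

#' Resampled intra/inter-group distance distributions per cytokine
#'
#' Per repeat, draws `n_subsets` random subsets of `subset_size` subjects
#' without replacement from each group (with 11 subjects this is
#' leave-one-out, with 12 leave-two-out); within each paired subset all
#' intra-group pairwise distances (each group) and all cross-group pairwise
#' distances are accumulated. Defaults mirror the protocol: 11 subsets of
#' 10, repeated 11 times.
#'
#' @param series recovery-phase `uniform_series_set` for both groups.
#' @param subset_size subjects per subset.
#' @param n_subsets subsets per repeat.
#' @param n_repeats repeats.
#' @param method distance method, see [series_distance()].
#' @param seed integer seed.
#' @return named list per cytokine of `distance_distributions`: lists
#'   `intra_hc`, `intra_gwi`, `pooled_intra`, `inter` plus a `summary`
#'   data.frame (mean, SE, median, MADM per list).
#' @export
resampled_distance_distributions <- function(series, subset_size = 10,
                                             n_subsets = 11, n_repeats = 11,
                                             method = "envelope", seed = 1) {
  ids_hc <- unique(series$subject_id[series$group == "HC"])
  ids_gwi <- unique(series$subject_id[series$group == "GWI"])
  if (length(ids_hc) < subset_size || length(ids_gwi) < subset_size) {
    stopf("subset_size %d exceeds a group size (%d HC, %d GWI)",
          subset_size, length(ids_hc), length(ids_gwi))
  }
  cytokines <- sort(unique(series$cytokine))
  ## precompute unique pairwise distances once per cytokine
  all_ids <- c(ids_hc, ids_gwi)
  with_seed(seed, {
    res <- list()
    for (cyt in cytokines) {
      sub <- series[series$cytokine == cyt, , drop = FALSE]
      curves <- lapply(stats::setNames(all_ids, all_ids), function(id) {
        r <- sub[sub$subject_id == id, , drop = FALSE]
        list(minutes = r$minutes, value = r$value)
      })
      D <- matrix(0, length(all_ids), length(all_ids),
                  dimnames = list(all_ids, all_ids))
      for (i in seq_along(all_ids)) {
        for (j in seq_len(i - 1L)) {
          d <- series_distance(curves[[i]], curves[[j]], method = method)
          D[i, j] <- D[j, i] <- d
        }
      }
      intra_hc <- numeric(0); intra_gwi <- numeric(0); inter <- numeric(0)
      for (r in seq_len(n_repeats)) {
        for (s in seq_len(n_subsets)) {
          sub_hc <- sample(ids_hc, subset_size)
          sub_gwi <- sample(ids_gwi, subset_size)
          ut <- upper.tri(matrix(0, subset_size, subset_size))
          intra_hc <- c(intra_hc, D[sub_hc, sub_hc][ut])
          intra_gwi <- c(intra_gwi, D[sub_gwi, sub_gwi][ut])
          inter <- c(inter, as.vector(D[sub_hc, sub_gwi]))
        }
      }
      uhc <- D[ids_hc, ids_hc][upper.tri(diag(length(ids_hc)))]
      ugwi <- D[ids_gwi, ids_gwi][upper.tri(diag(length(ids_gwi)))]
      res[[cyt]] <- distance_distributions(
        cyt, intra_hc, intra_gwi, inter,
        unique_pairs = list(intra_hc = uhc, intra_gwi = ugwi,
                            inter = as.vector(D[ids_hc, ids_gwi]),
                            D = D, ids_hc = ids_hc, ids_gwi = ids_gwi))
    }
    res
  })
}

distance_distributions <- function(cytokine, intra_hc, intra_gwi, inter,
                                   unique_pairs = NULL) {
  pooled <- c(intra_hc, intra_gwi)
  summ <- function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
      median = stats::median(v), madm = stats::median(abs(v - stats::median(v))),
      n = length(v))
  }
  structure(list(
    cytokine = cytokine, intra_hc = intra_hc, intra_gwi = intra_gwi,
    pooled_intra = pooled, inter = inter, unique_pairs = unique_pairs,
    summary = as.data.frame(rbind(
      intra_hc = summ(intra_hc), intra_gwi = summ(intra_gwi),
      pooled_intra = summ(pooled), inter = summ(inter)))
  ), class = "distance_distributions")
}

#' @export
print.distance_distributions <- function(x, ...) {
  cat(sprintf("<distance_distributions> %s\n", x$cytokine))
  print(round(x$summary, 4))
  invisible(x)
}

#' Two-sample tests of inter- vs intra-group divergence
#'
#' Two-sided Student t and Wilcoxon rank-sum tests of the inter-group
#' distances against the pooled intra-group distances, plus the same tests
#' of HC-intra vs GWI-intra. When the distribution object carries the
#' unique subject-pair distances, the tests are computed on those: the
#' resampled lists repeat each underlying pair many times, which would
#' grossly overstate the effective sample size (the resampled lists remain
#' the summary-statistic distributions).
#'
#' Because the distances in each list share subjects, they are not
#' independent samples, and the large-sample null of the rank-sum test is
#' mis-calibrated on them. When the full subject-pair distance matrix is
#' available, the rank-sum statistic is therefore referred to its
#' subject-label permutation distribution (a Mantel-type test, exact under
#' exchangeability of subjects); otherwise the asymptotic test is used.
#'
#' @param dist a `distance_distributions` object.
#' @param n_perm number of subject-label permutations (used when the
#'   unique-pair matrix is stored).
#' @param perm_seed seed for the permutation draw (RNG state restored).
#' @return list with `t_p`, `ranksum_p`, `direction`
#'   (`"inter>intra"`/`"inter<intra"`), and `intra_t_p`, `intra_ranksum_p`,
#'   `intra_direction` for the within-group comparison.
#' @export
test_group_separation <- function(dist, n_perm = 400, perm_seed = 1) {
  cmp <- function(a, b, larger, smaller, w_p = NULL) {
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0)) {
      warnf("degenerate distance lists; p reported as 1")
      return(list(t_p = 1, w_p = 1,
                  direction = if (mean(a) >= mean(b)) larger else smaller))
    }
    t_p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    if (is.null(w_p)) {
      w_p <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    }
    list(t_p = t_p, w_p = w_p,
         direction = if (mean(a) >= mean(b)) larger else smaller)
  }
  u <- dist$unique_pairs
  if (!is.null(u) && !is.null(u$D)) {
    perm <- permuted_ranksum_p(u$D, u$ids_hc, u$ids_gwi, n_perm, perm_seed)
    main <- cmp(u$inter, c(u$intra_hc, u$intra_gwi),
                "inter>intra", "inter<intra", w_p = perm$inter_p)
    within <- cmp(u$intra_hc, u$intra_gwi, "hc>gwi", "hc<gwi",
                  w_p = perm$intra_p)
  } else if (!is.null(u)) {
    main <- cmp(u$inter, c(u$intra_hc, u$intra_gwi),
                "inter>intra", "inter<intra")
    within <- cmp(u$intra_hc, u$intra_gwi, "hc>gwi", "hc<gwi")
  } else {
    main <- cmp(dist$inter, dist$pooled_intra, "inter>intra", "inter<intra")
    within <- cmp(dist$intra_hc, dist$intra_gwi, "hc>gwi", "hc<gwi")
  }
  list(t_p = main$t_p, ranksum_p = main$w_p, direction = main$direction,
       intra_t_p = within$t_p, intra_ranksum_p = within$w_p,
       intra_direction = within$direction)
}

## Subject-label permutation reference for the rank-sum statistics.
## inter test: rank-sum of cross-group pair distances among all pairs;
## intra test: rank-sum of group-1 pairs among all within-group pairs.
permuted_ranksum_p <- function(D, ids_hc, ids_gwi, n_perm, perm_seed) {
  ids <- c(ids_hc, ids_gwi)
  n <- length(ids)
  n1 <- length(ids_hc)
  Dm <- D[ids, ids]
  ut <- which(upper.tri(Dm))
  rk_all <- rank(Dm[ut])                    # global pair ranks, fixed
  pair_i <- row(Dm)[ut]; pair_j <- col(Dm)[ut]
  stat_inter <- function(is_hc) {
    sum(rk_all[is_hc[pair_i] != is_hc[pair_j]])
  }
  stat_intra <- function(is_hc) {
    within <- is_hc[pair_i] == is_hc[pair_j]
    v <- Dm[ut][within]
    sum(rank(v)[is_hc[pair_i[within]]])
  }
  obs_hc <- c(rep(TRUE, n1), rep(FALSE, n - n1))
  t_inter <- stat_inter(obs_hc)
  t_intra <- stat_intra(obs_hc)
  with_seed(perm_seed, {
    perm_inter <- numeric(n_perm)
    perm_intra <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      lab <- rep(FALSE, n)
      lab[sample.int(n, n1)] <- TRUE
      perm_inter[b] <- stat_inter(lab)
      perm_intra[b] <- stat_intra(lab)
    }
    two_sided <- function(obs, ref) {
      ctr <- mean(ref)
      (1 + sum(abs(ref - ctr) >= abs(obs - ctr))) / (length(ref) + 1)
    }
    list(inter_p = two_sided(t_inter, perm_inter),
         intra_p = two_sided(t_intra, perm_intra))
  })
}

#' Per-cytokine divergence summary table
#'
#' @param dists output of [resampled_distance_distributions()].
#' @return data.frame, one row per cytokine: mean/SE/median/MADM of the
#'   pooled-intra and inter lists plus t and rank-sum p-values.
#' @export
divergence_table <- function(dists) {
  rows <- lapply(dists, function(d) {
    p <- suppressWarnings(test_group_separation(d))
    data.frame(
      cytokine = d$cytokine,
      intra_mean = d$summary["pooled_intra", "mean"],
      intra_se = d$summary["pooled_intra", "se"],
      inter_mean = d$summary["inter", "mean"],
      inter_se = d$summary["inter", "se"],
      inter_median = d$summary["inter", "median"],
      inter_madm = d$summary["inter", "madm"],
      t_p = p$t_p, ranksum_p = p$ranksum_p, direction = p$direction,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
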