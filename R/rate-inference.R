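## Per-subject inference of the signed directed network over the aggregate
## nodes: linear rate model dx/dt = A x fitted by partial least squares
## (NIPALS PLS2) with broken-stick retention of latent components, followed
## by relative-magnitude pruning of coefficients into discrete edges.

#' Inference configuration
#'
#' @param lambda broken-stick scale: components are retained while their
#'   explained predictor-variance fraction exceeds `lambda * b_k` (Horn-type
#'   thresholds; `lambda = 1` is the textbook broken stick; smaller values
#'   retain more components).
#' @param theta pruning threshold as a fraction of the largest off-diagonal
#'   coefficient magnitude, in `[0, 1)`.
#' @param standardize_predictors scale predictors to unit variance before
#'   the latent-variable fit (coefficients are back-transformed).
#' @param derivative_scheme finite-difference scheme; only `"central"`.
#' @return an `inference_config` list.
#' @export
inference_config <- function(lambda = 0.01, theta = 0.2,
                             standardize_predictors = TRUE,
                             derivative_scheme = "central") {
  stopifnot(is.finite(lambda), lambda > 0, is.finite(theta),
            theta >= 0, theta < 1)
  derivative_scheme <- match.arg(derivative_scheme, "central")
  structure(list(lambda = lambda, theta = theta,
                 standardize_predictors = standardize_predictors,
                 derivative_scheme = derivative_scheme),
            class = "inference_config")
}

#' Estimate time derivatives of aggregate scores
#'
#' Central differences at interior grid points, one-sided at the ends,
#' divided by the grid step (exact for series linear in time).
#'
#' @param scores node x time matrix, or an [aggregate_scores()] object.
#' @param step_minutes grid step; inferred from an `aggregate_scores` input.
#' @return node x time matrix of rates (per minute), aligned to the grid.
#' @export
estimate_derivatives <- function(scores, step_minutes = NULL) {
  if (inherits(scores, "aggregate_scores")) {
    step_minutes <- diff(scores$minutes[1:2])
    scores <- scores$scores
  }
  if (is.null(step_minutes)) stopf("step_minutes required for a bare matrix")
  m <- ncol(scores)
  if (m < 3) stopf("need at least 3 time points for derivative estimation")
  D <- matrix(0, nrow(scores), m, dimnames = dimnames(scores))
  D[, 1] <- (scores[, 2] - scores[, 1]) / step_minutes
  D[, m] <- (scores[, m] - scores[, m - 1]) / step_minutes
  D[, 2:(m - 1)] <- (scores[, 3:m] - scores[, 1:(m - 2)]) / (2 * step_minutes)
  D
}

#' Broken-stick selection of the number of latent components
#'
#' Thresholds are the expected fragment sizes of a unit stick broken into
#' `p` pieces, `b_k = (1/p) * sum_{i=k..p} 1/i`. The retained count K is
#' the longest prefix whose variance fractions all exceed `lambda * b_k`,
#' with a minimum of one component.
#'
#' @param variance_fractions non-increasing explained-variance fractions.
#' @param lambda threshold scale (> 0).
#' @param p stick length (defaults to the number of fractions supplied).
#' @return integer K >= 1.
#' @export
broken_stick_select <- function(variance_fractions, lambda = 1,
                                p = length(variance_fractions)) {
  if (length(variance_fractions) == 0) stopf("no variance fractions supplied")
  b <- broken_stick_thresholds(p)[seq_along(variance_fractions)]
  above <- variance_fractions > lambda * b
  K <- if (above[1]) {
    r <- rle(above)
    if (r$values[1]) r$lengths[1] else 0L
  } else 0L
  max(1L, as.integer(K))
}

#' @rdname broken_stick_select
#' @export
broken_stick_thresholds <- function(p) {
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

## NIPALS PLS2: X (n x p) predictors, Y (n x q) responses, both already
## centered (and X optionally scaled by caller). Returns per-component
## weights/loadings, regression coefficients for 1..ncomp components, and
## the fraction of X variance captured by each component.
pls2_nipals <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  ncomp <- min(ncomp, p, n - 1)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  ssx_total <- sum(X^2)
  xvar <- numeric(ncomp)
  Xk <- X; Yk <- Y
  for (k in seq_len(ncomp)) {
    u <- Yk[, which.max(colSums(Yk^2))]
    if (sum(u^2) < 1e-300) { ncomp <- k - 1L; break }
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xk, u); w <- w / sqrt(sum(w^2))
      tt <- Xk %*% w
      qv <- crossprod(Yk, tt); qv <- qv / sqrt(sum(qv^2))
      u <- Yk %*% qv
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    pv <- crossprod(Xk, tt) / sum(tt^2)
    cq <- crossprod(Yk, tt) / sum(tt^2)
    W[, k] <- w; P[, k] <- pv; Q[, k] <- cq; Tm[, k] <- tt
    xvar[k] <- sum((tt %*% t(pv))^2) / ssx_total
    Xk <- Xk - tt %*% t(pv)
    Yk <- Yk - tt %*% t(cq)
  }
  if (ncomp < 1) stopf("degenerate input: no usable latent component")
  coef_for <- function(K) {
    Wk <- W[, seq_len(K), drop = FALSE]
    Pk <- P[, seq_len(K), drop = FALSE]
    Qk <- Q[, seq_len(K), drop = FALSE]
    Wk %*% solve(crossprod(Pk, Wk), t(Qk))  # p x q
  }
  list(ncomp = ncomp, W = W[, seq_len(ncomp), drop = FALSE],
       P = P[, seq_len(ncomp), drop = FALSE],
       Q = Q[, seq_len(ncomp), drop = FALSE],
       scores = Tm[, seq_len(ncomp), drop = FALSE],
       xvar_fractions = xvar[seq_len(ncomp)], coef_for = coef_for)
}

#' Fit the dense rate matrix by latent-variable regression
#'
#' Regresses all node rates jointly on all node scores (one multivariate
#' PLS2 fit per subject), with the number of latent components chosen by
#' [broken_stick_select()] applied to the predictor-variance fractions, and
#' coefficients back-transformed to the original score scale into the rate
#' orientation: `A[i, j]` is the influence of source j on the rate of
#' target i.
#'
#' @param scores node x time score matrix.
#' @param rates node x time rate matrix (same grid).
#' @param config an [inference_config()].
#' @return list with dense `A`, retained components `K`, predictor-variance
#'   fractions, and centering/scaling used.
#' @export
fit_rate_matrix <- function(scores, rates, config = inference_config()) {
  stopifnot(ncol(scores) == ncol(rates), nrow(scores) == nrow(rates))
  nodes <- rownames(scores) %||% as.character(seq_len(nrow(scores)))
  X <- t(scores); Y <- t(rates)
  x_center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center)
  Yc <- sweep(Y, 2, y_center)
  x_scale <- rep(1, ncol(X))
  if (isTRUE(config$standardize_predictors)) {
    x_scale <- apply(Xc, 2, stats::sd)
    if (any(x_scale < 1e-12)) {
      stopf("zero-variance predictor node(s): %s",
            paste(nodes[x_scale < 1e-12], collapse = ", "))
    }
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  fit <- pls2_nipals(Xc, Yc, ncomp = ncol(Xc))
  K <- broken_stick_select(fit$xvar_fractions, lambda = config$lambda,
                           p = ncol(Xc))
  K <- min(K, fit$ncomp)
  B <- fit$coef_for(K)                       # p x q on standardized scale
  A <- t(sweep(B, 1, x_scale, "/"))          # rows = targets, cols = sources
  dimnames(A) <- list(nodes, nodes)
  list(A = A, K = K, xvar_fractions = fit$xvar_fractions,
       x_center = x_center, y_center = y_center, x_scale = x_scale)
}

#' Prune a dense coefficient matrix into a sparse signed network
#'
#' Off-diagonal entries smaller in magnitude than `theta` times the largest
#' off-diagonal magnitude are zeroed; the diagonal (self-degradation) is
#' preserved unchanged.
#'
#' @param A_dense square coefficient matrix.
#' @param theta relative threshold in `[0, 1)`.
#' @return pruned matrix.
#' @export
prune_to_network <- function(A_dense, theta = 0.1) {
  stopifnot(theta >= 0, theta < 1)
  off <- row(A_dense) != col(A_dense)
  mx <- max(abs(A_dense[off]))
  if (mx == 0) {
    warnf("all off-diagonal coefficients are zero; empty network")
    return(A_dense)
  }
  A <- A_dense
  A[off & abs(A_dense) < theta * mx] <- 0
  A
}

#' Fit a per-subject signed directed rate network
#'
#' The central model fit: estimates rates by finite differences, fits the
#' dense rate matrix by PLS with broken-stick retention, and prunes it to a
#' sparse signed network. Returns a classed object with the usual
#' accessors.
#'
#' @param scores an [aggregate_scores()] object (or node x time matrix).
#' @param minutes time grid when `scores` is a bare matrix.
#' @param config an [inference_config()].
#' @param rates optional precomputed node x time rate matrix (bypasses the
#'   finite-difference step; used for exact-derivative validation).
#' @return a `rate_network` object: fields `A` (pruned), `A_dense`, `K`,
#'   `xvar_fractions`, `config`, `nodes`, `scores`, `rates`, `fitted`,
#'   `subject_id`, `group`.
#' @export
fit_rate_network <- function(scores, minutes = NULL,
                             config = inference_config(), rates = NULL) {
  subject_id <- NA_character_; group <- NA_character_
  if (inherits(scores, "aggregate_scores")) {
    subject_id <- scores$subject_id; group <- scores$group
    minutes <- scores$minutes
    scores <- scores$scores
  }
  if (is.null(minutes)) stopf("minutes required for a bare score matrix")
  if (is.null(rates)) {
    rates <- estimate_derivatives(scores, step_minutes = diff(minutes[1:2]))
  }
  fit <- fit_rate_matrix(scores, rates, config)
  A <- prune_to_network(fit$A, theta = config$theta)
  fitted <- fit$A %*% sweep(scores, 1, fit$x_center) + fit$y_center
  structure(list(
    A = A, A_dense = fit$A, K = fit$K,
    xvar_fractions = fit$xvar_fractions,
    config = config, nodes = rownames(fit$A), minutes = minutes,
    scores = scores, rates = rates, fitted = fitted,
    subject_id = subject_id, group = group
  ), class = "rate_network")
}

#' @export
print.rate_network <- function(x, ...) {
  ne <- sum(x$A != 0 & row(x$A) != col(x$A))
  cat(sprintf(
    "<rate_network> %s%d nodes, %d edges (K = %d latent components)\n",
    if (!is.na(x$subject_id)) paste0(x$subject_id, ": ") else "",
    length(x$nodes), ne, x$K))
  invisible(x)
}

#' @export
summary.rate_network <- function(object, ...) {
  e <- adjacency_to_edges(object$A)
  cat(sprintf("Rate network for %s (%s)\n",
              object$subject_id, object$group))
  cat(sprintf("  latent components retained: %d (variance fractions %s)\n",
              object$K,
              paste(sprintf("%.3f", object$xvar_fractions), collapse = ", ")))
  cat(sprintf("  edges: %d (%d activating, %d inhibiting)\n",
              nrow(e), sum(e$sign > 0), sum(e$sign < 0)))
  rmse <- sqrt(mean((object$rates - object$fitted)^2))
  cat(sprintf("  rate-fit RMSE: %.4g per minute\n", rmse))
  invisible(object)
}

#' @export
coef.rate_network <- function(object, pruned = TRUE, ...) {
  if (pruned) object$A else object$A_dense
}

#' @export
residuals.rate_network <- function(object, ...) {
  object$rates - object$fitted
}

#' Predicted rates for new score trajectories
#' @param object a `rate_network`.
#' @param newdata node x time score matrix (default: training scores).
#' @param pruned use the pruned matrix (default the dense fit).
#' @param ... unused.
#' @export
predict.rate_network <- function(object, newdata = NULL, pruned = FALSE, ...) {
  S <- if (is.null(newdata)) object$scores else newdata
  A <- if (pruned) object$A else object$A_dense
  A %*% sweep(S, 1, rowMeans(object$scores)) +
    rowMeans(object$rates)
}

#' Simulate score trajectories from a fitted rate network
#' @param object a `rate_network`.
#' @param nsim number of trajectories (with `noise_sd > 0`).
#' @param seed integer seed.
#' @param x0 initial state (defaults to the first observed score column).
#' @param times time grid (defaults to the fit grid).
#' @param noise_sd process noise sd (0 = deterministic).
#' @param ... unused.
#' @return node x time matrix (or list of them when `nsim > 1`).
#' @export
simulate.rate_network <- function(object, nsim = 1, seed = 1, x0 = NULL,
                                  times = NULL, noise_sd = 0, ...) {
  if (is.null(x0)) x0 <- object$scores[, 1]
  if (is.null(times)) times <- object$minutes
  one <- function(k) {
    simulate_trajectory(object$A_dense, x0, basal = 0, times = times,
                        process_noise_sd = noise_sd,
                        seed = derive_seed(seed, k))
  }
  if (nsim == 1) one(1) else lapply(seq_len(nsim), one)
}

#' Plot a fitted rate network as a signed digraph
#' @param x a `rate_network`.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.rate_network <- function(x, ...) {
  e <- adjacency_to_edges(x$A)
  g <- igraph::graph_from_data_frame(
    e[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = x$nodes))
  igraph::E(g)$color <- ifelse(e$sign > 0, "forestgreen", "firebrick")
  igraph::E(g)$width <- 1 + 3 * e$weight / max(e$weight)
  igraph::plot.igraph(g, edge.arrow.size = 0.4, ...)
  invisible(x)
}

#' Edge recall, positive predictive value and F-score vs a reference
#'
#' A match is an edge with the same source, target and direction (and the
#' same sign when `sign_sensitive`); the diagonal is always excluded, as is
#' any ambiguous-sign reference edge under sign-sensitive matching.
#'
#' @param inferred,reference adjacency matrices (target rows, source
#'   columns), [signed_edges()] tables, or `rate_network` objects.
#' @param sign_sensitive require matching signs.
#' @return list `recall`, `ppv`, `f`, `n_matches`, `n_inferred`,
#'   `n_reference`, `empty_inferred` flag.
#' @export
edge_fscore <- function(inferred, reference, sign_sensitive = FALSE) {
  Ai <- as_adjacency_input(inferred)
  Ar <- as_adjacency_input(reference)
  if (!identical(dim(Ai), dim(Ar))) stopf("node sets differ")
  if (!is.null(rownames(Ai)) && !is.null(rownames(Ar)) &&
      !identical(rownames(Ai), rownames(Ar))) {
    stopf("node order differs between inferred and reference")
  }
  off <- row(Ai) != col(Ai)
  ei <- off & Ai != 0
  er <- off & Ar != 0
  matches <- if (sign_sensitive) {
    sum(ei & er & sign(Ai) == sign(Ar))
  } else sum(ei & er)
  n_inf <- sum(ei); n_ref <- sum(er)
  recall <- if (n_ref > 0) matches / n_ref else NA_real_
  ppv <- if (n_inf > 0) matches / n_inf else 0
  f <- if (is.na(recall) || recall + ppv == 0) 0 else
    2 * recall * ppv / (recall + ppv)
  list(recall = recall, ppv = ppv, f = f, n_matches = matches,
       n_inferred = n_inf, n_reference = n_ref,
       empty_inferred = n_inf == 0)
}

as_adjacency_input <- function(x) {
  if (inherits(x, "rate_network")) return(x$A)
  if (inherits(x, "signed_edges") || is.data.frame(x)) {
    return(edges_to_adjacency(x))
  }
  as.matrix(x)
}

#' Calibrate (lambda, theta) by constrained simulated annealing
#'
#' Maximizes the mean F-score of per-subject inferred networks against a
#' reference network over the box `lambda_bounds x theta_bounds`, using
#' geometric-cooling simulated annealing with Gaussian proposals reflected
#' at the box walls. The objective is deterministic per candidate;
#' the accepted-move sequence is reproducible from the seed.
#'
#' @param score_sets list of [aggregate_scores()] (training subjects).
#' @param reference reference network (matrix or [signed_edges()]).
#' @param lambda_bounds,theta_bounds numeric length-2 boxes.
#' @param sa_config list with `t0` (initial temperature), `cooling`
#'   (geometric factor), `iters`.
#' @param sign_sensitive score edge matches with signs.
#' @param seed integer seed.
#' @return list with `config` (best [inference_config()]), `f` (its mean
#'   F-score), and `trace` (data.frame of iteration, candidate, objective).
#' @export
calibrate_inference <- function(score_sets, reference,
                                lambda_bounds = c(1e-3, 0.1),
                                theta_bounds = c(0, 0.5),
                                sa_config = list(t0 = 0.1, cooling = 0.95,
                                                 iters = 200),
                                sign_sensitive = FALSE, seed = 1) {
  if (length(score_sets) < 1) stopf("need at least one training subject")
  if (diff(range(lambda_bounds)) < 0 || diff(range(theta_bounds)) < 0) {
    stopf("empty bounds")
  }
  Ar <- as_adjacency_input(reference)
  ## dense fits depend on lambda only; cache them per lambda value
  dense_cache <- new.env(parent = emptyenv())
  objective <- function(lambda, theta) {
    key <- sprintf("%.12g", lambda)
    fits <- if (!is.null(dense_cache[[key]])) dense_cache[[key]] else {
      f <- lapply(score_sets, function(sc) {
        fit_rate_network(sc, config = inference_config(
          lambda = lambda, theta = 0))$A_dense
      })
      dense_cache[[key]] <- f
      f
    }
    mean(vapply(fits, function(Ad) {
      edge_fscore(prune_to_network(Ad, theta), Ar,
                  sign_sensitive = sign_sensitive)$f
    }, numeric(1)))
  }
  with_seed(seed, {
    reflect <- function(v, lo, hi) {
      if (hi == lo) return(lo)
      span <- hi - lo
      v <- (v - lo) %% (2 * span)
      lo + ifelse(v > span, 2 * span - v, v)
    }
    cur <- c(mean(lambda_bounds), mean(theta_bounds))
    cur_f <- objective(cur[1], cur[2])
    best <- cur; best_f <- cur_f
    temp <- sa_config$t0
    step <- c(diff(range(lambda_bounds)), diff(range(theta_bounds))) / 6
    trace <- vector("list", sa_config$iters)
    for (it in seq_len(sa_config$iters)) {
      cand <- c(reflect(cur[1] + stats::rnorm(1, 0, step[1] + 1e-12),
                        lambda_bounds[1], lambda_bounds[2]),
                reflect(cur[2] + stats::rnorm(1, 0, step[2] + 1e-12),
                        theta_bounds[1], theta_bounds[2]))
      cand_f <- objective(cand[1], cand[2])
      accept <- cand_f >= cur_f ||
        stats::runif(1) < exp((cand_f - cur_f) / temp)
      if (accept) { cur <- cand; cur_f <- cand_f }
      if (cand_f > best_f) { best <- cand; best_f <- cand_f }
      trace[[it]] <- data.frame(iter = it, lambda = cand[1],
                                theta = cand[2], f = cand_f,
                                accepted = accept)
      temp <- temp * sa_config$cooling
    }
    list(config = inference_config(lambda = best[1], theta = best[2]),
         f = best_f, trace = do.call(rbind, trace))
  })
}
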