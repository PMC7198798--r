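test_that("finite-difference rates are exact for polynomials", {
  t <- seq(0, 30, 3)
  ## linear: slope 2 per 3-min step = 2/3 per minute everywhere
  S <- rbind(a = 2 * seq_along(t), b = rep(5, length(t)))
  D <- estimate_derivatives(S, step_minutes = 3)
  expect_near(D["a", ], 2 / 3)
  expect_near(D["b", ], 0)
  ## quadratic: central differences are exact in the interior
  S2 <- rbind(q = t^2)
  D2 <- estimate_derivatives(S2, step_minutes = 3)
  expect_near(D2[1, 2:(length(t) - 1)], 2 * t[2:(length(t) - 1)])
  expect_error(estimate_derivatives(S[, 1:2, drop = FALSE], 3), "at least 3")
})

test_that("broken-stick selection matches the closed-form thresholds", {
  ## worked example: p = 4, lambda = 1
  b4 <- sapply(1:4, function(k) sum(1 / (k:4)) / 4)
  expect_near(broken_stick_thresholds(4), b4)
  expect_near(b4, c(0.520833, 0.270833, 0.145833, 0.0625), tol = 1e-6)
  expect_equal(broken_stick_select(c(0.6, 0.25, 0.1, 0.05), lambda = 1), 1L)
  expect_equal(broken_stick_select(c(0.97, 0.03), lambda = 1), 1L)
  ## lambda -> 0 retains everything
  expect_equal(broken_stick_select(c(0.6, 0.25, 0.1, 0.05), lambda = 1e-12),
               4L)
  ## exhaustive oracle over p <= 20 and a lambda grid
  for (p in c(2, 5, 9, 13, 20)) {
    b <- sapply(seq_len(p), function(k) sum(1 / (k:p)) / p)
    expect_near(broken_stick_thresholds(p), b)
    set.seed(p)
    fr <- sort(prop.table(runif(p) + 0.05), decreasing = TRUE)
    for (lam in c(0.01, 0.25, 1, 2, 4)) {
      above <- fr > lam * b
      K_oracle <- if (!above[1]) 1L else {
        r <- rle(above); as.integer(r$lengths[1])
      }
      expect_equal(broken_stick_select(fr, lambda = lam), max(1L, K_oracle))
    }
  }
  expect_error(broken_stick_select(numeric(0)), "no variance")
})

test_that("the latent-variable fit equals least squares in the full-rank limit", {
  set.seed(8)
  S <- matrix(rnorm(9 * 40), 9, 40,
              dimnames = list(AGGREGATE_NODES, NULL))
  A <- matrix(rnorm(81, sd = 0.3), 9, 9)
  R <- A %*% S + matrix(rnorm(9 * 40, sd = 0.01), 9, 40)
  fit <- fit_rate_matrix(S, R, inference_config(lambda = 1e-12))
  expect_equal(fit$K, 9L)
  ## independent oracle: ordinary multivariate least squares
  B <- t(stats::coef(stats::lm(t(R) ~ t(S)))[-1, ])
  expect_near(fit$A, B, tol = 1e-6)
})

test_that("noiseless trajectories recover the generating network", {
  A <- sample_group_network(seed = 41)
  ## exact-discretization data with exact derivatives supplied
  set.seed(2)
  x0 <- rnorm(9, 0.5, 0.3)
  M <- as.matrix(Matrix::expm(A * 3))
  S <- matrix(0, 9, 81, dimnames = list(AGGREGATE_NODES, NULL))
  S[, 1] <- x0
  for (k in 2:81) S[, k] <- M %*% S[, k - 1]
  R <- A %*% S
  fit <- fit_rate_matrix(S, R, inference_config(lambda = 1e-6))
  expect_lt(max(abs(fit$A - A)), 0.05)
  ## full route (simulated states, finite-difference rates, pruning)
  m <- ground_truth_model(A_true = A)
  sc <- simulate_score_cohort(m, n_subjects = 2, seed = 77)
  for (i in 1:2) {
    net <- fit_rate_network(sc$scores[[i]])
    fs <- edge_fscore(net, sc$networks[[i]])
    expect_gt(fs$f, 0.7)
  }
  ## Eq-1 orientation survives end-to-end: predicted rates from the dense
  ## fit match the fitted values (residual check against transposition)
  net <- fit_rate_network(sc$scores[[1]])
  expect_near(predict(net), net$fitted, tol = 1e-9)
  expect_lt(sqrt(mean(residuals(net)^2)), 0.05 * sd(net$rates))
})

test_that("only driving nodes earn columns; node order is equivariant", {
  ## one active source: x1 drives x2; all other nodes quiescent noise
  set.seed(4)
  t <- seq(0, 240, 3)
  S <- matrix(rnorm(9 * 81, sd = 1e-3), 9, 81,
              dimnames = list(AGGREGATE_NODES, NULL))
  S[1, ] <- sin(t / 20)
  S[2, ] <- cos(t / 20)
  R <- matrix(0, 9, 81, dimnames = dimnames(S))
  R[2, ] <- 0.5 * S[1, ]                 # only MK1A influences MK1B's rate
  fit <- fit_rate_matrix(S, R, inference_config(lambda = 0.01))
  expect_gt(abs(fit$A[2, 1]), 10 * max(abs(fit$A[-2, ])))
  ## permuting node order permutes the fitted matrix consistently
  perm <- c(3, 1, 2, 9, 4:8)
  fit_p <- fit_rate_matrix(S[perm, ], R[perm, ], inference_config(lambda = 0.01))
  expect_near(fit_p$A, fit$A[perm, perm], tol = 1e-8)
  ## zero-variance predictors are rejected
  S0 <- S; S0[5, ] <- 1
  expect_error(fit_rate_matrix(S0, R, inference_config()), "zero-variance")
})

test_that("pruning thresholds relative to the strongest interaction", {
  A <- toy_adjacency(list(list("MK1A", "MK1B", 1), list("MK1B", "MK1A", 0.4)),
                     nodes = c("MK1A", "MK1B"))
  expect_equal(prune_to_network(A, 0), A)
  P <- prune_to_network(A, 0.5)
  expect_equal(P["MK1B", "MK1A"], 1)
  expect_equal(P["MK1A", "MK1B"], 0)
  P99 <- prune_to_network(A, 0.999)
  expect_equal(sum(P99 != 0), 1)
  expect_warning(prune_to_network(matrix(0, 3, 3), 0.1), "empty")
})

test_that("edge scores follow set arithmetic and the counting identity", {
  ref <- random_signed_matrix(9, 0.4, seed = 6)
  expect_equal(edge_fscore(ref, ref),
               list(recall = 1, ppv = 1, f = 1,
                    n_matches = sum(ref != 0), n_inferred = sum(ref != 0),
                    n_reference = sum(ref != 0), empty_inferred = FALSE))
  ## half of the reference, nothing else
  idx <- which(ref != 0)
  half <- ref; half[idx[seq(1, length(idx), 2)]] <- 0
  fs <- edge_fscore(half, ref)
  expect_equal(fs$ppv, 1)
  expect_equal(fs$recall, sum(half != 0) / sum(ref != 0))
  expect_equal(fs$f, 2 * fs$recall / (1 + fs$recall))
  ## disjoint sets
  disj <- ref * 0; disj[1, 2] <- ifelse(ref[1, 2] == 0, 1, 0)
  if (sum(disj) > 0) expect_equal(edge_fscore(disj, ref)$f, 0)
  ## counting identity on random pairs, sign-sensitive and not
  for (s in 1:5) {
    a <- random_signed_matrix(9, 0.3, seed = 100 + s)
    b <- random_signed_matrix(9, 0.3, seed = 200 + s)
    for (ss in c(TRUE, FALSE)) {
      fs <- edge_fscore(a, b, sign_sensitive = ss)
      expect_equal(fs$recall * fs$n_reference, fs$n_matches)
      expect_equal(fs$ppv * fs$n_inferred, fs$n_matches)
    }
  }
  ## empty inferred network reports ppv 0 with the flag
  fs0 <- edge_fscore(ref * 0, ref)
  expect_true(fs0$empty_inferred)
  expect_equal(fs0$ppv, 0)
})

test_that("annealing calibration finds the optimum and is reproducible", {
  m <- ground_truth_model(seed = 55)
  sc <- simulate_score_cohort(m, n_subjects = 2, seed = 3)
  ## collapsed bounds return that point
  cal0 <- calibrate_inference(sc$scores, m$A_true,
                              lambda_bounds = c(0.01, 0.01),
                              theta_bounds = c(0.2, 0.2),
                              sa_config = list(t0 = 0.05, cooling = 0.9,
                                               iters = 5), seed = 1)
  expect_equal(cal0$config$lambda, 0.01)
  expect_equal(cal0$config$theta, 0.2)
  ## SA at least matches an exhaustive grid on the same candidates
  cal <- calibrate_inference(sc$scores, m$A_true,
                             lambda_bounds = c(1e-3, 0.1),
                             theta_bounds = c(0.05, 0.4),
                             sa_config = list(t0 = 0.05, cooling = 0.9,
                                              iters = 30), seed = 2)
  grid_f <- sapply(c(1e-3, 0.01, 0.1), function(lam) {
    mean(sapply(sc$scores, function(s) {
      edge_fscore(fit_rate_network(s, config = inference_config(
        lambda = lam, theta = 0.2)), m$A_true)$f
    }))
  })
  expect_gte(cal$f, max(grid_f) - 0.05)
  ## deterministic under the seed
  cal2 <- calibrate_inference(sc$scores, m$A_true,
                              lambda_bounds = c(1e-3, 0.1),
                              theta_bounds = c(0.05, 0.4),
                              sa_config = list(t0 = 0.05, cooling = 0.9,
                                               iters = 30), seed = 2)
  expect_identical(cal$trace, cal2$trace)
  expect_error(calibrate_inference(list(), m$A_true), "at least one")
})

test_that("model methods print, summarize, and simulate coherently", {
  m <- ground_truth_model(seed = 20)
  sc <- simulate_score_cohort(m, n_subjects = 1, seed = 5)
  net <- fit_rate_network(sc$scores[[1]])
  expect_output(print(net), "rate_network")
  expect_output(summary(net), "latent components")
  expect_identical(coef(net), net$A)
  expect_identical(coef(net, pruned = FALSE), net$A_dense)
  tr <- simulate(net, times = seq(0, 30, 3))
  expect_equal(dim(tr), c(9, 11))
  expect_equal(tr[, 1], net$scores[, 1])
})
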