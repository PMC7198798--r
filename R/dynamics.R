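## Qualitative discrete-state circuit simulation: fuzzy-logic target-state
## resolution (max-OR over activators, AND-NOT of the inhibitor envelope),
## sigmoidal incremental transitions with per-node time constants sampled
## from a truncated Gaussian, and ensemble traces for paired comparison of
## original, healthy and blockade-edited circuits.

#' Simulation parameters for the qualitative dynamics engine
#'
#' @param steepness logistic reshaping steepness (centered at 0.5).
#' @param tau_mean,tau_sd mean and sd (in steps) of the per-node time
#'   constants, sampled truncated-positive Gaussian per run.
#' @param dt integration step (state units per step).
#' @param horizon number of steps.
#' @param n_runs ensemble size.
#' @param basal per-node resting level in `[0, 1]` (recycled).
#' @param seed integer seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(steepness = 8, tau_mean = 10, tau_sd = 2,
                              dt = 1, horizon = 100, n_runs = 100,
                              basal = 0.2, seed = 1) {
  stopifnot(steepness > 0, tau_mean > 0, tau_sd >= 0, dt > 0, horizon >= 0,
            n_runs >= 1, all(basal >= 0 & basal <= 1))
  structure(list(steepness = steepness, tau_mean = tau_mean,
                 tau_sd = tau_sd, dt = dt, horizon = horizon,
                 n_runs = n_runs, basal = basal, seed = seed),
            class = "simulation_params")
}

logistic_shape <- function(u, s) 1 / (1 + exp(-s * (u - 0.5)))

#' Resolve the fuzzy-logic target state of one node
#'
#' Activation is the fuzzy OR (maximum) over activators of
#' `normalized |weight| x state`; inhibition likewise over inhibitors. A
#' node with no activators rests at `basal`; otherwise the target is
#' `activation * (1 - inhibition)` (fuzzy AND-NOT).
#'
#' @param states node states in `[0, 1]`.
#' @param A signed adjacency matrix (target rows, source columns); weights
#'   are normalized by the largest off-diagonal magnitude.
#' @param node node name or index.
#' @param basal resting level for unregulated nodes.
#' @return target state in `[0, 1]`.
#' @export
resolve_target_state <- function(states, A, node, basal = 0.2) {
  A <- as_adjacency_input(A)
  i <- if (is.character(node)) match(node, rownames(A)) else as.integer(node)
  if (is.na(i)) stopf("unknown node: %s", node)
  off <- row(A) != col(A)
  if (!any(off) || max(abs(A[off])) == 0) return(basal)
  mx <- max(abs(A[off]))
  w <- A[i, ] / mx
  w[i] <- 0
  act <- which(w > 0); inh <- which(w < 0)
  if (length(act) == 0) return(basal)
  a <- max(w[act] * states[act])
  h <- if (length(inh) > 0) max(-w[inh] * states[inh]) else 0
  min(1, max(0, a * (1 - h)))
}

#' Advance all node states one step
#'
#' Each node moves a fraction `dt / tau_i` of the way from its current
#' state toward the logistic reshaping of its fuzzy target,
#' `x_i <- x_i + (dt / tau_i) (sigma_s(target_i) - x_i)`, clamped to
#' `[0, 1]`.
#'
#' @param states current state vector in `[0, 1]`.
#' @param A signed adjacency matrix.
#' @param params a [simulation_params()].
#' @param tau per-node time constants (> 0).
#' @return next state vector.
#' @export
advance_state <- function(states, A, params, tau) {
  if (any(tau <= 0)) stopf("time constants must be positive")
  basal <- rep_len(params$basal, length(states))
  targets <- vapply(seq_along(states), function(i) {
    resolve_target_state(states, A, i, basal = basal[i])
  }, numeric(1))
  x <- states + (params$dt / tau) * (logistic_shape(targets, params$steepness) - states)
  pmin(1, pmax(0, x))
}

#' Simulate an ensemble of qualitative trajectories
#'
#' Runs `n_runs` trajectories from `x0` with per-run time constants drawn
#' from a truncated-positive Gaussian; the per-run draws can be supplied
#' explicitly (`tau_matrix`) so different circuits are simulated under
#' identical sampled parameters for paired comparison.
#'
#' @param A signed adjacency matrix.
#' @param x0 initial states in `[0, 1]` (the peak-effort state vector).
#' @param params a [simulation_params()].
#' @param tau_matrix optional n_runs x n_nodes matrix of time constants.
#' @param scenario label carried in the result.
#' @return a `simulation_trace`: `mean` and `sd` node x (horizon + 1)
#'   matrices, the per-run array `runs`, the `tau_matrix` used, `scenario`.
#' @export
simulate_ensemble <- function(A, x0, params = simulation_params(),
                              tau_matrix = NULL, scenario = "source") {
  A <- as_adjacency_input(A)
  n <- nrow(A)
  stopifnot(length(x0) == n, all(x0 >= 0 & x0 <= 1))
  if (is.null(tau_matrix)) {
    tau_matrix <- draw_tau_matrix(params, n)
  }
  stopifnot(nrow(tau_matrix) == params$n_runs, ncol(tau_matrix) == n)
  runs <- array(0, dim = c(n, params$horizon + 1, params$n_runs),
                dimnames = list(rownames(A), NULL, NULL))
  for (r in seq_len(params$n_runs)) {
    x <- x0
    runs[, 1, r] <- x
    for (k in seq_len(params$horizon)) {
      x <- advance_state(x, A, params, tau_matrix[r, ])
      runs[, k + 1, r] <- x
    }
  }
  structure(list(
    mean = apply(runs, c(1, 2), mean),
    sd = apply(runs, c(1, 2), stats::sd),
    runs = runs, tau_matrix = tau_matrix, scenario = scenario,
    params = params
  ), class = "simulation_trace")
}

draw_tau_matrix <- function(params, n) {
  with_seed(params$seed, {
    M <- matrix(stats::rnorm(params$n_runs * n, params$tau_mean,
                             params$tau_sd), params$n_runs, n)
    while (any(M <= 0)) {       # truncated-positive Gaussian by resampling
      bad <- M <= 0
      M[bad] <- stats::rnorm(sum(bad), params$tau_mean, params$tau_sd)
    }
    M
  })
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("<simulation_trace> %s: %d nodes x %d steps x %d runs\n",
              x$scenario, nrow(x$mean), ncol(x$mean) - 1,
              dim(x$runs)[3]))
  invisible(x)
}

#' Simulate source, target and treated circuits under shared parameters
#'
#' Draws one set of per-run time constants and runs every circuit under it,
#' so scenario differences reflect topology alone.
#'
#' @param circuits named list of adjacency matrices (e.g. `source`,
#'   `target`, `treated`).
#' @param x0 shared initial state vector.
#' @param params a [simulation_params()].
#' @return named list of `simulation_trace` objects.
#' @export
simulate_scenarios <- function(circuits, x0, params = simulation_params()) {
  n <- nrow(as_adjacency_input(circuits[[1]]))
  tau <- draw_tau_matrix(params, n)
  out <- lapply(names(circuits), function(nm) {
    simulate_ensemble(circuits[[nm]], x0, params, tau_matrix = tau,
                      scenario = nm)
  })
  stats::setNames(out, names(circuits))
}

#' Per-node rescue score of a treated circuit
#'
#' `r = 1 - RMS(treated - target) / RMS(source - target)` over ensemble
#' mean traces: 1 is a perfect rescue (treated matches the healthy
#' target), 0 no change from the untreated source, negative a worsening.
#' A source already matching the target (denominator below `eps`) reports 0
#' with a flag.
#'
#' @param source_trace,target_trace,treated_trace `simulation_trace`
#'   objects (or mean matrices) with aligned horizons.
#' @param eps degenerate-denominator guard.
#' @return data.frame: `node`, `rescue`, `degenerate`.
#' @export
rescue_score <- function(source_trace, target_trace, treated_trace,
                         eps = 1e-9) {
  m <- function(x) if (inherits(x, "simulation_trace")) x$mean else as.matrix(x)
  S <- m(source_trace); Tg <- m(target_trace); Tr <- m(treated_trace)
  if (!identical(dim(S), dim(Tg)) || !identical(dim(S), dim(Tr))) {
    stopf("trace shapes differ")
  }
  rms <- function(M) sqrt(rowMeans(M^2))
  denom <- rms(S - Tg)
  num <- rms(Tr - Tg)
  degenerate <- denom < eps
  r <- ifelse(degenerate, 0, 1 - num / denom)
  data.frame(node = rownames(S) %||% as.character(seq_len(nrow(S))),
             rescue = unname(r), degenerate = unname(degenerate),
             stringsAsFactors = FALSE)
}
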