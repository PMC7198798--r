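## Config-driven end-to-end orchestration: cohort (synthetic or file) ->
## preprocessing -> divergence -> aggregation -> per-subject inference ->
## consensus -> topological comparison -> blockade search -> qualitative
## dynamics, under one master seed, returning a structured report.

#' Pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it by a fixed counter scheme.
#' @param panel_path optional path to a panel file; when NULL a synthetic
#'   cohort is generated from `cohort_spec`.
#' @param cohort_spec a [synthetic_cohort_spec()] (defaults to one built
#'   from the master seed).
#' @param exclude_subjects subject ids dropped before preprocessing.
#' @param step_minutes,window_minutes preprocessing grid and window.
#' @param divergence_subset_size,divergence_n_subsets,divergence_n_repeats
#'   resampling scheme for the divergence stage.
#' @param calibrate run simulated-annealing calibration of (lambda, theta)
#'   against the reference network before inference (slower); otherwise
#'   `inference` is used as-is.
#' @param inference an [inference_config()].
#' @param consensus_subset_size,consensus_n_subsamples,consensus_quorum
#'   consensus-stage sizes.
#' @param intervention_max_combo largest blockade set (default 2).
#' @param dynamics a [simulation_params()].
#' @param reference reference network edge table (defaults to the packaged
#'   synthetic stand-in, [reference_network()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, panel_path = NULL, cohort_spec = NULL,
                            exclude_subjects = character(),
                            step_minutes = 3, window_minutes = 240,
                            divergence_subset_size = 10,
                            divergence_n_subsets = 11,
                            divergence_n_repeats = 11,
                            calibrate = FALSE,
                            inference = inference_config(),
                            consensus_subset_size = 10,
                            consensus_n_subsamples = 100,
                            consensus_quorum = 6,
                            intervention_max_combo = 2,
                            dynamics = simulation_params(),
                            reference = NULL) {
  if (!is.null(panel_path) && !file.exists(panel_path)) {
    stopf("panel file not found: %s", panel_path)
  }
  if (is.null(cohort_spec) && is.null(panel_path)) {
    cohort_spec <- synthetic_cohort_spec(seed = derive_seed(seed, 1))
  }
  structure(list(
    seed = seed, panel_path = panel_path, cohort_spec = cohort_spec,
    exclude_subjects = exclude_subjects, step_minutes = step_minutes,
    window_minutes = window_minutes,
    divergence_subset_size = divergence_subset_size,
    divergence_n_subsets = divergence_n_subsets,
    divergence_n_repeats = divergence_n_repeats,
    calibrate = calibrate, inference = inference,
    consensus_subset_size = consensus_subset_size,
    consensus_n_subsamples = consensus_n_subsamples,
    consensus_quorum = consensus_quorum,
    intervention_max_combo = intervention_max_combo,
    dynamics = dynamics, reference = reference
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in protocol order and returns a report list with
#' eight sections: `cohort`, `divergence`, `aggregation`, `inference`,
#' `consensus`, `comparison`, `intervention`, `dynamics`. Deterministic
#' given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  ## -- cohort ----------------------------------------------------------
  truth <- NULL
  panel <- stage("cohort", {
    if (!is.null(config$panel_path)) {
      read_panel(config$panel_path)
    } else {
      cohort <- emit_cohort(config$cohort_spec)
      truth <- cohort$truth
      cohort$panel
    }
  })
  n_per_group <- table(unique(panel[c("subject_id", "group")])$group)
  if (min(n_per_group) - length(config$exclude_subjects) <
      config$consensus_subset_size) {
    stopf("consensus subset_size %d exceeds smallest group size %d",
          config$consensus_subset_size, min(n_per_group))
  }
  ## -- preprocess ------------------------------------------------------
  series <- stage("preprocess", preprocess_panel(
    panel, exclude_subjects = config$exclude_subjects,
    step_minutes = config$step_minutes,
    window_minutes = config$window_minutes))
  ## -- divergence ------------------------------------------------------
  divergence <- stage("divergence", {
    dists <- resampled_distance_distributions(
      series, subset_size = config$divergence_subset_size,
      n_subsets = config$divergence_n_subsets,
      n_repeats = config$divergence_n_repeats,
      seed = derive_seed(config$seed, 2))
    divergence_table(dists)
  })
  ## -- aggregation -----------------------------------------------------
  model <- stage("aggregate", fit_pooled_pca(series))
  scores <- stage("aggregate", score_aggregates(series, model))
  variance_table <- do.call(rbind, lapply(names(model$sets), function(bn) {
    s <- model$sets[[bn]]
    data.frame(set = bn,
               constituents = paste(s$cytokines, collapse = ","),
               pc1_fraction = s$var_fractions[1],
               pc2_fraction = if (length(s$var_fractions) > 1)
                 s$var_fractions[2] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ## -- inference -------------------------------------------------------
  reference <- config$reference %||% reference_network()
  ref_adj <- edges_to_adjacency(reference)
  inf_cfg <- config$inference
  calibration <- NULL
  if (isTRUE(config$calibrate)) {
    calibration <- stage("calibrate", calibrate_inference(
      scores, ref_adj, seed = derive_seed(config$seed, 3)))
    inf_cfg <- calibration$config
  }
  fits <- stage("infer", lapply(scores, fit_rate_network, config = inf_cfg))
  nets <- lapply(fits, `[[`, "A")
  groups <- vapply(fits, `[[`, character(1), "group")
  ## -- consensus -------------------------------------------------------
  ens <- stage("consensus", {
    lapply(stats::setNames(c("HC", "GWI"), c("HC", "GWI")), function(g) {
      consensus_ensemble(nets[groups == g],
                         subset_size = config$consensus_subset_size,
                         n_subsamples = config$consensus_n_subsamples,
                         quorum = config$consensus_quorum,
                         seed = derive_seed(config$seed, 4), group = g)
    })
  })
  concordance <- stage("consensus", {
    lapply(ens, function(e) {
      rbind(
        ensemble_concordance(nets[groups == e$group], ref_adj)[1, ] |>
          transform(level = "subject"),
        ensemble_concordance(e, ref_adj))
    })
  })
  ## -- comparison ------------------------------------------------------
  comparison <- stage("compare", {
    ged <- ged_significance(ens$HC, ens$GWI,
                            seed = derive_seed(config$seed, 5))
    list(
      ged = ged,
      centrality_medians = lapply(ens, ensemble_centrality_medians),
      motifs = lapply(ens, function(e) classify_ffls(e$characteristic)),
      feedback = lapply(ens, function(e)
        find_feedback_loops(e$characteristic)))
  })
  ## -- intervention ----------------------------------------------------
  intervention <- stage("intervene", rank_blockades(
    ens$GWI$characteristic, ens$HC$characteristic,
    max_combo = config$intervention_max_combo))
  ## -- dynamics --------------------------------------------------------
  dynamics <- stage("dynamics", {
    best <- intervention$blocked[intervention$n_blocked > 0][1]
    blocked_nodes <- strsplit(best, ",")[[1]]
    src <- ens$GWI$characteristic
    tgt <- ens$HC$characteristic
    params <- config$dynamics
    params$seed <- derive_seed(config$seed, 6)
    x0 <- rep(0.9, nrow(src))    # peak-effort elevation
    traces <- simulate_scenarios(
      list(source = src, target = tgt,
           treated = apply_blockade(src, blocked_nodes)),
      x0 = x0, params = params)
    list(blocked = blocked_nodes, traces = traces,
         rescue = rescue_score(traces$source, traces$target,
                               traces$treated))
  })
  structure(list(
    cohort = list(n_hc = unname(n_per_group["HC"]),
                  n_gwi = unname(n_per_group["GWI"]),
                  n_records = nrow(panel), truth = truth,
                  excluded = config$exclude_subjects),
    divergence = divergence,
    aggregation = list(variance_table = variance_table,
                       node_names = model$node_names),
    inference = list(config = inf_cfg, calibration = calibration,
                     networks = nets, groups = groups),
    consensus = list(ensembles = ens, concordance = concordance),
    comparison = comparison,
    intervention = intervention,
    dynamics = dynamics,
    config = config
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  cohort: %d HC + %d GWI subjects, %d records\n",
              x$cohort$n_hc, x$cohort$n_gwi, x$cohort$n_records))
  cat(sprintf("  divergence: %d cytokines, %d with ranksum p < 0.05\n",
              nrow(x$divergence), sum(x$divergence$ranksum_p < 0.05)))
  ged <- x$comparison$ged
  cat(sprintf("  GED inter %.4f vs pooled intra %.4f (ranksum p %.3g)\n",
              mean(ged$inter), mean(ged$pooled_intra),
              ged$inter_p[["ranksum_p"]]))
  ce <- function(e) sum(e$characteristic != 0)
  cat(sprintf("  characteristic edges: HC %d, GWI %d\n",
              ce(x$consensus$ensembles$HC), ce(x$consensus$ensembles$GWI)))
  best <- x$intervention[x$intervention$n_blocked > 0, ][1, ]
  cat(sprintf("  best blockade: {%s} GED %.4f (%.1f%% reduction)\n",
              best$blocked, best$ged_mean, best$pct_reduction))
  invisible(x)
}

#' Serialize a pipeline report
#'
#' JSON keeps the numeric tables (6 significant digits); markdown renders
#' one table per section.
#'
#' @param report a `pipeline_report`.
#' @param path output file.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  sections <- report_sections(report)
  if (format == "json") {
    jsonlite::write_json(sections, path, auto_unbox = TRUE, digits = 6,
                         pretty = TRUE, na = "null")
  } else {
    lines <- character(0)
    for (nm in names(sections)) {
      lines <- c(lines, sprintf("## %s", nm), "")
      sec <- sections[[nm]]
      if (is.data.frame(sec)) {
        lines <- c(lines, md_table(sec), "")
      } else {
        for (sub in names(sec)) {
          lines <- c(lines, sprintf("### %s", sub), "")
          v <- sec[[sub]]
          if (is.data.frame(v)) lines <- c(lines, md_table(v), "")
          else lines <- c(lines, paste0("- ", sub, ": ",
                                        paste(format(v, digits = 6),
                                              collapse = ", ")), "")
        }
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}

report_sections <- function(report) {
  ens <- report$consensus$ensembles
  char_edges <- function(e) nrow(adjacency_to_edges(e$characteristic))
  ged <- report$comparison$ged
  list(
    cohort = data.frame(n_hc = report$cohort$n_hc,
                        n_gwi = report$cohort$n_gwi,
                        n_records = report$cohort$n_records),
    divergence = report$divergence,
    aggregation = report$aggregation$variance_table,
    inference = data.frame(
      lambda = report$inference$config$lambda,
      theta = report$inference$config$theta,
      n_networks = length(report$inference$networks)),
    consensus = data.frame(
      group = c("HC", "GWI"),
      characteristic_edges = c(char_edges(ens$HC), char_edges(ens$GWI)),
      median_consensus_edges = vapply(ens, function(e) {
        stats::median(vapply(e$consensus_networks,
                             function(A) sum(A != 0), numeric(1)))
      }, numeric(1))),
    concordance = do.call(rbind, lapply(names(report$consensus$concordance),
      function(g) transform(report$consensus$concordance[[g]], group = g))),
    comparison = list(
      ged = data.frame(
        inter_mean = mean(ged$inter),
        pooled_intra_mean = mean(ged$pooled_intra),
        inter_t_p = unname(ged$inter_p[["t_p"]]),
        inter_ranksum_p = unname(ged$inter_p[["ranksum_p"]]),
        intra_ranksum_p = unname(ged$intra_p[["ranksum_p"]])),
      motifs = do.call(rbind, lapply(names(report$comparison$motifs),
        function(g) {
          m <- report$comparison$motifs[[g]]
          if (nrow(m) == 0) cbind(m, group = character(0))
          else transform(m, group = g)
        }))),
    intervention = utils::head(as.data.frame(report$intervention), 10),
    dynamics = report$dynamics$rescue
  )
}

md_table <- function(df) {
  df <- as.data.frame(lapply(df, function(c) {
    if (is.numeric(c)) signif(c, 6) else c
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- names(df)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  if (nrow(df) == 0) return(c(header, rule))
  body <- apply(df, 1, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(header, rule, body)
}
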