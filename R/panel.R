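## Cytokine panel container and preprocessing chain.
##
## A panel is a long-format data.frame (subject_id, group, cytokine,
## timepoint_label, minutes_from_T1, concentration) with a units attribute,
## either "pg_ml" (raw concentrations) or "fold_change" (normalized to the
## healthy resting baseline). The time axis is anchored at peak effort
## (T1 = 0 min); pre-peak samples carry negative minutes.

PANEL_COLUMNS <- c(
  "subject_id", "group", "cytokine", "timepoint_label",
  "minutes_from_T1", "concentration"
)

#' Construct and validate a cytokine panel
#'
#' @param records data.frame with columns `subject_id`, `group` (HC/GWI),
#'   `cytokine` (one of [PANEL_CYTOKINES]), `timepoint_label` (one of
#'   [TIMEPOINT_LABELS]), `minutes_from_T1` (minutes relative to peak
#'   effort), `concentration` (pg/ml, or fold change).
#' @param units `"pg_ml"` or `"fold_change"`.
#' @return A `cytokine_panel`: the validated data.frame with a `units`
#'   attribute, rows ordered by subject, cytokine, time.
#' @export
cytokine_panel <- function(records, units = c("pg_ml", "fold_change")) {
  units <- match.arg(units)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PANEL_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stopf("panel is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  records <- records[PANEL_COLUMNS]
  records$subject_id <- as.character(records$subject_id)
  records$group <- as.character(records$group)
  records$cytokine <- as.character(records$cytokine)
  records$timepoint_label <- as.character(records$timepoint_label)
  records$minutes_from_T1 <- as.numeric(records$minutes_from_T1)
  records$concentration <- as.numeric(records$concentration)

  if (nrow(records) > 0) {
    bad_group <- setdiff(unique(records$group), c("HC", "GWI"))
    if (length(bad_group) > 0) {
      stopf("unknown group label(s): %s", paste(bad_group, collapse = ", "))
    }
    bad_cyt <- setdiff(unique(records$cytokine), PANEL_CYTOKINES)
    if (length(bad_cyt) > 0) {
      stopf("unknown cytokine name(s): %s", paste(bad_cyt, collapse = ", "))
    }
    bad_lab <- setdiff(unique(records$timepoint_label), TIMEPOINT_LABELS)
    if (length(bad_lab) > 0) {
      stopf("unknown timepoint label(s): %s", paste(bad_lab, collapse = ", "))
    }
    neg <- which(!is.finite(records$concentration) | records$concentration < 0)
    if (units == "pg_ml" && length(neg) > 0) {
      stopf("negative or non-finite concentration at record(s): %s",
            paste(utils::head(neg, 5), collapse = ", "))
    }
    if (units == "fold_change" && any(records$concentration <= 0)) {
      stopf("fold-change panel must have strictly positive values")
    }
    key <- paste(records$subject_id, records$cytokine,
                 records$timepoint_label, sep = "\r")
    if (anyDuplicated(key) > 0) {
      d <- key[duplicated(key)][1]
      stopf("duplicated (subject, cytokine, timepoint) record: %s",
            gsub("\r", ", ", d))
    }
    records <- records[order(records$subject_id, records$cytokine,
                             records$minutes_from_T1), , drop = FALSE]
    ## per subject x cytokine, minutes must be strictly increasing
    sp <- split(records$minutes_from_T1,
                paste(records$subject_id, records$cytokine, sep = "\r"))
    for (nm in names(sp)) {
      if (any(diff(sp[[nm]]) <= 0)) {
        stopf("minutes_from_T1 not strictly increasing for (%s)",
              gsub("\r", ", ", nm))
      }
    }
    rownames(records) <- NULL
  }
  structure(records, units = units, class = c("cytokine_panel", "data.frame"))
}

#' @export
print.cytokine_panel <- function(x, ...) {
  cat(sprintf(
    "<cytokine_panel> %d records | %d subjects | %d cytokines | units=%s\n",
    nrow(x), length(unique(x$subject_id)), length(unique(x$cytokine)),
    panel_units(x)))
  invisible(x)
}

#' Units flag of a panel
#' @param panel a [cytokine_panel()]
#' @return `"pg_ml"` or `"fold_change"`
#' @export
panel_units <- function(panel) attr(panel, "units", exact = TRUE) %||% "pg_ml"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cytokine panel from a delimited file
#'
#' Expects columns `subject_id, group, cytokine, timepoint_label,
#' minutes_from_T1, concentration` and an optional leading comment line
#' `# units=pg_ml` (or `fold_change`).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return a validated [cytokine_panel()].
#' @export
read_panel <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  first <- readLines(path, n = 1L)
  units <- "pg_ml"
  if (length(first) == 1 && grepl("^#\\s*units=", first)) {
    units <- sub("^#\\s*units=\\s*", "", first)
    units <- trimws(units)
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(PANEL_COLUMNS)), PANEL_COLUMNS))
  }
  panel <- cytokine_panel(df, units = units)
  log_info("read %d panel records from %s", nrow(panel), path)
  panel
}

#' Write a cytokine panel to a delimited file
#'
#' Writes a `# units=` header comment followed by a UTF-8 table; the output
#' round-trips through [read_panel()].
#'
#' @param panel a [cytokine_panel()]
#' @param path output path
#' @param dialect `"tsv"` or `"csv"`
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# units=%s", panel_units(panel)), con)
  utils::write.table(as.data.frame(panel), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Replace non-detect (zero) concentrations by the cytokine's observed floor
#'
#' Zeros (values below the assay detection limit) are replaced by the
#' minimum strictly positive concentration of that cytokine observed across
#' all subjects of both groups.
#'
#' @param panel a pg/ml [cytokine_panel()]
#' @return panel with zeros replaced; idempotent.
#' @export
replace_nondetects <- function(panel) {
  if (panel_units(panel) != "pg_ml") {
    stopf("replace_nondetects expects a pg_ml panel")
  }
  n_zero_total <- 0L
  for (cyt in unique(panel$cytokine)) {
    idx <- panel$cytokine == cyt
    v <- panel$concentration[idx]
    zeros <- v == 0
    if (!any(zeros)) next
    pos <- v[v > 0]
    if (length(pos) == 0) {
      stopf("cytokine %s has no detectable value in any subject; floor undefined", cyt)
    }
    panel$concentration[idx][zeros] <- min(pos)
    n_zero_total <- n_zero_total + sum(zeros)
  }
  log_info("replaced %d non-detect values", n_zero_total)
  panel
}

#' Linearly interpolate each subject x cytokine series onto a uniform grid
#'
#' Piecewise-linear interpolation from the first to the last observed minute
#' of each series, at a fixed step (default 3 min, the minimum sampling
#' interval of the protocol). No extrapolation beyond observed endpoints.
#'
#' @param panel a [cytokine_panel()]
#' @param step_minutes grid spacing in minutes (> 0).
#' @return a `uniform_series_set`: long data.frame (`subject_id`, `group`,
#'   `cytokine`, `minutes`, `value`) with `step` and `units` attributes.
#' @export
interpolate_uniform <- function(panel, step_minutes = 3) {
  stopifnot(step_minutes > 0)
  sp <- split(seq_len(nrow(panel)),
              paste(panel$subject_id, panel$cytokine, sep = "\r"))
  out <- vector("list", length(sp))
  for (k in seq_along(sp)) {
    rows <- sp[[k]]
    t <- panel$minutes_from_T1[rows]
    v <- panel$concentration[rows]
    if (length(t) < 2) {
      stopf("series (%s) has fewer than 2 observations",
            gsub("\r", ", ", names(sp)[k]))
    }
    grid <- seq(t[1], t[length(t)], by = step_minutes)
    vi <- stats::approx(t, v, xout = grid, method = "linear")$y
    out[[k]] <- data.frame(
      subject_id = panel$subject_id[rows[1]],
      group = panel$group[rows[1]],
      cytokine = panel$cytokine[rows[1]],
      minutes = grid, value = vi, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, step = step_minutes, units = panel_units(panel),
            class = c("uniform_series_set", "data.frame"))
}

#' @export
print.uniform_series_set <- function(x, ...) {
  cat(sprintf(
    "<uniform_series_set> %d points | %d series | step=%g min | units=%s\n",
    nrow(x), length(unique(paste(x$subject_id, x$cytokine))),
    attr(x, "step", exact = TRUE), attr(x, "units", exact = TRUE)))
  invisible(x)
}

#' Normalize interpolated series to fold change over the healthy resting baseline
#'
#' Per cytokine, the baseline is the mean of log2 concentrations at rest (T0)
#' over healthy-control subjects, i.e. the log2 of the geometric mean of HC
#' resting values; each value v becomes 2^(log2 v - baseline) = v / geomean.
#' Baselines are computed from the raw (uninterpolated) T0 observations.
#'
#' @param series a `uniform_series_set` in pg/ml (post non-detect replacement).
#' @param panel_meta the pg/ml [cytokine_panel()] supplying raw T0 records.
#' @return the series in fold-change units.
#' @export
to_fold_change <- function(series, panel_meta) {
  if (attr(series, "units", exact = TRUE) != "pg_ml") {
    stopf("series already normalized")
  }
  t0 <- panel_meta[panel_meta$timepoint_label == "T0" &
                     panel_meta$group == "HC", , drop = FALSE]
  if (nrow(t0) == 0) stopf("no HC resting (T0) records; baseline undefined")
  if (any(t0$concentration <= 0)) {
    stopf("non-positive T0 concentration; run replace_nondetects first")
  }
  base <- tapply(log2(t0$concentration), t0$cytokine, mean)
  missing <- setdiff(unique(series$cytokine), names(base))
  if (length(missing) > 0) {
    stopf("no HC T0 baseline for cytokine(s): %s",
          paste(missing, collapse = ", "))
  }
  if (any(series$value <= 0)) {
    stopf("non-positive series values; run replace_nondetects first")
  }
  series$value <- 2^(log2(series$value) - unname(base[series$cytokine]))
  attr(series, "units") <- "fold_change"
  series
}

#' Restrict series to the recovery window
#'
#' Keeps grid points with minutes from peak effort in `[0, window_minutes]`
#' (default the 4-h recovery period, covering 6 of the 8 draws).
#'
#' @param series a `uniform_series_set`
#' @param window_minutes end of the recovery window (default 240).
#' @return clipped `uniform_series_set`.
#' @export
slice_recovery <- function(series, window_minutes = 240) {
  keep <- series$minutes >= 0 & series$minutes <= window_minutes
  if (!any(keep)) stopf("recovery window [0, %g] contains no grid points", window_minutes)
  ends <- tapply(series$minutes, paste(series$subject_id, series$cytokine),
                 max)
  if (any(ends < window_minutes)) {
    warnf("%d series end before %g min; kept as-is (no extrapolation)",
          sum(ends < window_minutes), window_minutes)
  }
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("step", "units", "class")] <-
    attributes(series)[c("step", "units", "class")]
  out
}

#' Standard preprocessing chain for a raw panel
#'
#' Non-detect replacement, optional subject exclusion, uniform-grid
#' interpolation, fold-change normalization to the HC resting baseline, and
#' recovery-window slicing, in that order.
#'
#' @param panel raw pg/ml [cytokine_panel()]
#' @param exclude_subjects character vector of subject ids dropped before
#'   processing (e.g. out-of-range outliers); no automatic outlier rule.
#' @param step_minutes interpolation step (min).
#' @param window_minutes recovery window end (min).
#' @return recovery-phase fold-change `uniform_series_set`.
#' @export
preprocess_panel <- function(panel, exclude_subjects = character(),
                             step_minutes = 3, window_minutes = 240) {
  if (length(exclude_subjects) > 0) {
    panel <- cytokine_panel(
      panel[!panel$subject_id %in% exclude_subjects, , drop = FALSE],
      units = panel_units(panel))
  }
  panel <- replace_nondetects(panel)
  ser <- interpolate_uniform(panel, step_minutes = step_minutes)
  ser <- to_fold_change(ser, panel)
  slice_recovery(ser, window_minutes = window_minutes)
}
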