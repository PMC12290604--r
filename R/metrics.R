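#' Time to peak of an event-related average
#'
#' TTP is the time of the highest signal change between the initial
#' deflection above 0 and the subsequent fall below 0: locate the first
#' sample strictly above zero, then the first later sample strictly below
#' zero (end of the series if none — end-of-window truncation), and return
#' the time of the maximum within that span, ties broken to the earliest
#' sample. Series with no sample above zero are flagged invalid.
#'
#' Zero crossings are detected against a small threshold, `rel_tol` times
#' the series maximum, so that numerically tiny wiggles around baseline do
#' not truncate the span; `rel_tol = 0` gives the strict literal rule.
#'
#' @param era A zeroed `era` tibble ([zero_first()]), possibly with extra
#'   grouping columns (`compartment`, `layer`, ...), or a bare numeric
#'   vector with `dt_s` supplied.
#' @param dt_s Sample spacing for numeric input.
#' @param rel_tol Relative deflection threshold; default 0.01.
#' @return A tibble of class `ttp_table`: one row per (grouping, duration)
#'   with `ttp_s`, `peak_value_pct`, `valid`.
#' @export
time_to_peak <- function(era, dt_s = NULL, rel_tol = 0.01) {
  if (is.numeric(era)) {
    r <- ttp_scan(era, rel_tol)
    return(tibble::new_tibble(
      tibble::tibble(ttp_s = r$index_time * (dt_s %||% 1),
                     peak_value_pct = r$peak, valid = r$valid),
      class = "ttp_table"))
  }
  stopifnot(inherits(era, "era") || all(c("duration_s", "time_s", "value")
                                        %in% names(era)))
  grp_cols <- intersect(c("contrast", "compartment", "layer", "duration_s"),
                        names(era))
  out <- dplyr::reframe(
    dplyr::group_by(era, dplyr::across(dplyr::all_of(grp_cols))),
    {
      o <- order(.data$time_s)
      ts <- .data$time_s[o]
      r <- ttp_scan(.data$value[o], rel_tol)
      tibble::tibble(ttp_s = if (r$valid) ts[r$index] else NA_real_,
                     peak_value_pct = r$peak, valid = r$valid)
    })
  tibble::new_tibble(out, class = "ttp_table")
}

# scan rule shared by time_to_peak; returns 1-based index of the peak
ttp_scan <- function(v, rel_tol = 0.01) {
  thr <- if (any(is.finite(v)) && max(v, na.rm = TRUE) > 0)
    rel_tol * max(v, na.rm = TRUE) else 0
  above <- which(v > thr)
  if (length(above) == 0)
    return(list(valid = FALSE, index = NA_integer_, index_time = NA_real_,
                peak = NA_real_))
  i0 <- above[1]
  below <- which(v < -thr)
  below <- below[below > i0]
  i1 <- if (length(below)) below[1] - 1L else length(v)
  span <- i0:i1
  vmax <- max(v[span])
  # ties (e.g. a saturated plateau) break to the earliest sample; detect
  # them at a small relative tolerance so trace carryover cannot tip them
  ip <- span[which(v[span] >= vmax - 1e-6 * abs(vmax))[1]]
  list(valid = TRUE, index = ip, index_time = ip - 1L, peak = v[ip])
}

#' Vessel over gray-matter peak-signal ratio
#'
#' Ratio of the peak signal change of vessel-dominated voxels to the peak
#' signal change in gray matter, per stimulus duration, peaks located by
#' the [time_to_peak()] span rule on zeroed percent-change averages. A
#' non-positive gray-matter peak makes the ratio invalid (`NA`).
#'
#' @param era_vessel,era_gm Zeroed `era` tibbles for the vessel and
#'   gray-matter masks (matching durations).
#' @return Tibble of class `ratio_table`: `duration_s`, `peak_vessel_pct`,
#'   `peak_gm_pct`, `ratio`, `valid`.
#' @export
peak_ratio <- function(era_vessel, era_gm) {
  tv <- time_to_peak(era_vessel)
  tg <- time_to_peak(era_gm)
  m <- dplyr::inner_join(
    dplyr::select(tv, "duration_s", peak_vessel_pct = "peak_value_pct",
                  v_valid = "valid"),
    dplyr::select(tg, "duration_s", peak_gm_pct = "peak_value_pct",
                  g_valid = "valid"),
    by = "duration_s")
  m <- dplyr::mutate(
    m,
    valid = .data$v_valid & .data$g_valid &
      !is.na(.data$peak_gm_pct) & .data$peak_gm_pct > 0,
    ratio = dplyr::if_else(.data$valid,
                           .data$peak_vessel_pct / .data$peak_gm_pct,
                           NA_real_))
  out <- dplyr::select(m, "duration_s", "peak_vessel_pct", "peak_gm_pct",
                       "ratio", "valid")
  tibble::new_tibble(out, class = "ratio_table")
}

#' Bundle pipeline results into a machine- and human-readable report
#'
#' Collects TTP tables, ratio tables and QC summaries into one list, writes
#' it as deterministic JSON plus TSV tables when `out_dir` is given, and
#' echoes any generator ground truth alongside the estimates so recovery
#' can be audited.
#'
#' @param ttp_tables Named list of `ttp_table`s (may be empty).
#' @param ratio_tables Named list of `ratio_table`s.
#' @param fd_series Optional named list of FD tibbles; summarized as mean /
#'   max FD and count above 0.9 mm.
#' @param tsnr_maps Optional named list of tSNR arrays; summarized by their
#'   finite-value median.
#' @param truth Optional ground-truth peak tibble
#'   ([ground_truth_peaks()]).
#' @param out_dir Optional output directory.
#' @return The report list, invisibly if written.
#' @export
summarize_metrics <- function(ttp_tables = list(), ratio_tables = list(),
                              fd_series = NULL, tsnr_maps = NULL,
                              truth = NULL, out_dir = NULL) {
  report <- list(
    ttp = lapply(ttp_tables, as.data.frame),
    ratios = lapply(ratio_tables, as.data.frame),
    qc = list(
      fd = if (!is.null(fd_series)) lapply(fd_series, function(f) {
        list(mean_mm = mean(f$fd_mm), max_mm = max(f$fd_mm),
             n_above_0.9mm = sum(f$fd_mm > 0.9))
      }),
      tsnr = if (!is.null(tsnr_maps)) lapply(tsnr_maps, function(m) {
        list(median = stats::median(m[is.finite(m)]))
      })),
    ground_truth = if (!is.null(truth)) as.data.frame(truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    for (nm in names(ttp_tables))
      utils::write.table(ttp_tables[[nm]],
                         file.path(out_dir, paste0("ttp_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    for (nm in names(ratio_tables))
      utils::write.table(ratio_tables[[nm]],
                         file.path(out_dir, paste0("ratio_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
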