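#' Extract per-trial windows from a time course
#'
#' Cuts one window per trial out of a (typically BOLD-corrected and
#' temporally upsampled) series, from the onset of stimulation until the end
#' of the trial's rest period. Onsets lie on the jittered effective grid, so
#' after subtracting each trial's onset all windows share a common
#' post-onset time base with spacing `dt_s`. The series' `measured` flags
#' are carried along so averaging can distinguish original volumes from
#' interpolated samples. Trials extending past the end of the run are
#' truncated and flagged.
#'
#' @param series A [sampled_series()] (e.g. from [roi_mean_series()]) on the
#'   upsampled stimulus-onset grid.
#' @param design A [make_design()] tibble.
#' @param run Which run(s) of the design to extract; default all.
#' @return A tibble of class `trial_set`: one row per retained sample with
#'   columns `run`, `trial`, `duration_s`, `jitter`, `iti_class`,
#'   `rel_time_s` (from stimulus onset), `value`, `measured`, `truncated`.
#' @export
extract_trials <- function(series, design, run = NULL) {
  stopifnot(inherits(series, "sampled_series"))
  trials <- if (is.null(run)) design else design[design$run %in% run, ]
  tt <- series_times(series)
  n <- length(tt)
  rows <- purrr::pmap_dfr(
    trials[, c("run", "trial", "onset_s", "duration_s", "jitter", "iti_s")],
    function(run, trial, onset_s, duration_s, jitter, iti_s) {
      n_samp <- floor((duration_s + iti_s) / series$dt_s + 1e-9)
      # first series sample at/after onset (onsets lie on the sample grid)
      i0 <- which(tt >= onset_s - 1e-9)[1]
      if (is.na(i0)) return(NULL)
      idx <- i0 + seq_len(n_samp) - 1L
      keep <- idx <= n
      idx <- idx[keep]
      # snap to exact grid multiples so equal offsets compare equal across
      # trials regardless of floating-point onset arithmetic
      rel <- round((tt[idx] - onset_s) / series$dt_s) * series$dt_s
      tibble::tibble(run = run, trial = trial, duration_s = duration_s,
                     jitter = jitter,
                     rel_time_s = rel,
                     value = series$values[idx],
                     measured = series$measured[idx],
                     truncated = !all(keep))
    })
  if (nrow(rows) > 0) rows$iti_class <- design$iti_class[1]
  structure(tibble::new_tibble(rows, class = "trial_set"),
            dt_s = series$dt_s, contrast = series$contrast)
}

#' Average trials into an event-related time course per duration
#'
#' Pointwise mean over all trials sharing a stimulus duration, interleaving
#' the jittered onsets onto the effective sampling grid. By default only
#' measured samples (original volumes) contribute at each timepoint — the
#' jitter phases tile the grid so every timepoint is covered — which makes
#' the noise-free reconstruction of a smooth response exact; timepoints
#' with no measured sample (e.g. truncated coverage) fall back to the
#' interpolated values. The number of measured contributions is reported
#' per timepoint.
#'
#' @param trials A `trial_set` from [extract_trials()] (several may be
#'   row-bound first).
#' @param use_measured If `FALSE`, average all (interpolated) samples
#'   instead.
#' @return A tibble of class `era` with columns `duration_s`, `time_s`,
#'   `value`, `n` (measured contributions), `n_total`, and attributes
#'   `dt_s`, `contrast`.
#' @export
average_trials <- function(trials, use_measured = TRUE) {
  stopifnot(nrow(trials) > 0)
  grp <- dplyr::group_by(trials, .data$duration_s, .data$rel_time_s)
  era <- dplyr::summarise(
    grp,
    n = sum(.data$measured),
    n_total = dplyr::n(),
    value = if (use_measured && any(.data$measured))
      mean(.data$value[.data$measured]) else mean(.data$value),
    .groups = "drop")
  era <- dplyr::arrange(era, .data$duration_s, .data$rel_time_s)
  era <- dplyr::rename(era, time_s = "rel_time_s")
  era <- era[, c("duration_s", "time_s", "value", "n", "n_total")]
  structure(tibble::new_tibble(era, class = "era"),
            dt_s = attr(trials, "dt_s"), contrast = attr(trials, "contrast"))
}

#' Baseline signal from the run edges
#'
#' The voxelwise (or series-wise) baseline: the mean over the first and
#' final `window_s` seconds of every run, averaged across runs.
#'
#' @param run_series_list List of [volume_series()] or [sampled_series()]
#'   objects (one per session-averaged run).
#' @param window_s Edge window length, seconds; default 30.
#' @return A 3D array for volume input, a scalar for sampled input.
#' @export
baseline_signal <- function(run_series_list, window_s = 30) {
  if (inherits(run_series_list, c("volume_series", "sampled_series")))
    run_series_list <- list(run_series_list)
  per_run <- lapply(run_series_list, function(s) {
    n <- n_vols(s)
    k <- floor(window_s / s$dt_s + 1e-9)
    if (n < 2 * k) stop("run shorter than twice the baseline window")
    idx <- c(seq_len(k), n - k + seq_len(k))
    if (inherits(s, "sampled_series")) return(mean(s$values[idx]))
    dims <- dim(s$data)
    m <- matrix(s$data, prod(dims[1:3]), dims[4])
    array(rowMeans(m[, idx, drop = FALSE]), dims[1:3])
  })
  Reduce(`+`, per_run) / length(per_run)
}

#' Convert an event-related average to percent signal change
#'
#' Divides each timepoint by the baseline and multiplies by 100. For the
#' VASO contrast the result is additionally multiplied by -1, since a CBV
#' increase lowers the nulled signal; after the final zeroing
#' ([zero_first()]) CBV increases then appear as positive deflections.
#'
#' @param era An `era` tibble from [average_trials()].
#' @param baseline Scalar baseline (e.g. [baseline_signal()] of the same
#'   masked series). Must be finite and nonzero.
#' @param contrast `"vaso"` or `"bold"`; defaults to the era's contrast tag.
#' @return The era with `value` in % signal change.
#' @export
percent_signal_change <- function(era, baseline, contrast = NULL) {
  if (is.null(contrast)) contrast <- attr(era, "contrast")
  if (!is.finite(baseline) || baseline == 0) stop("invalid baseline")
  sgn <- if (identical(contrast, "vaso")) -1 else 1
  era$value <- sgn * 100 * era$value / baseline
  era
}

#' Stitch short-ITI and long-ITI segments of an event-related average
#'
#' Trial windows from short-ITI runs end earlier than those from long-ITI
#' runs, so the tail of an event-related average is estimated from the
#' long-ITI runs only and can sit at an offset. The offset — the difference
#' between the first long-only timepoint and the last short-covered
#' timepoint — is subtracted from all long-only timepoints, so the junction
#' pair takes the same value; short-covered timepoints are untouched.
#'
#' @param era_short `era` covering the short-ITI window (typically averaged
#'   over all runs).
#' @param era_long `era` covering the full long-ITI window (long runs only).
#' @return An `era` over the full window with a `segment` column
#'   (`"short_covered"` / `"long_only"`).
#' @export
stitch_iti <- function(era_short, era_long) {
  stopifnot(inherits(era_short, "era"), inherits(era_long, "era"))
  dt <- attr(era_short, "dt_s")
  out <- purrr::map_dfr(sort(unique(era_short$duration_s)), function(d) {
    s <- era_short[era_short$duration_s == d, ]
    l <- era_long[era_long$duration_s == d, ]
    if (nrow(l) == 0) stop("no long-ITI segment for duration ", d)
    t_end <- max(s$time_s)
    tail <- l[l$time_s > t_end + 1e-9, ]
    if (nrow(tail) == 0) stop("no long-only timepoints beyond the junction",
                              " for duration ", d)
    offset <- tail$value[which.min(tail$time_s)] - s$value[which.max(s$time_s)]
    tail$value <- tail$value - offset
    s$segment <- "short_covered"
    tail$segment <- "long_only"
    dplyr::bind_rows(s, tail)
  })
  structure(tibble::new_tibble(out, class = "era"),
            dt_s = dt, contrast = attr(era_short, "contrast"))
}

#' Zero the first timepoint of an event-related average
#'
#' Subtracts the value at the first timepoint from every timepoint (per
#' stimulus duration), so each event-related average starts at exactly 0.
#' Applied per layer/compartment and duration before any averaging across
#' participants.
#'
#' @param era An `era` tibble, or a bare numeric vector.
#' @return Same type, first value 0.
#' @export
zero_first <- function(era) {
  if (is.numeric(era)) return(era - era[1])
  stopifnot(nrow(era) > 0)
  out <- dplyr::mutate(era,
                       value = .data$value - .data$value[which.min(.data$time_s)],
                       .by = "duration_s")
  structure(tibble::new_tibble(out, class = "era"),
            dt_s = attr(era, "dt_s"), contrast = attr(era, "contrast"))
}
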