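#' BOLD-corrected VASO series for one simulated run
#'
#' The signal-conditioning chain for one run: BOLD-contamination correction
#' by dynamic division of the native-rate volume pairs (each cycle's nulled
#' volume by the same cycle's BOLD volume, which cancels the quasi-static
#' within-cycle contamination exactly), followed by temporal upsampling of
#' the corrected VASO series and of the BOLD series by `factor` onto the
#' jittered stimulus-onset grid. Dividing measured volume pairs before any
#' interpolation keeps the correction a ratio of measurements.
#'
#' @param run One element of `simulate_participant()$runs` (or any list
#'   with `nulled` and `bold` [volume_series()]).
#' @param factor Temporal upsampling factor; default 4 (to the 0.785 s
#'   stimulus-onset grid).
#' @return A list with `vaso` and `bold` (both upsampled
#'   [volume_series()]).
#' @export
boco_run <- function(run, factor = 4) {
  vaso <- boco(run$nulled, run$bold)
  list(vaso = upsample_temporal(vaso, factor),
       bold = upsample_temporal(run$bold, factor))
}

#' Event-related average over a mask for a simulated participant
#'
#' Runs the full event-related chain for one voxel mask: upsample, BOLD
#' correction, mask-mean time course, per-trial extraction across all runs,
#' jitter-interleaved averaging per stimulus duration, percent signal
#' change against the 30 s run-edge baseline (with VASO sign inversion),
#' short/long-ITI stitching (when both run classes are present), and
#' first-timepoint zeroing.
#'
#' @param sim A [simulate_participant()] result.
#' @param mask Logical 3D voxel mask.
#' @param contrast `"vaso"` or `"bold"`.
#' @param factor Temporal upsampling factor; default 4.
#' @param use_measured Passed to [average_trials()].
#' @param baseline_window_s Baseline edge window, seconds; default 30.
#' @param precomputed Optional list of [boco_run()] results (one per run),
#'   to avoid recomputing the corrected series when several masks are
#'   analyzed.
#' @return An `era` tibble (zeroed % signal change per duration, with a
#'   `segment` column when stitching occurred).
#' @export
era_pipeline <- function(sim, mask, contrast = c("vaso", "bold"), factor = 4,
                         use_measured = TRUE, baseline_window_s = 30,
                         precomputed = NULL) {
  contrast <- match.arg(contrast)
  trial_sets <- list(); run_series <- list(); classes <- character(0)
  for (i in seq_along(sim$runs)) {
    run <- sim$runs[[i]]
    s4 <- if (is.null(precomputed)) boco_run(run, factor)[[contrast]]
    else precomputed[[i]][[contrast]]
    ser <- roi_mean_series(s4, mask)
    design <- if (run$iti_class == "short") sim$design_short else sim$design_long
    trial_sets[[i]] <- extract_trials(ser, design, run = run$design_run)
    run_series[[i]] <- ser
    classes[i] <- run$iti_class
  }
  dt <- attr(trial_sets[[1]], "dt_s")
  all_trials <- structure(
    tibble::new_tibble(dplyr::bind_rows(trial_sets), class = "trial_set"),
    dt_s = dt, contrast = contrast)
  base <- baseline_signal(run_series, baseline_window_s)

  era_all <- percent_signal_change(average_trials(all_trials, use_measured),
                                   base, contrast)
  if (length(unique(classes)) == 2) {
    itis_short <- iti_set("short")
    keep <- era_all$time_s <=
      (floor((era_all$duration_s +
                unname(itis_short[as.character(era_all$duration_s)])) / dt) - 1) *
      dt + 1e-9
    era_short <- structure(tibble::new_tibble(era_all[keep, ], class = "era"),
                           dt_s = dt, contrast = contrast)
    long_trials <- structure(
      tibble::new_tibble(dplyr::bind_rows(trial_sets[classes == "long"]),
                         class = "trial_set"),
      dt_s = dt, contrast = contrast)
    era_long <- percent_signal_change(average_trials(long_trials, use_measured),
                                      base, contrast)
    era <- stitch_iti(era_short, era_long)
  } else {
    era <- era_all
  }
  zero_first(era)
}

#' Compartment-resolved event-related averages and headline metrics
#'
#' Convenience driver reproducing the participant-level analysis on
#' simulated data: event-related averages for each hemodynamic compartment
#' (ground-truth masks), for all of gray matter and for the vessel mask;
#' time-to-peak per compartment and duration; and the vessel/gray-matter
#' peak-signal ratio per duration. Both the VASO and BOLD contrasts are
#' analyzed.
#'
#' @inheritParams era_pipeline
#' @param use_roi Restrict gray matter to the geometry's disc ROI footprint
#'   (`FALSE` by default: the whole synthetic ribbon is the ROI).
#' @return A list with `eras` (tibble with `contrast`, `compartment`
#'   columns), `ttp` (`ttp_table`), `ratio` (`ratio_table` per contrast),
#'   and `truth` (generator peak ground truth).
#' @export
participant_metrics <- function(sim, factor = 4, use_measured = TRUE,
                                use_roi = FALSE) {
  geo <- sim$geometry
  masks <- list(
    gm_deep = geo$compartments == 1L,
    gm_middle = geo$compartments == 2L,
    gm_superficial = geo$compartments == 3L,
    vessel = geo$compartments == 4L,
    gm = array(geo$compartments %in% 1:3, dim(geo$compartments)))
  if (use_roi) {
    dm <- depth_map(geo)
    roi <- disc_roi(geo, dm)
    for (nm in setdiff(names(masks), "vessel"))
      masks[[nm]] <- masks[[nm]] & roi
  }
  pre <- lapply(sim$runs, boco_run, factor = factor)
  eras <- purrr::map_dfr(c("vaso", "bold"), function(ct) {
    purrr::map_dfr(names(masks), function(nm) {
      e <- era_pipeline(sim, masks[[nm]], ct, factor, use_measured,
                        precomputed = pre)
      e$contrast <- ct; e$compartment <- nm
      e
    })
  })
  dt <- cycle_s(sim$acq) / factor
  era_cls <- function(df) structure(tibble::new_tibble(df, class = "era"),
                                    dt_s = dt, contrast = df$contrast[1])
  ttp <- time_to_peak(era_cls(eras[eras$compartment != "gm", ]))
  ratio <- purrr::map_dfr(c("vaso", "bold"), function(ct) {
    r <- peak_ratio(
      era_cls(eras[eras$contrast == ct & eras$compartment == "vessel", ]),
      era_cls(eras[eras$contrast == ct & eras$compartment == "gm", ]))
    r$contrast <- ct
    r
  })
  truth <- sim$runs[[1]]$truth$peaks
  list(eras = eras, ttp = ttp, ratio = ratio, truth = truth)
}
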