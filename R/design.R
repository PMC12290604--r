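#' Inter-trial-interval sets paired with the stimulus durations
#'
#' Each stimulus duration has a corresponding rest period; longer stimuli are
#' followed by longer rests. Two regimes exist: short ITIs (higher trial
#' throughput) and long ITIs (fuller return to baseline).
#'
#' @param iti_class `"short"` or `"long"`.
#' @return Named numeric vector of rest durations (s), named by the stimulus
#'   duration (s) they follow.
#' @export
iti_set <- function(iti_class = c("short", "long")) {
  iti_class <- match.arg(iti_class)
  durations <- c(1, 2, 4, 12, 24)
  itis <- if (iti_class == "short") c(10, 12, 14, 20, 24) else c(20, 22, 24, 30, 40)
  stats::setNames(itis, durations)
}

#' Generate a jittered stimulus design
#'
#' Builds per-run trial lists for the jittered block/event design: five
#' stimulus durations (1, 2, 4, 12 and 24 s), each presented exactly once per
#' jitter phase and run, with onsets systematically jittered over
#' `n_jitters` phases of the acquisition cycle so that trial averaging
#' samples the response on the effective `eff_dt(acq)` grid. Every onset
#' falls on the jitter grid (a multiple of `block_s` relative to a cycle
#' start) and each trial is followed by its duration-matched rest period, so
#' trial windows (stimulus + rest) never overlap.
#'
#' For long-ITI designs one trial pattern is generated and reused for every
#' run (rests are long enough to avoid carryover, and a shared pattern lets
#' nulled and BOLD runs be averaged across sessions before BOLD-correction);
#' short-ITI designs are shuffled independently per run.
#'
#' @param acq An [acq_scheme()].
#' @param n_runs Number of runs (>= 1).
#' @param iti_class `"short"` or `"long"`.
#' @param seed Optional integer seed (trial-order shuffling and attention
#'   targets).
#' @param initial_rest_s,final_rest_s Rest padding at the run edges, seconds;
#'   defaults 30 (the baseline window length).
#' @param targets_per_run Mean number of attention-task targets per run,
#'   recorded as metadata only.
#'
#' @return A tibble of class `stim_design` with columns `run`, `trial`,
#'   `onset_s`, `duration_s`, `jitter`, `iti_s`, `iti_class`, and attributes
#'   `acq`, `run_duration_s` (per-run total length, whole cycles) and
#'   `target_onsets_s` (list of per-run attention-target times).
#' @examples
#' d <- make_design(acq_scheme(), n_runs = 1, iti_class = "short", seed = 1)
#' nrow(d)  # 20 trials: 5 durations x 4 jitters
#' @export
make_design <- function(acq, n_runs = 1, iti_class = c("short", "long"),
                        seed = NULL, initial_rest_s = 30, final_rest_s = 30,
                        targets_per_run = 11) {
  stopifnot(inherits(acq, "acq_scheme"), n_runs >= 1)
  iti_class <- match.arg(iti_class)
  itis <- iti_set(iti_class)
  durations <- as.numeric(names(itis))

  build <- function() {
    pairs <- tidyr::expand_grid(duration_s = durations,
                                jitter = seq_len(acq$n_jitters) - 1L)
    pairs <- pairs[sample.int(nrow(pairs)), ]
    cursor <- initial_rest_s
    onsets <- numeric(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      j <- pairs$jitter[i]
      # smallest grid time  c*cycle + j*block  >= cursor
      c0 <- ceiling((cursor - j * acq$block_s) / cycle_s(acq) - 1e-9)
      onsets[i] <- max(c0, 0) * cycle_s(acq) + j * acq$block_s
      cursor <- onsets[i] + pairs$duration_s[i] + itis[as.character(pairs$duration_s[i])]
    }
    list(trials = dplyr::mutate(pairs, onset_s = onsets,
                                iti_s = unname(itis[as.character(pairs$duration_s)])),
         end_s = cursor)
  }

  gen <- function() {
    if (iti_class == "long") {
      one <- build()
      runs <- rep(list(one), n_runs)
    } else {
      runs <- replicate(n_runs, build(), simplify = FALSE)
    }
    targets <- lapply(runs, function(r) {
      n_t <- stats::rpois(1, targets_per_run)
      sort(stats::runif(n_t, 0, r$end_s))
    })
    list(runs = runs, targets = targets)
  }
  g <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  tbl <- dplyr::bind_rows(lapply(seq_len(n_runs), function(r) {
    dplyr::mutate(g$runs[[r]]$trials, run = r, .before = 1)
  }))
  tbl <- dplyr::arrange(tbl, .data$run, .data$onset_s)
  tbl <- dplyr::mutate(tbl, trial = dplyr::row_number(), .by = "run")
  tbl <- dplyr::select(tbl, "run", "trial", "onset_s", "duration_s", "jitter", "iti_s")
  tbl$iti_class <- iti_class
  run_dur <- vapply(g$runs, function(r) {
    ceiling((r$end_s + final_rest_s) / cycle_s(acq)) * cycle_s(acq)
  }, numeric(1))
  structure(tibble::new_tibble(tbl, class = "stim_design"),
            acq = acq, run_duration_s = run_dur, target_onsets_s = g$targets)
}

#' Check the structural invariants of a stimulus design
#'
#' Brute-force validation: each duration occurs exactly once per (jitter,
#' run), all onsets lie on the jitter grid, and trial windows (stimulus +
#' rest) do not overlap within a run.
#'
#' @param design A `stim_design`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_design <- function(design) {
  acq <- attr(design, "acq")
  counts <- dplyr::count(design, .data$run, .data$jitter, .data$duration_s)
  if (any(counts$n != 1L))
    stop("some (run, jitter, duration) cell does not contain exactly one trial")
  k <- design$onset_s / acq$block_s
  if (any(abs(k - round(k)) > 1e-8))
    stop("onsets are not multiples of block_s")
  if (any(round(k) %% acq$blocks_per_cycle != design$jitter))
    stop("onsets do not respect the jitter grid")
  for (r in unique(design$run)) {
    d <- dplyr::arrange(design[design$run == r, ], .data$onset_s)
    ends <- d$onset_s + d$duration_s + d$iti_s
    if (any(d$onset_s[-1] < ends[-nrow(d)] - 1e-9))
      stop("overlapping trial windows in run ", r)
  }
  invisible(TRUE)
}
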