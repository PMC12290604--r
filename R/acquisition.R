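#' Symmetric VASO acquisition scheme
#'
#' Timing of a symmetric SS-SI VASO acquisition cycle. One cycle consists of
#' `blocks_per_cycle` equally long blocks of `block_s` seconds each:
#' inversion delay, blood-nulled EPI readout, an additional delay, and the
#' BOLD EPI readout. One nulled and one BOLD volume are acquired per cycle.
#' Jittering stimulus onsets over `n_jitters` phases of the cycle makes the
#' effective sampling interval of event-related averages
#' `cycle length / n_jitters`, uncoupling the volume TR from the effective
#' temporal resolution (0.785 s for the defaults).
#'
#' @param block_s Block duration in seconds. Default 0.785.
#' @param blocks_per_cycle Number of equally spaced blocks per acquisition
#'   cycle. Default 4 (inversion delay, nulled readout, delay, BOLD readout).
#' @param n_jitters Number of stimulus-onset jitter phases. Default 4.
#' @param volumes_per_run Optional number of cycles (volume pairs) per run;
#'   usually derived from the stimulus design and left `NULL`.
#' @param nulled_block,bold_block 1-based block index at whose onset the
#'   nulled / BOLD volume is sampled. Defaults 2 and 4. Setting them equal
#'   yields a synchronized acquisition in which both contrasts sample the
#'   hemodynamic response at identical times (useful for exactness checks of
#'   the BOLD-correction algebra).
#' @param ti1_s,ti2_s,shot_tr_s Sequence timing metadata (inversion times and
#'   shot TR, seconds); recorded but not used by the sampling model.
#'
#' @return An object of class `acq_scheme`.
#' @examples
#' acq <- acq_scheme()
#' cycle_s(acq)   # 3.14 s volume-pair TR
#' eff_dt(acq)    # 0.785 s effective sampling interval
#' @export
acq_scheme <- function(block_s = 0.785, blocks_per_cycle = 4L, n_jitters = 4L,
                       volumes_per_run = NULL,
                       nulled_block = 2L, bold_block = 4L,
                       ti1_s = 1.047, ti2_s = 2.462, shot_tr_s = 0.042) {
  stopifnot(block_s > 0, blocks_per_cycle >= 1, n_jitters >= 1,
            nulled_block >= 1, nulled_block <= blocks_per_cycle,
            bold_block >= 1, bold_block <= blocks_per_cycle)
  structure(
    list(block_s = block_s,
         blocks_per_cycle = as.integer(blocks_per_cycle),
         n_jitters = as.integer(n_jitters),
         volumes_per_run = if (is.null(volumes_per_run)) NULL else as.integer(volumes_per_run),
         nulled_block = as.integer(nulled_block),
         bold_block = as.integer(bold_block),
         ti1_s = ti1_s, ti2_s = ti2_s, shot_tr_s = shot_tr_s),
    class = "acq_scheme")
}

#' @rdname acq_scheme
#' @param acq An `acq_scheme`.
#' @export
cycle_s <- function(acq) acq$blocks_per_cycle * acq$block_s

#' @rdname acq_scheme
#' @export
eff_dt <- function(acq) cycle_s(acq) / acq$n_jitters

#' Sample times of one contrast's volume series
#'
#' Times (seconds from run start) at which the nulled or BOLD volumes of a
#' run sample the underlying signal, taken at the onset of that contrast's
#' readout block within each cycle.
#'
#' @param acq An `acq_scheme`.
#' @param n_cycles Number of acquisition cycles in the run.
#' @param contrast `"nulled"` or `"bold"`.
#' @return Numeric vector of length `n_cycles`.
#' @export
sample_times <- function(acq, n_cycles, contrast = c("nulled", "bold")) {
  contrast <- match.arg(contrast)
  block <- if (contrast == "nulled") acq$nulled_block else acq$bold_block
  (seq_len(n_cycles) - 1) * cycle_s(acq) + (block - 1) * acq$block_s
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("<acq_scheme>\n")
  cat(sprintf("  %d x %.3f s blocks per cycle (cycle %.3f s), %d jitters -> effective dt %.3f s\n",
              x$blocks_per_cycle, x$block_s, cycle_s(x), x$n_jitters, eff_dt(x)))
  cat(sprintf("  nulled readout at block %d, BOLD at block %d\n",
              x$nulled_block, x$bold_block))
  invisible(x)
}
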