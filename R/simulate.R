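#' Simulate one run of interleaved nulled/BOLD volumes
#'
#' Generates the two volume series of a symmetric VASO acquisition for one
#' run of a stimulus design. Per voxel, with `v(t)` the fractional CBV
#' response and `delta(t)` the fractional BOLD response of the voxel's
#' compartment (zero outside GM and vessel voxels), cycle `i` yields
#' \deqn{S_{bold}[i] = S0_b (1 + \delta(t_{b,i})),\qquad
#'       S_{nulled}[i] = S0_n (1 - v(t_{n,i})) (1 + g\,\delta(t_{b,i})),}
#' where `t_n` and `t_b` are the onsets of the nulled and BOLD readout
#' blocks of the cycle: the CBV response is sampled at the nulled readout,
#' while the multiplicative T2* contamination is treated as quasi-static
#' within the cycle (one BOLD state per cycle, evaluated at the BOLD
#' readout, entering both volumes). i.i.d. Gaussian noise is added.
#' Responses are sums of per-trial saturating boxcar-convolution responses
#' ([compartment_response()]). A rigid motion trace is generated as
#' metadata (a smooth random walk); the images themselves are aligned —
#' registration is out of scope and the trace feeds only the framewise
#' displacement QC.
#'
#' @param geometry A [build_geometry()] result.
#' @param design A [make_design()] result.
#' @param acq The [acq_scheme()] the design was built for.
#' @param model A [compartment_model()].
#' @param run Which run of the design to simulate.
#' @param seed Optional integer seed (noise and motion).
#' @param noise If `FALSE`, omit noise regardless of the model's `noise_sd`.
#' @param motion_sd Per-volume random-walk step sd of the motion trace
#'   (mm for translations; rad, scaled by 1/50, for rotations). Default 0
#'   (still subject).
#'
#' @return A list with elements `nulled` and `bold` ([volume_series()]),
#'   `motion` (tibble: 3 translations mm, 3 rotations rad; one row per
#'   cycle), and `truth` (generative ground truth: per
#'   compartment/contrast/duration analytic peak times and amplitudes, the
#'   compartment response matrices at the sample times, and the model).
#' @export
simulate_run <- function(geometry, design, acq, model, run = 1,
                         seed = NULL, noise = TRUE, motion_sd = 0) {
  stopifnot(inherits(geometry, "vaso_geometry"),
            inherits(design, "stim_design"),
            inherits(acq, "acq_scheme"),
            inherits(model, "compartment_model"))
  trials <- design[design$run == run, ]
  if (nrow(trials) == 0) stop("design has no run ", run)
  run_dur <- attr(design, "run_duration_s")[run]
  n_cycles <- as.integer(ceiling(run_dur / cycle_s(acq) - 1e-9))
  t_n <- sample_times(acq, n_cycles, "nulled")
  t_b <- sample_times(acq, n_cycles, "bold")

  comps <- compartment_names()
  v_n <- t(vapply(comps, function(cp) run_response(t_n, trials, model, cp, "cbv"),
                  numeric(n_cycles)))
  # T2* contamination is treated as quasi-static within a cycle: one BOLD
  # state per cycle, evaluated at the BOLD readout, multiplies both volumes
  d_b <- t(vapply(comps, function(cp) run_response(t_b, trials, model, cp, "bold"),
                  numeric(n_cycles)))

  # per-compartment signal factors, row 1 = non-responding tissue
  fac_n <- rbind(rep(1, n_cycles), (1 - v_n) * (1 + model$bold_gain * d_b))
  fac_b <- rbind(rep(1, n_cycles), 1 + d_b)

  lab <- geometry$labels
  tiss <- c("background", "csf", "gm", "wm", "vessel")[match(lab, geometry$codes)]
  s0n <- ifelse(tiss == "background", 0,
                model$s0_nulled[ifelse(tiss == "vessel", "vessel",
                                       ifelse(tiss == "gm", "gm", tiss))])
  s0b <- ifelse(tiss == "background", 0,
                model$s0_bold[ifelse(tiss == "vessel", "vessel",
                                     ifelse(tiss == "gm", "gm", tiss))])
  comp_row <- as.vector(geometry$compartments) + 1L  # 1 = no response

  S_n <- as.vector(s0n) * fac_n[comp_row, , drop = FALSE]
  S_b <- as.vector(s0b) * fac_b[comp_row, , drop = FALSE]

  gen_noise <- function() {
    if (noise && model$noise_sd > 0) {
      S_n <<- S_n + stats::rnorm(length(S_n), 0, model$noise_sd)
      S_b <<- S_b + stats::rnorm(length(S_b), 0, model$noise_sd)
    }
    steps <- matrix(stats::rnorm(n_cycles * 6, 0,
                                 motion_sd * rep(c(1, 1, 1, .02, .02, .02), each = n_cycles)),
                    n_cycles, 6)
    apply(steps, 2, cumsum)
  }
  mot <- if (is.null(seed)) gen_noise() else withr::with_seed(seed, gen_noise())
  if (n_cycles == 1) mot <- matrix(mot, 1, 6)
  motion <- tibble::as_tibble(as.data.frame(mot))
  names(motion) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                     "rot_x_rad", "rot_y_rad", "rot_z_rad")

  dims <- c(geometry$grid_shape, n_cycles)
  truth <- list(
    peaks = ground_truth_peaks(model, unique(trials$duration_s)),
    v_nulled = v_n, delta_bold = d_b,
    compartments = comps, t_nulled = t_n, t_bold = t_b,
    model = model, run = run, seed = seed)
  list(nulled = volume_series(array(S_n, dims), "nulled", cycle_s(acq),
                              (acq$nulled_block - 1) * acq$block_s),
       bold = volume_series(array(S_b, dims), "bold", cycle_s(acq),
                            (acq$bold_block - 1) * acq$block_s),
       motion = motion, truth = truth)
}

#' Analytic peak ground truth for every compartment, contrast and duration
#'
#' @param model A [compartment_model()].
#' @param durations_s Stimulus durations, seconds.
#' @return Tibble: `compartment`, `contrast`, `duration_s`, `peak_time_s`,
#'   `peak_value_pct` (fractional response x 100).
#' @export
ground_truth_peaks <- function(model, durations_s = c(1, 2, 4, 12, 24)) {
  grid <- tidyr::expand_grid(compartment = compartment_names(),
                             contrast = c("cbv", "bold"),
                             duration_s = sort(durations_s))
  purrr::pmap_dfr(grid, function(compartment, contrast, duration_s) {
    r <- compartment_response(duration_s, model, compartment, contrast)
    tibble::tibble(compartment = compartment, contrast = contrast,
                   duration_s = duration_s, peak_time_s = r$peak_time_s,
                   peak_value_pct = 100 * r$peak_value)
  })
}

#' Simulate a participant: several runs with short- and long-ITI designs
#'
#' Convenience wrapper generating the designs (independent trial patterns
#' per short-ITI run, one shared pattern for all long-ITI runs) and
#' simulating every run. Each simulated run stands for one session-averaged
#' run of the acquisition.
#'
#' @inheritParams simulate_run
#' @param n_short,n_long Number of short- and long-ITI runs.
#' @param seed Integer seed controlling designs, noise and motion.
#' @return A list with `design_short`, `design_long` and `runs` (list of
#'   [simulate_run()] results, short runs first), plus `acq`, `model`,
#'   `geometry`.
#' @export
simulate_participant <- function(geometry, acq, model,
                                 n_short = 2, n_long = 2, seed = 1,
                                 noise = TRUE, motion_sd = 0) {
  design_short <- if (n_short > 0)
    make_design(acq, n_short, "short", seed = seed) else NULL
  design_long <- if (n_long > 0)
    make_design(acq, n_long, "long", seed = seed + 1L) else NULL
  runs <- list()
  k <- 0
  for (r in seq_len(n_short)) {
    k <- k + 1
    runs[[k]] <- simulate_run(geometry, design_short, acq, model, run = r,
                              seed = seed + 100L + k, noise = noise,
                              motion_sd = motion_sd)
    runs[[k]]$iti_class <- "short"; runs[[k]]$design_run <- r
  }
  for (r in seq_len(n_long)) {
    k <- k + 1
    runs[[k]] <- simulate_run(geometry, design_long, acq, model, run = r,
                              seed = seed + 100L + k, noise = noise,
                              motion_sd = motion_sd)
    runs[[k]]$iti_class <- "long"; runs[[k]]$design_run <- r
  }
  list(design_short = design_short, design_long = design_long, runs = runs,
       acq = acq, model = model, geometry = geometry, seed = seed)
}
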