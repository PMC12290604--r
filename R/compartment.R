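#' Gamma-variate impulse response parameterized by mean and sd
#'
#' Density of a gamma distribution with `shape = (mean/sd)^2` and
#' `scale = sd^2/mean`, shifted by an onset delay. This is the same kernel
#' family as the GLM hemodynamic response function, which keeps generated
#' responses analytically tractable: the response to a boxcar stimulus is a
#' difference of gamma CDFs.
#'
#' @param t Time points, seconds.
#' @param mean_s,sd_s Mean and standard deviation of the (unshifted) kernel.
#' @param delay_s Onset delay, seconds.
#' @return Kernel values at `t` (density, 1/s).
#' @export
gamma_variate <- function(t, mean_s, sd_s, delay_s = 0) {
  stopifnot(mean_s > 0, sd_s > 0)
  stats::dgamma(t - delay_s, shape = (mean_s / sd_s)^2, scale = sd_s^2 / mean_s)
}

# unit-amplitude boxcar (duration d) convolved with the gamma-variate kernel:
# closed form as a CDF difference; lies in [0, 1)
boxcar_gamma <- function(t, duration_s, mean_s, sd_s, delay_s = 0) {
  shape <- (mean_s / sd_s)^2; scale <- sd_s^2 / mean_s
  stats::pgamma(t - delay_s, shape, scale = scale) -
    stats::pgamma(t - delay_s - duration_s, shape, scale = scale)
}

#' Default compartment response parameters
#'
#' One row per (compartment, contrast): gamma-variate impulse response
#' (onset delay, mean, sd), fractional response amplitude, and a saturation
#' ceiling applied to the unit boxcar convolution before amplitude scaling
#' (`cap = Inf` means the response is linear in stimulus duration).
#'
#' The defaults encode the physiology the pipeline is designed to resolve:
#' gray-matter CBV responses are slow (capillary dilation; mean lag
#' approximately 6 s, slightly later superficially) and keep growing with
#' stimulus duration; vessel CBV responds fast (active arterial dilation)
#' but saturates by 2 s of stimulation (`cap` equals the peak of the 2 s
#' boxcar convolution, so 2 s and 24 s stimuli give equal vessel peaks);
#' BOLD is strongly vessel-biased and increases toward the cortical surface
#' (draining-vein effect) without saturation.
#'
#' @return A tibble with columns `compartment`, `contrast`, `delay_s`,
#'   `mean_s`, `sd_s`, `amplitude` (fractional), `cap`.
#' @export
default_compartment_params <- function() {
  p <- tibble::tribble(
    ~compartment,       ~contrast, ~delay_s, ~mean_s, ~sd_s, ~amplitude, ~cap,
    "gm_deep",          "cbv",     0.5,      5.5,     3.0,   0.012,      Inf,
    "gm_middle",        "cbv",     0.5,      6.0,     3.0,   0.020,      Inf,
    "gm_superficial",   "cbv",     0.5,      6.5,     3.0,   0.016,      Inf,
    "vessel",           "cbv",     0.5,      2.5,     1.25,  0.022,      NA,
    "gm_deep",          "bold",    0.5,      5.0,     2.5,   0.010,      Inf,
    "gm_middle",        "bold",    0.5,      5.0,     2.5,   0.015,      Inf,
    "gm_superficial",   "bold",    0.5,      5.0,     2.5,   0.020,      Inf,
    "vessel",           "bold",    0.5,      5.5,     2.5,   0.050,      Inf
  )
  # vessel CBV ceiling: peak of the 2 s unit boxcar response, so stimuli of
  # 2 s and longer all reach the same (saturated) peak
  i <- which(p$compartment == "vessel" & p$contrast == "cbv")
  tg <- seq(0, 40, by = 0.005)
  p$cap[i] <- max(boxcar_gamma(tg, 2, p$mean_s[i], p$sd_s[i], p$delay_s[i]))
  p
}

#' Generative model of compartment hemodynamics and VASO signal formation
#'
#' Bundles the per-compartment CBV and BOLD response parameters with the
#' signal-formation constants of the interleaved nulled/BOLD acquisition:
#' baseline signal levels per tissue, the multiplicative BOLD-contamination
#' gain `g` of the nulled series, and the Gaussian noise level.
#'
#' Signal model per voxel (compartment responses `v(t)` = fractional CBV
#' response, `delta(t)` = fractional BOLD response):
#' \deqn{S_{bold}(t) = S0_b (1 + \delta(t))}
#' \deqn{S_{nulled}(t) = S0_n (1 - v(t)) (1 + g \delta(t))}
#' so dividing nulled by BOLD (BOLD-correction) cancels the contamination
#' when `g = 1` and both contrasts sample the response at the same times.
#'
#' @param params Response parameter tibble; see
#'   [default_compartment_params()].
#' @param bold_gain Contamination gain `g`. Default 1.
#' @param s0_nulled,s0_bold Named baseline signals per tissue
#'   (`gm`, `wm`, `csf`, `vessel`), arbitrary units.
#' @param tsnr_target Baseline temporal SNR of the nulled GM signal used to
#'   set the noise level when `noise_sd` is `NULL`. Default 15 (VASO-like).
#' @param noise_sd i.i.d. Gaussian noise sd (same for both contrasts);
#'   overrides `tsnr_target` when given.
#' @return An object of class `compartment_model`.
#' @export
compartment_model <- function(params = default_compartment_params(),
                              bold_gain = 1,
                              s0_nulled = c(gm = 100, wm = 130, csf = 60, vessel = 70),
                              s0_bold = c(gm = 100, wm = 90, csf = 110, vessel = 100),
                              tsnr_target = 15, noise_sd = NULL) {
  stopifnot(all(c("compartment", "contrast", "delay_s", "mean_s", "sd_s",
                  "amplitude", "cap") %in% names(params)),
            all(params$mean_s > 0), all(params$sd_s > 0),
            all(params$delay_s >= 0), all(params$cap >= 0))
  if (is.null(noise_sd)) noise_sd <- unname(s0_nulled[["gm"]]) / tsnr_target
  structure(list(params = params, bold_gain = bold_gain,
                 s0_nulled = s0_nulled, s0_bold = s0_bold,
                 noise_sd = noise_sd),
            class = "compartment_model")
}

get_params <- function(model, compartment, contrast) {
  p <- model$params[model$params$compartment == compartment &
                      model$params$contrast == contrast, ]
  if (nrow(p) != 1)
    stop("no (or ambiguous) parameters for ", compartment, "/", contrast)
  p
}

#' Response of one compartment to a single stimulus
#'
#' Fractional signal response of a compartment to a boxcar stimulus of the
#' given duration: the unit boxcar convolved with the compartment's
#' gamma-variate impulse response (closed form: difference of gamma CDFs),
#' clipped at the saturation ceiling `cap`, then scaled by the amplitude.
#' The analytic peak time and amplitude, evaluated on a fine grid (5 ms) and
#' with ties broken to the earliest time, are returned as ground truth for
#' recovery tests.
#'
#' @param duration_s Stimulus duration, seconds (> 0).
#' @param model A [compartment_model()].
#' @param compartment One of [compartment_names()].
#' @param contrast `"cbv"` or `"bold"`.
#' @param t_grid Time points (s, from stimulus onset) at which to evaluate
#'   the curve; should cover stimulus plus rest.
#' @return A list with `curve` (tibble `time_s`, `value`), `peak_time_s`,
#'   `peak_value`, and the parameter row used.
#' @export
compartment_response <- function(duration_s, model, compartment,
                                 contrast = c("cbv", "bold"),
                                 t_grid = seq(0, duration_s + 30, by = 0.1)) {
  contrast <- match.arg(contrast)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  p <- get_params(model, compartment, contrast)
  f <- function(t) p$amplitude *
    pmin(boxcar_gamma(t, duration_s, p$mean_s, p$sd_s, p$delay_s), p$cap)
  tf <- seq(min(t_grid), max(max(t_grid), duration_s + 30), by = 0.005)
  vf <- f(tf)
  i <- which.max(vf)  # which.max -> earliest tie
  list(curve = tibble::tibble(time_s = t_grid, value = f(t_grid)),
       peak_time_s = tf[i], peak_value = vf[i], params = p)
}

# total fractional response of one compartment over a run: sum of per-trial
# responses (trial windows do not overlap, so saturation stays per-trial)
run_response <- function(t, trials, model, compartment, contrast) {
  p <- get_params(model, compartment, contrast)
  out <- numeric(length(t))
  for (i in seq_len(nrow(trials))) {
    out <- out + p$amplitude *
      pmin(boxcar_gamma(t - trials$onset_s[i], trials$duration_s[i],
                        p$mean_s, p$sd_s, p$delay_s), p$cap)
  }
  out
}
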