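#' Write a volume series or 3D map to NIfTI
#'
#' @param x A [volume_series()] or a 3D array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, voxel_mm = 0.9) {
  dat <- if (inherits(x, "volume_series")) x$data else x
  img <- RNifti::asNifti(dat)
  pd <- c(voxel_mm, voxel_mm, voxel_mm)
  if (inherits(x, "volume_series")) pd <- c(pd, x$dt_s)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume series
#'
#' @param path NIfTI path.
#' @param contrast Contrast tag for 4D input.
#' @param dt_s,origin_s Timing; `dt_s` defaults to the header's repetition
#'   time.
#' @return A [volume_series()] for 4D input, a plain array otherwise.
#' @export
read_volume <- function(path, contrast = c("nulled", "bold", "vaso"),
                        dt_s = NULL, origin_s = 0) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) < 4) return(arr)
  if (is.null(dt_s)) dt_s <- RNifti::pixdim(img)[4]
  volume_series(arr, match.arg(contrast), dt_s, origin_s)
}

#' Write a stimulus design as BIDS-style events files
#'
#' One tab-separated events file per run with columns `onset`, `duration`,
#' `trial_type` (`stim_<d>s`).
#'
#' @param design A [make_design()] tibble.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_events <- function(design, dir, prefix = "task") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sort(unique(design$run)), function(r) {
    d <- design[design$run == r, ]
    tab <- data.frame(onset = d$onset_s, duration = d$duration_s,
                      trial_type = paste0("stim_", d$duration_s, "s"))
    p <- file.path(dir, sprintf("%s_run-%02d_events.tsv", prefix, r))
    utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a BIDS-style events file
#' @param path Events TSV path.
#' @return Tibble with `onset_s`, `duration_s`, `trial_type`.
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path)
  tibble::tibble(onset_s = d$onset, duration_s = d$duration,
                 trial_type = d$trial_type)
}

#' Write / read a 6-column rigid motion trace
#' @param motion Tibble with 3 translations (mm) and 3 rotations (rad).
#' @param path TSV path.
#' @return `write_motion`: the path, invisibly; `read_motion`: a tibble.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) tibble::as_tibble(utils::read.delim(path))

#' Write a full simulated run to disk
#'
#' NIfTI volumes (nulled, BOLD, labels, vessel mask), BIDS-style events,
#' motion TSV and a ground-truth JSON (generative parameters and analytic
#' peaks).
#'
#' @param sim A [simulate_participant()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geo <- sim$geometry
  write_volume(geo$labels, file.path(dir, "labels.nii.gz"), geo$voxel_mm)
  write_volume((geo$labels == geo$codes[["vessel"]]) * 1,
               file.path(dir, "vessel_mask.nii.gz"), geo$voxel_mm)
  for (i in seq_along(sim$runs)) {
    run <- sim$runs[[i]]
    write_volume(run$nulled,
                 file.path(dir, sprintf("run-%02d_nulled.nii.gz", i)),
                 geo$voxel_mm)
    write_volume(run$bold,
                 file.path(dir, sprintf("run-%02d_bold.nii.gz", i)),
                 geo$voxel_mm)
    write_motion(run$motion,
                 file.path(dir, sprintf("run-%02d_motion.tsv", i)))
  }
  if (!is.null(sim$design_short))
    write_events(sim$design_short, dir, "short")
  if (!is.null(sim$design_long))
    write_events(sim$design_long, dir, "long")
  truth <- list(peaks = as.data.frame(sim$runs[[1]]$truth$peaks),
                params = as.data.frame(sim$model$params),
                bold_gain = sim$model$bold_gain,
                noise_sd = sim$model$noise_sd,
                seed = sim$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate from a YAML configuration file
#'
#' The configuration may override any of: `grid_shape`, `annulus_radii`,
#' `n_vessels`, `voxel_mm`, `block_s`, `n_jitters`, `n_short`, `n_long`,
#' `bold_gain`, `tsnr_target`, `noise` (logical), `motion_sd`, and a
#' `params` table (list of records with the [default_compartment_params()]
#' columns).
#'
#' @param config Path to a YAML file (or a pre-parsed list).
#' @param out_dir Optional directory; when given the simulation is written
#'   with [write_simulation()].
#' @param seed Integer seed.
#' @return The [simulate_participant()] result, invisibly when written.
#' @export
simulate_from_config <- function(config, out_dir = NULL, seed = 1) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  geo <- build_geometry(
    grid_shape = unlist(cfg$grid_shape) %||% c(40, 40, 10),
    annulus_radii = unlist(cfg$annulus_radii) %||% c(10, 16),
    n_vessels = cfg$n_vessels %||% 4, seed = seed,
    voxel_mm = cfg$voxel_mm %||% 0.9)
  acq <- acq_scheme(block_s = cfg$block_s %||% 0.785,
                    n_jitters = cfg$n_jitters %||% 4L)
  params <- if (is.null(cfg$params)) default_compartment_params()
  else dplyr::bind_rows(lapply(cfg$params, tibble::as_tibble))
  model <- compartment_model(params = params,
                             bold_gain = cfg$bold_gain %||% 1,
                             tsnr_target = cfg$tsnr_target %||% 15)
  sim <- simulate_participant(geo, acq, model,
                              n_short = cfg$n_short %||% 2,
                              n_long = cfg$n_long %||% 2,
                              seed = seed,
                              noise = cfg$noise %||% TRUE,
                              motion_sd = cfg$motion_sd %||% 0)
  if (!is.null(out_dir)) {
    write_simulation(sim, out_dir)
    return(invisible(sim))
  }
  sim
}
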