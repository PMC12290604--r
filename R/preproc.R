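#' Framewise displacement from rigid motion parameters
#'
#' Scalar head-motion summary per volume pair: the sum of absolute
#' translation differences plus the rotation differences converted to arc
#' length on a nominal head radius,
#' `FD_t = sum |d trans_i| + r * sum |d rot_i|`.
#'
#' @param trace Data frame with one row per volume and six columns: three
#'   translations (mm) then three rotations (radians), e.g. the `motion`
#'   element of [simulate_run()].
#' @param head_radius_mm Nominal head radius for the rotation arc length;
#'   default 50 mm.
#' @return A tibble with columns `frame` (index of the later volume of each
#'   pair, `2:n`) and `fd_mm`; zero rows for a single-volume trace.
#' @export
framewise_displacement <- function(trace, head_radius_mm = 50) {
  m <- as.matrix(trace)
  stopifnot(ncol(m) == 6, all(is.finite(m)))
  if (nrow(m) < 2)
    return(tibble::tibble(frame = integer(0), fd_mm = numeric(0)))
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  tibble::tibble(frame = 2:nrow(m), fd_mm = unname(fd))
}

#' Flag volumes displaced by more than a threshold
#'
#' @param fd An FD tibble from [framewise_displacement()] or a bare numeric
#'   FD series.
#' @param threshold_mm Displacement threshold; the convention is the voxel
#'   size (0.9 mm for the nominal acquisition).
#' @return Sorted integer positions (1-based) in the FD series exceeding the
#'   threshold.
#' @export
flag_high_motion <- function(fd, threshold_mm = 0.9) {
  stopifnot(threshold_mm > 0)
  v <- if (is.data.frame(fd)) fd$fd_mm else as.numeric(fd)
  sort(which(v > threshold_mm))
}

#' Voxelwise average of several runs
#'
#' @param series_list List of [volume_series()] objects on identical grids,
#'   with equal lengths, timing and contrast tags.
#' @return A [volume_series()] with the arithmetic mean.
#' @export
average_runs <- function(series_list) {
  stopifnot(length(series_list) >= 1,
            all(vapply(series_list, inherits, logical(1), "volume_series")))
  ref <- series_list[[1]]
  for (s in series_list[-1]) {
    if (!identical(dim(s$data), dim(ref$data)) ||
        !identical(s$contrast, ref$contrast) ||
        abs(s$dt_s - ref$dt_s) > 1e-9 || abs(s$origin_s - ref$origin_s) > 1e-9)
      stop("runs differ in grid, length, timing or contrast")
  }
  acc <- Reduce(`+`, lapply(series_list, `[[`, "data"))
  volume_series(acc / length(series_list), ref$contrast, ref$dt_s,
                ref$origin_s, ref$measured)
}

# linear upsampling of a time dimension with edge-hold beyond the last
# original sample; original samples preserved at stride `factor`
upsample_values <- function(m, factor) {
  n <- ncol(m)
  idx <- (seq_len(n * factor) - 1) / factor + 1   # fractional original index
  lo <- pmin(floor(idx), n); hi <- pmin(lo + 1, n)
  w <- idx - floor(idx)
  m[, lo, drop = FALSE] * rep(1 - w, each = nrow(m)) +
    m[, hi, drop = FALSE] * rep(w, each = nrow(m))
}

#' Temporal upsampling of a volume series
#'
#' Upsamples by an integer factor to match the jittered stimulus-onset grid
#' (4x for the default scheme: volume-pair TR 3.14 s to the 0.785 s grid).
#' Original samples are preserved at stride `factor`; in-between samples are
#' filled by linear interpolation; samples beyond the last original volume
#' hold the edge value. The `measured` flag marks the original samples.
#'
#' @param series A [volume_series()] or [sampled_series()].
#' @param factor Integer >= 1.
#' @param method Interpolation kernel; only `"linear"` is implemented.
#' @return The upsampled series (same class), with `dt_s / factor`.
#' @export
upsample_temporal <- function(series, factor = 4, method = "linear") {
  stopifnot(factor >= 1, factor == round(factor))
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (factor == 1L) return(series)
  n <- n_vols(series)
  measured <- rep(FALSE, n * factor)
  measured[seq(1, by = factor, length.out = n)] <- series$measured
  if (inherits(series, "sampled_series")) {
    v <- upsample_values(matrix(series$values, 1), factor)
    return(sampled_series(as.vector(v), series$contrast, series$dt_s / factor,
                          series$origin_s, measured))
  }
  stopifnot(inherits(series, "volume_series"))
  dims <- dim(series$data)
  m <- matrix(series$data, prod(dims[1:3]), dims[4])
  out <- upsample_values(m, factor)
  volume_series(array(out, c(dims[1:3], dims[4] * factor)), series$contrast,
                series$dt_s / factor, series$origin_s, measured)
}

#' BOLD-contamination correction by dynamic division (BOCO)
#'
#' Divides the nulled series voxelwise by the BOLD series to remove the
#' multiplicative T2* contamination from the CBV-weighted signal, yielding
#' the BOLD-corrected VASO series. If the BOLD series is one volume short,
#' its first volume is duplicated to match (the first nulled volume precedes
#' the first BOLD readout). Voxels whose BOLD magnitude falls below
#' `guard_rel` times their temporal mean magnitude are flagged invalid
#' (`NaN`) rather than producing infinities.
#'
#' @param nulled,bold [volume_series()] objects on the same grid (both
#'   native-rate or both upsampled).
#' @param guard_rel Relative division guard; default `1e-6`.
#' @return A [volume_series()] with contrast `"vaso"`, on the nulled
#'   series' timing; `measured` is the elementwise AND of the inputs'.
#' @export
boco <- function(nulled, bold, guard_rel = 1e-6) {
  stopifnot(inherits(nulled, "volume_series"), inherits(bold, "volume_series"),
            nulled$contrast == "nulled", bold$contrast == "bold",
            identical(dim(nulled$data)[1:3], dim(bold$data)[1:3]),
            abs(nulled$dt_s - bold$dt_s) < 1e-9)
  nn <- n_vols(nulled); nb <- n_vols(bold)
  bdat <- bold$data
  bmeas <- bold$measured
  if (nb == nn - 1L) {
    bdat <- array(c(bdat[, , , 1L], bdat), dim = dim(nulled$data))
    bmeas <- c(bmeas[1L], bmeas)
  } else if (nb != nn) {
    stop("nulled and BOLD lengths differ by more than one volume")
  }
  V <- prod(dim(nulled$data)[1:3])
  num <- matrix(nulled$data, V, nn)
  den <- matrix(bdat, V, nn)
  floor_v <- guard_rel * rowMeans(abs(den))
  bad <- abs(den) <= pmax(floor_v, .Machine$double.xmin)
  out <- num / den
  out[bad] <- NaN
  volume_series(array(out, dim(nulled$data)), "vaso", nulled$dt_s,
                nulled$origin_s, nulled$measured & bmeas)
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise temporal mean divided by temporal standard deviation.
#' Zero-variance voxels are flagged `NaN`.
#'
#' @param series A [volume_series()] with at least two volumes.
#' @return 3D array.
#' @export
tsnr <- function(series) {
  stopifnot(inherits(series, "volume_series"), n_vols(series) >= 2)
  dims <- dim(series$data)
  m <- matrix(series$data, prod(dims[1:3]), dims[4])
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (dims[4] - 1))
  out <- mu / sd
  out[sd == 0] <- NaN
  array(out, dims[1:3])
}

#' T1-weighted map as the inverse coefficient of variation
#'
#' Computes `mean / sd` of the concatenated nulled and BOLD time series per
#' voxel (1/CV). The long T1 relaxation of the symmetric acquisition makes
#' this map strongly T1-weighted, useful for registration QC.
#'
#' @param nulled,bold [volume_series()] objects on the same spatial grid.
#' @return 3D array; `NaN` where the pooled sd is zero.
#' @export
t1w_from_cv <- function(nulled, bold) {
  stopifnot(inherits(nulled, "volume_series"), inherits(bold, "volume_series"),
            identical(dim(nulled$data)[1:3], dim(bold$data)[1:3]))
  dims <- dim(nulled$data)[1:3]
  m <- cbind(matrix(nulled$data, prod(dims), n_vols(nulled)),
             matrix(bold$data, prod(dims), n_vols(bold)))
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  out <- mu / sd
  out[sd == 0] <- NaN
  array(out, dims)
}
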