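#' 4D volume time series
#'
#' A light container for a 4D scalar field (x, y, z, t) with a contrast tag,
#' sampling interval, the offset of the first sample within the acquisition
#' cycle, and an optional per-timepoint `measured` flag distinguishing
#' original volumes from interpolated ones after temporal upsampling.
#'
#' @param data 4D numeric array.
#' @param contrast `"nulled"`, `"bold"` or `"vaso"`.
#' @param dt_s Sampling interval, seconds (> 0).
#' @param origin_s Time of the first sample, seconds from run start.
#' @param measured Logical vector, one per timepoint; `NULL` means all
#'   measured.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, contrast = c("nulled", "bold", "vaso"),
                          dt_s, origin_s = 0, measured = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(is.array(data), length(dim(data)) == 4, dt_s > 0)
  n <- dim(data)[4]
  if (is.null(measured)) measured <- rep(TRUE, n)
  stopifnot(length(measured) == n)
  structure(list(data = data, contrast = contrast, dt_s = dt_s,
                 origin_s = origin_s, measured = measured),
            class = "volume_series")
}

#' @rdname volume_series
#' @param x A `volume_series` or `sampled_series`.
#' @export
n_vols <- function(x) {
  if (inherits(x, "volume_series")) dim(x$data)[4] else length(x$values)
}

#' @rdname volume_series
#' @export
series_times <- function(x) x$origin_s + (seq_len(n_vols(x)) - 1) * x$dt_s

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series %s> %s voxels x %d vols, dt %.3f s, origin %.3f s\n",
              x$contrast, paste(dim(x$data)[1:3], collapse = " x "),
              n_vols(x), x$dt_s, x$origin_s))
  invisible(x)
}

#' One-dimensional sampled signal
#'
#' A single time course (e.g. the mean over a mask) carrying the same timing
#' metadata as a [volume_series()].
#'
#' @param values Numeric vector.
#' @inheritParams volume_series
#' @return An object of class `sampled_series`.
#' @export
sampled_series <- function(values, contrast = c("nulled", "bold", "vaso"),
                           dt_s, origin_s = 0, measured = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(is.numeric(values), dt_s > 0)
  if (is.null(measured)) measured <- rep(TRUE, length(values))
  stopifnot(length(measured) == length(values))
  structure(list(values = as.numeric(values), contrast = contrast,
                 dt_s = dt_s, origin_s = origin_s, measured = measured),
            class = "sampled_series")
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf("<sampled_series %s> %d samples, dt %.3f s, origin %.3f s\n",
              x$contrast, n_vols(x), x$dt_s, x$origin_s))
  invisible(x)
}

#' Mean time course within a voxel mask
#'
#' @param series A [volume_series()].
#' @param mask Logical or 0/1 3D array matching the series grid.
#' @return A [sampled_series()].
#' @export
roi_mean_series <- function(series, mask) {
  stopifnot(inherits(series, "volume_series"))
  mask <- array(as.logical(mask), dim = dim(mask))
  stopifnot(identical(dim(mask), dim(series$data)[1:3]), any(mask))
  m <- matrix(series$data, prod(dim(series$data)[1:3]), n_vols(series))
  vals <- colMeans(m[as.vector(mask), , drop = FALSE])
  sampled_series(vals, series$contrast, series$dt_s, series$origin_s,
                 series$measured)
}
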