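#' Canonical gamma hemodynamic response kernel
#'
#' Gamma-density HRF parameterized by its mean lag and standard deviation
#' via moment matching (`shape = (mean/sd)^2`, `scale = sd^2/mean`), sampled
#' at `dt` and normalized to unit area. Defaults: mean lag 6 s, sd 3 s
#' (shape 4, scale 1.5, mode at 4.5 s).
#'
#' @param mean_lag_s,sd_s Kernel mean and sd, seconds.
#' @param dt Sampling interval, seconds.
#' @param length_s Kernel support, seconds; default 32.
#' @return A tibble of class `hrf_kernel` with columns `time_s`, `value`,
#'   and attributes `dt`, `mean_lag_s`, `sd_s`.
#' @export
gamma_hrf <- function(mean_lag_s = 6, sd_s = 3, dt = 0.785, length_s = 32) {
  stopifnot(mean_lag_s > 0, sd_s > 0, dt > 0)
  t <- seq(0, length_s, by = dt)
  v <- gamma_variate(t, mean_lag_s, sd_s)
  v <- v / (sum(v) * dt)
  structure(tibble::new_tibble(tibble::tibble(time_s = t, value = v),
                               class = "hrf_kernel"),
            dt = dt, mean_lag_s = mean_lag_s, sd_s = sd_s)
}

#' Discrete first and second moments of a sampled kernel
#' @param hrf An [gamma_hrf()] kernel.
#' @return Named vector: `mean_s`, `sd_s`.
#' @export
hrf_moments <- function(hrf) {
  w <- hrf$value / sum(hrf$value)
  m <- sum(w * hrf$time_s)
  c(mean_s = m, sd_s = sqrt(sum(w * (hrf$time_s - m)^2)))
}

#' Discrete-cosine high-pass drift basis
#'
#' DCT regressors spanning the drift frequencies below the cutoff:
#' `K = floor(2 * T * cutoff_hz)` columns for a run of total duration
#' `T = n_vols * dt`, i.e. drifts with period longer than `1/cutoff`
#' (100 s at the default 0.01 Hz). Columns are mutually orthogonal.
#'
#' @param n_vols Number of volumes (>= 2).
#' @param dt Volume sampling interval, seconds.
#' @param cutoff_hz High-pass cutoff; 0 yields no columns.
#' @return `n_vols x K` matrix (possibly zero columns).
#' @export
highpass_basis <- function(n_vols, dt, cutoff_hz = 0.01) {
  stopifnot(n_vols >= 2, dt > 0, cutoff_hz >= 0)
  K <- floor(2 * n_vols * dt * cutoff_hz)
  K <- min(K, n_vols - 1)
  n <- n_vols
  if (K < 1) return(matrix(numeric(0), n, 0))
  k <- seq_len(K)
  m <- outer(seq_len(n) - 0.5, k, function(i, k) cos(pi * k * i / n))
  colnames(m) <- paste0("dct_", k)
  m
}

#' Build the GLM design matrix for a run
#'
#' One regressor per stimulus duration: the boxcar of all trials of that
#' duration convolved with the gamma HRF on a fine grid, sampled at the
#' volume acquisition times; plus an intercept and the discrete-cosine
#' drift columns.
#'
#' @param design A [make_design()] tibble (one run).
#' @param hrf A [gamma_hrf()] kernel (its `dt` sets the convolution grid).
#' @param n_vols Number of volumes in the series.
#' @param dt Volume sampling interval, seconds.
#' @param cutoff_hz High-pass cutoff for the drift columns; default 0.01.
#' @param run Which run of the design; default 1.
#' @param origin_s Time of the first volume, seconds.
#' @return Numeric matrix `n_vols x (n_durations + 1 + K)` with named
#'   columns (`stim_<d>s`, `intercept`, `dct_k`); errors on rank deficiency
#'   or an all-zero stimulus column.
#' @export
build_design_matrix <- function(design, hrf, n_vols, dt, cutoff_hz = 0.01,
                                run = 1, origin_s = 0) {
  trials <- design[design$run == run, ]
  stopifnot(nrow(trials) > 0, n_vols >= 2)
  durations <- sort(unique(trials$duration_s))
  fine_dt <- attr(hrf, "dt")
  t_end <- origin_s + (n_vols - 1) * dt + max(hrf$time_s) + max(durations)
  tf <- seq(0, t_end, by = fine_dt)
  vol_t <- origin_s + (seq_len(n_vols) - 1) * dt
  cols <- vapply(durations, function(d) {
    tr <- trials[trials$duration_s == d, ]
    box <- rowSums(vapply(seq_len(nrow(tr)), function(i) {
      as.numeric(tf >= tr$onset_s[i] & tf < tr$onset_s[i] + d)
    }, numeric(length(tf))))
    nf <- nrow(hrf)
    regfull <- stats::filter(c(numeric(nf - 1), box), hrf$value * fine_dt,
                             method = "convolution", sides = 1)
    reg <- as.numeric(regfull)[(nf - 1) + seq_along(tf)]
    stats::approx(tf, reg, xout = vol_t, rule = 2)$y
  }, numeric(n_vols))
  colnames(cols) <- paste0("stim_", durations, "s")
  if (any(apply(cols, 2, function(x) all(abs(x) < 1e-12))))
    stop("a stimulus condition produces an all-zero regressor")
  X <- cbind(cols, intercept = rep(1, n_vols),
             highpass_basis(n_vols, dt, cutoff_hz))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (", ncol(X), " columns, rank ",
         qr(X)$rank, ")")
  X
}

#' Fit a voxelwise ordinary-least-squares GLM
#'
#' OLS fit of each voxel's time course on the design matrix, with
#' t-statistics for a contrast of the coefficients converted to z-scores by
#' CDF matching at the residual degrees of freedom
#' (`z = qnorm(pt(t, df))`, computed on the log scale for stability).
#' Voxels with zero residual variance are flagged (`NaN` statistics).
#'
#' @param series A [volume_series()], [sampled_series()], or a numeric
#'   matrix `n_vols x n_voxels`.
#' @param X Design matrix from [build_design_matrix()] (full column rank).
#' @param contrast_vector Numeric contrast across columns of `X`; by default
#'   the mean of all `stim_*` columns against baseline.
#' @return An object of class `vaso_glm`: list with `beta` (p x V),
#'   `sigma2`, `df`, `t`, `z` (length-V vectors for the contrast),
#'   `contrast_vector`, `terms`, and `dims` (spatial grid, if any).
#' @export
fit_glm <- function(series, X, contrast_vector = NULL) {
  dims <- NULL
  if (inherits(series, "volume_series")) {
    dims <- dim(series$data)[1:3]
    Y <- t(matrix(series$data, prod(dims), dim(series$data)[4]))
  } else if (inherits(series, "sampled_series")) {
    Y <- matrix(series$values, ncol = 1)
  } else {
    Y <- as.matrix(series)
  }
  stopifnot(nrow(Y) == nrow(X))
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - p
  sigma2 <- colSums(res^2) / df
  if (is.null(contrast_vector)) {
    contrast_vector <- as.numeric(grepl("^stim_", colnames(X)))
    contrast_vector <- contrast_vector / sum(contrast_vector)
  }
  stopifnot(length(contrast_vector) == p)
  xtx_inv <- chol2inv(qr.R(qrx))
  cvar <- drop(t(contrast_vector) %*% xtx_inv %*% contrast_vector)
  tval <- drop(crossprod(contrast_vector, beta)) / sqrt(sigma2 * cvar)
  tval[sigma2 <= 0] <- NaN
  z <- t_to_z(tval, df)
  structure(list(beta = beta, sigma2 = sigma2, df = df, t = tval, z = z,
                 contrast_vector = contrast_vector, terms = colnames(X),
                 dims = dims),
            class = "vaso_glm")
}

# t -> z by matching tail probabilities at df degrees of freedom (log scale)
t_to_z <- function(t, df) {
  z <- rep(NaN, length(t))
  ok <- is.finite(t)
  lp <- stats::pt(t[ok], df, lower.tail = FALSE, log.p = TRUE)
  z[ok] <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z
}

#' Reshape a fitted statistic to the spatial grid
#' @param fit A [fit_glm()] result with spatial dims.
#' @param what `"z"`, `"t"`, or the name of a design column (beta map).
#' @return 3D array.
#' @export
stat_map <- function(fit, what = "z") {
  stopifnot(inherits(fit, "vaso_glm"), !is.null(fit$dims))
  v <- if (what %in% c("z", "t")) fit[[what]]
  else fit$beta[match(what, fit$terms), ]
  array(v, fit$dims)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a voxelwise GLM fit
#'
#' @param x A `vaso_glm`.
#' @param ... Unused.
#' @return Tibble with one row per (voxel, term): `voxel`, `term`,
#'   `estimate`, plus per-voxel `statistic` (t) and `z` on the contrast.
#' @export
tidy.vaso_glm <- function(x, ...) {
  p <- nrow(x$beta); V <- ncol(x$beta)
  tibble::tibble(voxel = rep(seq_len(V), each = p),
                 term = rep(x$terms, V),
                 estimate = as.vector(x$beta),
                 statistic = rep(x$t, each = p),
                 z = rep(x$z, each = p))
}

#' @rdname tidy.vaso_glm
#' @return For `glance`: one-row tibble with `n_voxels`, `n_terms`,
#'   `df_residual`, `median_sigma2`.
#' @export
glance.vaso_glm <- function(x, ...) {
  tibble::tibble(n_voxels = ncol(x$beta), n_terms = nrow(x$beta),
                 df_residual = x$df,
                 median_sigma2 = stats::median(x$sigma2, na.rm = TRUE))
}

#' Fixed-effects combination of session z-maps
#'
#' Stouffer combination across sessions: `z_comb = sum(z_i) / sqrt(k)`.
#'
#' @param zmaps List of z arrays (or vectors) on one grid.
#' @return Combined array of the same shape.
#' @export
combine_sessions <- function(zmaps) {
  stopifnot(length(zmaps) >= 1)
  d1 <- dim(zmaps[[1]])
  for (z in zmaps[-1])
    if (!identical(dim(z), d1)) stop("session maps are on different grids")
  Reduce(`+`, zmaps) / sqrt(length(zmaps))
}

#' Depth profile of a statistic map
#'
#' Mean statistic per cortical layer bin within an ROI.
#'
#' @param stat_map 3D statistic array (z or % change).
#' @param layer_map Integer layer array from [bin_layers()].
#' @param roi Optional logical mask restricting the profile.
#' @param n_layers Number of layers; default `max(layer_map)`.
#' @return Tibble `layer`, `value`, `n_voxels`; empty layers yield `NA`
#'   value with `n_voxels = 0`.
#' @export
layer_profile <- function(stat_map, layer_map, roi = NULL, n_layers = NULL) {
  stopifnot(identical(dim(stat_map), dim(layer_map)))
  keep <- !is.na(layer_map)
  if (!is.null(roi)) keep <- keep & as.logical(roi)
  lay <- layer_map[keep]; val <- stat_map[keep]
  if (is.null(n_layers)) n_layers <- max(lay)
  purrr::map_dfr(seq_len(n_layers), function(L) {
    v <- val[lay == L]
    tibble::tibble(layer = L,
                   value = if (length(v)) mean(v, na.rm = TRUE) else NA_real_,
                   n_voxels = length(v))
  })
}

#' Min-max normalise a layer profile
#'
#' Rescales `value` to `[0, 1]` (per duration group if a `duration_s`
#' column is present), to compare profile shapes across conditions.
#'
#' @param profile Tibble with a `value` column (e.g. [layer_profile()]).
#' @return The profile with a `value_norm` column.
#' @export
minmax_normalise <- function(profile) {
  norm1 <- function(x) {
    r <- range(x, na.rm = TRUE)
    if (diff(r) == 0) stop("cannot min-max normalise a constant profile")
    (x - r[1]) / diff(r)
  }
  if ("duration_s" %in% names(profile))
    dplyr::mutate(profile, value_norm = norm1(.data$value), .by = "duration_s")
  else dplyr::mutate(profile, value_norm = norm1(.data$value))
}
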