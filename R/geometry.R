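#' Tissue label codes used by the simulator and layering code
#' @return Named integer vector.
#' @export
tissue_codes <- function() {
  c(background = 0L, csf = 1L, gm = 2L, wm = 3L, vessel = 4L)
}

#' Build a synthetic layered-cortex geometry
#'
#' Generates a ground-truth label volume for the simulator: a cylindrical
#' gray-matter (GM) annulus (a curved cortical ribbon) wrapped around white
#' matter (WM), surrounded by CSF, with optional vessel-dominated voxel
#' "tubes" in the CSF immediately outside the GM/CSF boundary — the
#' synthetic stand-in for pial vessels segmented from anatomical data. The
#' annulus has a closed-form equivolume depth, `(r^2 - r_in^2) /
#' (r_out^2 - r_in^2)` at radius `r`, which is stored as generator ground
#' truth along with a compartment map splitting GM into equivolume
#' deep/middle/superficial thirds.
#'
#' @param grid_shape Integer vector of length 3, voxels. Default
#'   `c(40, 40, 10)`.
#' @param annulus_radii Inner (WM/GM) and outer (GM/CSF) boundary radii in
#'   voxels. Default `c(10, 16)`.
#' @param n_vessels Number of vessel tubes (>= 0). Default 4.
#' @param seed Optional integer seed (vessel placement).
#' @param voxel_mm Isotropic voxel size in mm (nominal 0.9).
#' @param roi_radius_mm Radius of the default disc ROI, mm.
#'
#' @return An object of class `vaso_geometry`: a list with `labels` (integer
#'   3D array coded per [tissue_codes()]), `depth_true` (analytic equivolume
#'   depth, `NA` outside GM), `compartments` (integer array: 0 none,
#'   1 GM-deep, 2 GM-middle, 3 GM-superficial, 4 vessel),
#'   `vessel_voxels` (n x 3 index matrix), plus the generating parameters.
#' @examples
#' geo <- build_geometry(seed = 1)
#' table(geo$labels)
#' @export
build_geometry <- function(grid_shape = c(40, 40, 10),
                           annulus_radii = c(10, 16),
                           n_vessels = 4, seed = NULL,
                           voxel_mm = 0.9, roi_radius_mm = 5.4) {
  stopifnot(length(grid_shape) == 3, length(annulus_radii) == 2,
            annulus_radii[1] > 0, annulus_radii[2] > annulus_radii[1],
            n_vessels >= 0)
  r_in <- annulus_radii[1]; r_out <- annulus_radii[2]
  cx <- (grid_shape[1] + 1) / 2; cy <- (grid_shape[2] + 1) / 2
  if (r_out + 3 > min(cx, cy, grid_shape[1] - cx, grid_shape[2] - cy) + 1)
    stop("annulus (plus a CSF margin) does not fit in the grid")

  codes <- tissue_codes()
  x <- seq_len(grid_shape[1]); y <- seq_len(grid_shape[2])
  r2d <- sqrt(outer((x - cx)^2, (y - cy)^2, `+`))
  slice <- array(codes[["csf"]], dim = grid_shape[1:2])
  slice[r2d < r_in] <- codes[["wm"]]
  slice[r2d >= r_in & r2d < r_out] <- codes[["gm"]]
  labels <- array(rep(slice, grid_shape[3]), dim = grid_shape)

  depth_slice <- array(NA_real_, dim = grid_shape[1:2])
  gm2d <- slice == codes[["gm"]]
  depth_slice[gm2d] <- (r2d[gm2d]^2 - r_in^2) / (r_out^2 - r_in^2)
  depth_true <- array(rep(depth_slice, grid_shape[3]), dim = grid_shape)

  # vessel tubes: CSF voxels within 1 voxel of a vertical line just outside
  # the GM/CSF boundary, spanning all slices (tube-like, touching GM)
  place_vessels <- function() {
    if (n_vessels == 0) return(matrix(numeric(0), ncol = 2))
    theta <- stats::runif(n_vessels, 0, 2 * pi)
    cbind(cx + (r_out + 0.8) * cos(theta), cy + (r_out + 0.8) * sin(theta))
  }
  centers <- if (is.null(seed)) place_vessels() else withr::with_seed(seed, place_vessels())
  vmask2d <- array(FALSE, dim = grid_shape[1:2])
  if (nrow(centers) > 0) {
    for (k in seq_len(nrow(centers))) {
      d2 <- outer((x - centers[k, 1])^2, (y - centers[k, 2])^2, `+`)
      vmask2d <- vmask2d | (d2 <= 1.2^2 & slice == codes[["csf"]])
    }
  }
  if (any(vmask2d)) {
    vslice <- slice
    vslice[vmask2d] <- codes[["vessel"]]
    labels <- array(rep(vslice, grid_shape[3]), dim = grid_shape)
  }
  vessel_voxels <- which(labels == codes[["vessel"]], arr.ind = TRUE)

  compartments <- array(0L, dim = grid_shape)
  gm <- labels == codes[["gm"]]
  compartments[gm & depth_true < 1 / 3] <- 1L
  compartments[gm & depth_true >= 1 / 3 & depth_true < 2 / 3] <- 2L
  compartments[gm & depth_true >= 2 / 3] <- 3L
  compartments[labels == codes[["vessel"]]] <- 4L

  # ROI center: a mid-depth GM voxel at angle 0, middle slice
  roi_center <- c(round(cx + sqrt((r_in^2 + r_out^2) / 2)), round(cy),
                  ceiling(grid_shape[3] / 2))

  structure(list(labels = labels, codes = codes, depth_true = depth_true,
                 compartments = compartments, vessel_voxels = vessel_voxels,
                 grid_shape = grid_shape, annulus_radii = annulus_radii,
                 center_xy = c(cx, cy), voxel_mm = voxel_mm,
                 roi_center = roi_center, roi_radius_mm = roi_radius_mm,
                 n_vessels = n_vessels, seed = seed),
            class = "vaso_geometry")
}

#' Names of the simulated hemodynamic compartments
#' @return Character vector in compartment-code order (codes 1 to 4).
#' @export
compartment_names <- function() c("gm_deep", "gm_middle", "gm_superficial", "vessel")

#' @export
print.vaso_geometry <- function(x, ...) {
  cat("<vaso_geometry>", paste(x$grid_shape, collapse = " x "),
      sprintf("voxels @ %.2f mm\n", x$voxel_mm))
  tab <- table(factor(x$labels, levels = x$codes, labels = names(x$codes)))
  print(tab)
  invisible(x)
}
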