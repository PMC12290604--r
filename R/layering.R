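# --- small geometry helpers ------------------------------------------------

# exact Euclidean distance from each query voxel to the nearest voxel of a
# target set, computed in chunks (query and target sets here are a few
# thousand voxels, so brute force is fast and exact)
dist_to_set <- function(query, target, chunk = 2048L) {
  stopifnot(ncol(query) == 3, ncol(target) == 3, nrow(target) > 0)
  out <- numeric(nrow(query))
  t2 <- rowSums(target^2)
  for (i in seq(1, nrow(query), by = chunk)) {
    j <- min(i + chunk - 1L, nrow(query))
    q <- query[i:j, , drop = FALSE]
    d2 <- outer(rowSums(q^2), t2, `+`) - 2 * q %*% t(target)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# 26-connected dilation of a logical array by one voxel
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

# replicate-edge shift of a 3D array along one axis
shift_axis <- function(a, axis, s) {
  d <- dim(a)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- pmin(pmax(idx[[axis]] + s, 1L), d[axis])
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# separable 3^3 box smoothing (NA-aware when the array contains NAs)
box_smooth <- function(a, passes = 1) {
  has_na <- anyNA(a)
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      if (has_na) {
        v <- ifelse(is.na(a), 0, a); w <- !is.na(a)
        num <- shift_axis(v, ax, -1L) + v + shift_axis(v, ax, 1L)
        den <- shift_axis(w, ax, -1L) + w + shift_axis(w, ax, 1L)
        a <- ifelse(den > 0, num / den, NA_real_)
        a[!w] <- NA_real_   # keep the support fixed
      } else {
        a <- (shift_axis(a, ax, -1L) + a + shift_axis(a, ax, 1L)) / 3
      }
    }
  }
  a
}

# signed sub-voxel distance to the boundary of a label set: positive
# outside, negative inside, linear across the interface (center-to-center
# distances shifted by half a voxel)
signed_distance <- function(inside) {
  d <- dim(inside)
  out_idx <- which(!inside, arr.ind = TRUE)
  in_idx <- which(inside, arr.ind = TRUE)
  s <- array(NA_real_, d)
  s[!inside] <- dist_to_set(out_idx, in_idx) - 0.5
  s[inside] <- -(dist_to_set(in_idx, out_idx) - 0.5)
  s
}

# central differences (one-sided at NA/edges) of a 3D array along one axis
diff_axis <- function(a, axis) {
  d <- dim(a)
  shift <- function(s) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[axis]] <- pmin(pmax(idx[[axis]] + s, 1L), d[axis])
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  fwd <- shift(1L); bwd <- shift(-1L)
  g <- (fwd - bwd) / 2
  g[is.na(g) & !is.na(fwd)] <- (fwd - a)[is.na(g) & !is.na(fwd)]
  g[is.na(g) & !is.na(bwd)] <- (a - bwd)[is.na(g) & !is.na(bwd)]
  g
}

# --- depth map -------------------------------------------------------------

#' Normalized cortical depth over the gray-matter ribbon
#'
#' Computes voxelwise cortical depth in `[0, 1]` (0 at the WM/GM boundary,
#' 1 at the GM/CSF boundary) for every GM voxel of a label volume, by either
#' the equidistant or the equivolume principle.
#'
#' Equidistant depth is the normalized boundary-distance fraction
#' `alpha = d_wm / (d_wm + d_csf)` (distances to the nearest WM and CSF
#' voxel, corrected by half a voxel from center-to-center to
#' center-to-interface). Equivolume depth corrects `alpha` for cortical
#' curvature so that equal depth increments enclose equal local volume:
#' streamline cross-sections scale as `1 + K_w * alpha * T` with `T` the
#' local thickness and `K_w` the curvature of the WM boundary (estimated as
#' the divergence of the normalized gradient of `d_wm - d_csf`, propagated
#' from the voxel's level set to the WM boundary), giving the closed-form
#' volume fraction
#' `depth = (alpha + K_w T alpha^2 / 2) / (1 + K_w T / 2)`.
#' This reproduces the equivolume principle exactly for flat slabs
#' (`K_w = 0`, where it reduces to equidistant depth) and for cylindrically
#' curved ribbons such as the annulus test geometry, and to first order in
#' curvature elsewhere.
#'
#' @param labels A [build_geometry()] result or an integer label array coded
#'   per [tissue_codes()] (vessel voxels count as CSF for boundary finding).
#' @param method `"equivolume"` (default) or `"equidistant"`.
#' @return An object of class `depth_map`: list with `depth` (3D array,
#'   `NA` outside GM), `thickness` and `curvature` arrays, and `method`.
#' @export
depth_map <- function(labels, method = c("equivolume", "equidistant")) {
  method <- match.arg(method)
  lab <- if (inherits(labels, "vaso_geometry")) labels$labels else labels
  codes <- tissue_codes()
  gm <- lab == codes[["gm"]]
  wm <- lab == codes[["wm"]]
  csf <- lab == codes[["csf"]] | lab == codes[["vessel"]]
  if (!any(gm) || !any(wm) || !any(csf))
    stop("label volume must contain GM, WM and CSF voxels")

  d <- dim(lab)
  # smoothed signed sub-voxel boundary distances: linear across each
  # interface, so box smoothing is unbiased and strips the lattice noise of
  # nearest-voxel distances
  s_w <- box_smooth(signed_distance(wm), passes = 3)
  s_c <- box_smooth(signed_distance(csf), passes = 3)
  eps <- 0.02
  dw_a <- pmax(s_w, eps); dc_a <- pmax(s_c, eps)
  alpha <- dw_a / (dw_a + dc_a)
  alpha[!gm] <- NA_real_

  if (method == "equidistant") {
    depth <- alpha
    curv <- array(0, d); curv[!gm] <- NA_real_
  } else {
    psi <- s_w - s_c
    gx <- diff_axis(psi, 1); gy <- diff_axis(psi, 2); gz <- diff_axis(psi, 3)
    gn <- sqrt(gx^2 + gy^2 + gz^2)
    gn[gn < 1e-8] <- NA_real_
    nx <- gx / gn; ny <- gy / gn; nz <- gz / gn
    K <- diff_axis(nx, 1) + diff_axis(ny, 2) + diff_axis(nz, 3)
    # propagate the level-set curvature to the WM boundary along the column
    denom <- 1 - K * dw_a
    Kw <- ifelse(abs(denom) > 0.2, K / denom, 5 * K * sign(denom))
    Kw[!is.finite(Kw)] <- 0
    # curvature varies smoothly along the ribbon: average it over the
    # dilated GM neighbourhood to suppress differentiation noise
    Kw[!dilate1(dilate1(gm))] <- NA_real_
    Kw <- box_smooth(Kw, passes = 10)
    Kw[is.na(Kw)] <- 0
    Tk <- dw_a + dc_a
    depth <- (alpha + Kw * Tk * alpha^2 / 2) / (1 + Kw * Tk / 2)
    depth <- pmin(pmax(depth, 0), 1)
    depth[!gm] <- NA_real_
    curv <- Kw; curv[!gm] <- NA_real_
  }
  thickness <- dw_a + dc_a; thickness[!gm] <- NA_real_
  structure(list(depth = depth, thickness = thickness, curvature = curv,
                 method = method),
            class = "depth_map")
}

#' Bin cortical depth into discrete layers
#'
#' Equal-width depth bins; layer 1 is deepest (at the WM boundary). Under an
#' equivolume depth map, equal-width bins enclose (approximately) equal
#' volume.
#'
#' @param depth A [depth_map()] or a depth array.
#' @param n_layers Number of layers (>= 1); 3 for temporal analyses, 11 for
#'   layer profiles.
#' @return Integer 3D array of layer indices, `NA` outside GM.
#' @export
bin_layers <- function(depth, n_layers) {
  stopifnot(n_layers >= 1)
  d <- if (inherits(depth, "depth_map")) depth$depth else depth
  lay <- pmin(floor(d * n_layers) + 1L, as.integer(n_layers))
  storage.mode(lay) <- "integer"
  lay
}

#' Geodesic disc region of interest within the gray-matter ribbon
#'
#' Grows a disc around a center cortical column: GM voxels whose
#' within-ribbon tangential geodesic distance to the center column is at
#' most `radius_mm`. Distances are shortest paths on the 26-connected GM
#' voxel graph with each step weighted by its component tangential to the
#' local depth gradient, so travel along a column is free and the ROI spans
#' all depths. This is a simplified stand-in for a full cortical (U,V)
#' parametrization, adequate for smooth synthetic ribbons.
#'
#' @param labels A [build_geometry()] result or label array.
#' @param depth A [depth_map()] for the same labels.
#' @param center_voxel Length-3 voxel index of the disc center (must be GM);
#'   defaults to the geometry's stored ROI center.
#' @param radius_mm Disc radius in mm; defaults to the geometry's stored ROI
#'   radius.
#' @param voxel_mm Isotropic voxel size, mm.
#' @return Logical 3D array (the ROI mask).
#' @export
disc_roi <- function(labels, depth, center_voxel = NULL, radius_mm = NULL,
                     voxel_mm = NULL) {
  geo <- if (inherits(labels, "vaso_geometry")) labels else NULL
  lab <- if (is.null(geo)) labels else geo$labels
  if (is.null(center_voxel)) center_voxel <- geo$roi_center
  if (is.null(radius_mm)) radius_mm <- geo$roi_radius_mm
  if (is.null(voxel_mm)) voxel_mm <- if (is.null(geo)) 1 else geo$voxel_mm
  codes <- tissue_codes()
  gm <- lab == codes[["gm"]]
  if (!gm[center_voxel[1], center_voxel[2], center_voxel[3]])
    stop("center voxel is not in gray matter")
  dmap <- if (inherits(depth, "depth_map")) depth$depth else depth

  vox <- which(gm, arr.ind = TRUE)
  id <- array(NA_integer_, dim(lab))
  id[gm] <- seq_len(nrow(vox))

  # unit depth-gradient at each GM voxel
  gx <- diff_axis(dmap, 1); gy <- diff_axis(dmap, 2); gz <- diff_axis(dmap, 3)
  gn <- sqrt(gx^2 + gy^2 + gz^2); gn[gn < 1e-12] <- 1
  nrm <- cbind(gx[gm] / gn[gm], gy[gm] / gn[gm], gz[gm] / gn[gm])

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- list(); wts <- list()
  d <- dim(lab)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    to <- rep(NA_integer_, nrow(vox))
    to[ok] <- id[nb[ok, , drop = FALSE]]
    keep <- ok & !is.na(to)
    if (!any(keep)) next
    step <- matrix(offs[k, ], sum(keep), 3, byrow = TRUE) * voxel_mm
    n_i <- nrm[keep, , drop = FALSE]
    along <- rowSums(step * n_i)
    tang2 <- pmax(rowSums(step^2) - along^2, 0)
    edges[[k]] <- cbind(which(keep), to[keep])
    wts[[k]] <- sqrt(tang2)
  }
  em <- do.call(rbind, edges)
  w <- unlist(wts)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  src <- id[center_voxel[1], center_voxel[2], center_voxel[3]]
  dist <- igraph::distances(g, v = src, weights = w)[1, ]
  roi <- array(FALSE, d)
  roi[gm][dist[id[gm]] <= radius_mm + 1e-6] <- TRUE
  roi
}
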