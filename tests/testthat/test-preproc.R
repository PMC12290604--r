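mk_trace <- function(m) {
  colnames(m) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                   "rot_x_rad", "rot_y_rad", "rot_z_rad")
  tibble::as_tibble(m)
}

test_that("framewise displacement sums translations and rotation arcs", {
  tr <- mk_trace(rbind(rep(0, 6), c(1, 0, 0, 0, 0, 0)))
  expect_equal(framewise_displacement(tr)$fd_mm, 1)
  # 0.01 rad on one axis at 50 mm radius is 0.5 mm of arc
  tr <- mk_trace(rbind(rep(0, 6), c(0, 0, 0, 0.01, 0, 0)))
  expect_equal(framewise_displacement(tr, head_radius_mm = 50)$fd_mm, 0.5)
  # constant trace, and invariance under a constant offset
  tr <- mk_trace(matrix(rnorm(6), 10, 6, byrow = TRUE))
  expect_equal(framewise_displacement(tr)$fd_mm, rep(0, 9))
  tr2 <- mk_trace(matrix(rnorm(60), 10, 6))
  off <- mk_trace(as.matrix(tr2) + matrix(rnorm(6), 10, 6, byrow = TRUE))
  expect_equal(framewise_displacement(tr2)$fd_mm,
               framewise_displacement(off)$fd_mm, tolerance = 1e-12)
  expect_equal(nrow(framewise_displacement(mk_trace(matrix(0, 1, 6)))), 0)
})

test_that("high-motion volumes are flagged against the voxel-size threshold", {
  expect_equal(flag_high_motion(c(0.1, 1.2, 0.3), 0.9), 2L)
  expect_equal(flag_high_motion(c(0.1, 0.2), 0.9), integer(0))
  # an injected 2 mm jump in a simulated trace is found at the jump
  f <- small_noisefree_run()
  m <- compartment_model()
  run <- simulate_run(f$geo, f$design, f$acq, m, seed = 3, motion_sd = 0.01)
  tr <- as.matrix(run$motion)
  k <- 40
  tr[k:nrow(tr), 1] <- tr[k:nrow(tr), 1] + 2
  fd <- framewise_displacement(mk_trace(tr))
  expect_equal(flag_high_motion(fd, 0.9), k - 1L)  # FD row k-1 = pair (k-1, k)
  expect_equal(fd$frame[k - 1L], k)
})

test_that("run averaging is the voxelwise mean and shrinks noise as 1/sqrt(k)", {
  dims <- c(4, 4, 2, 30)
  mk <- function(x) volume_series(array(x, dims), "nulled", 3.14)
  a <- array(rnorm(prod(dims)), dims)
  expect_equal(average_runs(list(mk(a), mk(a)))$data, a)
  expect_equal(average_runs(list(mk(a), mk(-a)))$data, array(0, dims))
  expect_error(average_runs(list(mk(a),
                                 volume_series(array(0, c(4, 4, 2, 31)),
                                               "nulled", 3.14))))
  set.seed(1)
  for (k in c(4, 16)) {
    runs <- lapply(seq_len(k), function(i)
      mk(array(rnorm(prod(dims)), dims)))
    resid_sd <- sd(average_runs(runs)$data)
    expect_equal(resid_sd, 1 / sqrt(k), tolerance = 0.1)
  }
})

test_that("temporal upsampling interpolates linearly and holds the edge", {
  s <- sampled_series(c(0, 1, 2, 3), "bold", 1)
  u <- upsample_temporal(s, 4)
  expect_equal(u$values[1:13], seq(0, 3, by = 0.25))
  expect_equal(u$values[14:16], c(3, 3, 3))  # edge-hold past the last sample
  expect_equal(u$dt_s, 0.25)
  expect_equal(which(u$measured), c(1, 5, 9, 13))
  expect_identical(upsample_temporal(s, 1), s)
  cst <- sampled_series(rep(7, 5), "bold", 1)
  expect_true(all(upsample_temporal(cst, 4)$values == 7))
  # volume series agrees with the 1D path
  v <- volume_series(array(rep(c(0, 1, 2, 3), each = 8), c(2, 2, 2, 4)),
                     "bold", 1)
  uv <- upsample_temporal(v, 2)
  expect_equal(uv$data[1, 1, 1, ], c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3))
})

test_that("upsampling and run averaging commute", {
  dims <- c(3, 3, 2, 20)
  set.seed(2)
  runs <- lapply(1:3, function(i)
    volume_series(array(rnorm(prod(dims)), dims), "nulled", 3.14))
  a <- upsample_temporal(average_runs(runs), 4)
  b <- average_runs(lapply(runs, upsample_temporal, factor = 4))
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("boco divides, duplicates a missing first volume, and guards zeros", {
  dims <- c(2, 2, 1, 6)
  n <- volume_series(array(rnorm(prod(dims), 100, 5), dims), "nulled", 3.14)
  b1 <- volume_series(array(1, dims), "bold", 3.14)
  expect_equal(boco(n, b1)$data, n$data)
  # one-volume-short BOLD: first volume duplicated
  b <- volume_series(array(rnorm(16, 100, 5), c(2, 2, 1, 4)), "bold", 3.14)
  n5 <- volume_series(array(100, c(2, 2, 1, 5)), "nulled", 3.14)
  v <- boco(n5, b)
  expect_equal(v$data[, , , 1], v$data[, , , 2])          # duplicated pair
  expect_equal(v$data[, , , 3], 100 / b$data[, , , 2])
  expect_error(boco(volume_series(array(1, c(2, 2, 1, 7)), "nulled", 3.14), b),
               "more than one volume")
  # dead BOLD voxel yields NaN, not infinity
  bz <- b1; bz$data[1, 1, 1, ] <- 0
  out <- boco(n, bz)
  expect_true(all(is.nan(out$data[1, 1, 1, ])))
  expect_false(any(is.infinite(out$data)))
})

test_that("tSNR is mean over sd with invalid flags for constant voxels", {
  dims <- c(2, 1, 1, 400)
  arr <- array(0, dims)
  x <- rnorm(400); x <- (x - mean(x)) / sd(x)
  arr[1, 1, 1, ] <- 100 + 10 * x   # mean 100, sd 10 exactly
  arr[2, 1, 1, ] <- 42
  m <- tsnr(volume_series(arr, "bold", 3.14))
  expect_equal(m[1, 1, 1], 10)
  expect_true(is.nan(m[2, 1, 1]))
  # Monte-Carlo: tSNR of mu + sd*noise approaches mu/sd
  set.seed(3)
  arr2 <- array(50 + 5 * rnorm(prod(dims)), dims)
  m2 <- tsnr(volume_series(arr2, "bold", 3.14))
  expect_equal(mean(m2), 10, tolerance = 0.15)
})

test_that("1/CV T1w map pools the concatenated moments and is scale invariant", {
  dims <- c(1, 1, 1, 200)
  set.seed(4)
  a <- 80 + 8 * rnorm(200); b <- 120 + 12 * rnorm(200)
  vn <- volume_series(array(a, dims), "nulled", 3.14)
  vb <- volume_series(array(b, dims), "bold", 3.14)
  m <- t1w_from_cv(vn, vb)
  # pooled-moment closed form on the concatenated samples
  cc <- c(a, b)
  expect_equal(m[1, 1, 1], mean(cc) / sd(cc))
  vn2 <- volume_series(array(2 * a, dims), "nulled", 3.14)
  vb2 <- volume_series(array(2 * b, dims), "bold", 3.14)
  expect_equal(t1w_from_cv(vn2, vb2)[1, 1, 1], m[1, 1, 1], tolerance = 1e-12)
  cst <- volume_series(array(5, dims), "nulled", 3.14)
  expect_true(is.nan(t1w_from_cv(cst, cst)[1, 1, 1]))
})
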