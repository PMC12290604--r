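test_that("the gamma HRF has the requested moments, mode and unit area", {
  h <- gamma_hrf(6, 3, dt = 0.1)
  expect_equal(sum(h$value) * 0.1, 1, tolerance = 1e-6)
  m <- hrf_moments(h)
  expect_lt(abs(m[["mean_s"]] - 6), 0.05)   # dt/2
  expect_lt(abs(m[["sd_s"]] - 3), 0.05)
  # shape 4, scale 1.5 -> mode at 4.5 s
  expect_equal(h$time_s[which.max(h$value)], 4.5, tolerance = 0.1)
  expect_true(all(h$value >= 0))
})

test_that("the DCT drift basis has the cutoff-determined size, orthogonal", {
  X <- highpass_basis(100, 3.14, 0.01)
  expect_equal(ncol(X), 6)    # floor(2 * 314 s * 0.01 Hz)
  g <- crossprod(X)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-9)
  expect_equal(ncol(highpass_basis(100, 3.14, 0)), 0)
})

test_that("design-matrix regressors peak near offset and scale with duration", {
  acq <- acq_scheme()
  d <- make_design(acq, 1, "long", seed = 13)
  h <- gamma_hrf(6, 3, dt = 0.1)
  n_vols <- ceiling(attr(d, "run_duration_s") / cycle_s(acq))
  X <- build_design_matrix(d, h, n_vols, cycle_s(acq))
  expect_true(all(c("stim_1s", "stim_24s", "intercept") %in% colnames(X)))
  expect_equal(qr(X)$rank, ncol(X))
  # the 24 s regressor peaks near trial offset + HRF lag
  tr24 <- d[d$duration_s == 24, ][1, ]
  vol_t <- (seq_len(n_vols) - 1) * cycle_s(acq)
  pk_t <- vol_t[which.max(X[, "stim_24s"] *
                            (vol_t > tr24$onset_s &
                               vol_t < tr24$onset_s + 40))]
  expect_lt(abs(pk_t - (tr24$onset_s + 24 + 2)), 6)
  # short-duration regressors grow about linearly with duration
  expect_equal(max(X[, "stim_2s"]) / max(X[, "stim_1s"]), 2, tolerance = 0.2)
  # a condition with no trials is rejected
  expect_error(build_design_matrix(d[d$duration_s != 4, ], h, n_vols,
                                   cycle_s(acq)),
               NA)  # dropping a duration just drops its column
  d0 <- d; d0$onset_s[d0$duration_s == 4] <- 1e6  # off the run -> zero column
  expect_error(build_design_matrix(d0, h, n_vols, cycle_s(acq)), "all-zero")
})

test_that("OLS recovers exact weights and matches the normal equations", {
  set.seed(20)
  X <- cbind(1, scale(matrix(rnorm(60 * 3), 60, 3), scale = FALSE))
  colnames(X) <- c("intercept", "stim_1s", "stim_2s", "stim_4s")
  # noise-free: beta recovered to machine precision
  w <- c(2, -1, 0.5, 3)
  y <- X %*% w
  fit <- fit_glm(matrix(y, ncol = 1), X)
  expect_equal(as.vector(fit$beta), w, tolerance = 1e-10)
  # randomized oracle equivalence
  for (i in 1:30) {
    n <- sample(10:40, 1); p <- sample(2:5, 1)
    Xi <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    colnames(Xi) <- c("intercept", paste0("x", seq_len(p - 1)))
    Y <- matrix(rnorm(n * 3), n, 3)
    fit <- fit_glm(Y, Xi, contrast_vector = c(1, rep(0, p - 1)))
    expect_equal(fit$beta, oracle_ols(Xi, Y), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("null z-statistics are standard normal", {
  set.seed(21)
  n <- 120
  X <- cbind(highpass_basis(n, 3.14, 0.01), intercept = 1,
             stim_4s = rnorm(n))
  Y <- matrix(rnorm(n * 6000), n, 6000)
  fit <- fit_glm(Y, X, contrast_vector = as.numeric(colnames(X) == "stim_4s"))
  expect_equal(sd(fit$z), 1, tolerance = 0.1)
  expect_lt(abs(mean(abs(fit$z) > 1.96) - 0.05), 0.012)
  # zero-variance voxel is flagged
  Y[, 1] <- 0
  fit2 <- fit_glm(Y, X)
  expect_true(is.nan(fit2$z[1]))
})

test_that("session combination is Stouffer fixed effects", {
  z <- array(rnorm(20), c(5, 4))
  expect_equal(combine_sessions(list(z)), z)
  expect_equal(combine_sessions(list(z, z)), z * sqrt(2))
  set.seed(22)
  zs <- lapply(1:4, function(i) matrix(rnorm(5000), 50, 100))
  zc <- combine_sessions(zs)
  expect_equal(sd(zc), 1, tolerance = 0.05)
  expect_error(combine_sessions(list(z, t(z))), "different grids")
})

test_that("layer profiles average within bins; min-max normalising rescales", {
  geo <- small_geometry(n_vessels = 0)
  depth <- geo$depth_true
  layers <- bin_layers(depth, 11)
  prof <- layer_profile(depth, layers)
  centers <- (seq_len(11) - 0.5) / 11
  expect_equal(prof$value, centers, tolerance = 0.05)
  flat <- layer_profile(array(3, dim(depth)), layers)
  expect_true(all(flat$value == 3))
  nm <- minmax_normalise(prof)
  expect_equal(min(nm$value_norm), 0)
  expect_equal(max(nm$value_norm), 1)
  expect_equal(minmax_normalise(tibble::tibble(value = c(2, 4, 6)))$value_norm,
               c(0, 0.5, 1))
  # affine transforms normalise identically
  aff <- prof; aff$value <- 3 * aff$value - 7
  expect_equal(minmax_normalise(aff)$value_norm, nm$value_norm)
  expect_error(minmax_normalise(tibble::tibble(value = rep(1, 5))), "constant")
})

test_that("a stronger middle-layer CBV drive yields a mid-depth z peak", {
  geo <- small_geometry(n_vessels = 0, seed = 4)
  acq <- acq_scheme()
  model <- compartment_model()  # tSNR 15 noise
  d <- make_design(acq, 1, "long", seed = 40)
  runs <- lapply(1:2, function(i)
    simulate_run(geo, d, acq, model, seed = 400 + i))
  nulled <- average_runs(lapply(runs, `[[`, "nulled"))
  bold <- average_runs(lapply(runs, `[[`, "bold"))
  vaso <- boco(nulled, bold)
  # GLM on the inverted VASO series so activation is positive
  inv <- vaso; inv$data <- -inv$data
  h <- gamma_hrf(6, 3, dt = 0.1)
  X <- build_design_matrix(d, h, n_vols(vaso), cycle_s(acq),
                           origin_s = vaso$origin_s)
  fit <- fit_glm(inv, X, contrast_vector =
                   as.numeric(colnames(X) == "stim_24s"))
  zmap <- stat_map(fit, "z")
  layers <- bin_layers(geo$depth_true, 3)
  prof <- layer_profile(zmap, layers)
  expect_equal(which.max(prof$value), 2)
})
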