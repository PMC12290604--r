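# fixtures are generated in code; heavy ones are memoised for the test run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small annulus geometry: fast for simulation-based tests
small_geometry <- function(n_vessels = 2, seed = 1) {
  build_geometry(grid_shape = c(24, 24, 4), annulus_radii = c(5, 9),
                 n_vessels = n_vessels, seed = seed)
}

# flat-slab label volume (GM ribbon of given thickness along x)
slab_labels <- function(nx = 14, ny = 24, nz = 24, wm_to = 4, gm_to = 10) {
  codes <- tissue_codes()
  lab <- array(codes[["csf"]], c(nx, ny, nz))
  lab[seq_len(wm_to), , ] <- codes[["wm"]]
  lab[(wm_to + 1):gm_to, , ] <- codes[["gm"]]
  lab
}

# noise-free single long-ITI run on the small geometry
small_noisefree_run <- function() {
  memo("small_noisefree_run", {
    geo <- small_geometry()
    acq <- acq_scheme()
    model <- compartment_model(noise_sd = 0)
    design <- make_design(acq, 1, "long", seed = 21)
    sim <- simulate_run(geo, design, acq, model, seed = 22, noise = FALSE)
    list(geo = geo, acq = acq, model = model, design = design, sim = sim)
  })
}

# noise-free 4-run participant on the default grid (used by the
# parameter-recovery checks; expensive, built once)
recovery_participant <- function() {
  memo("recovery_participant", {
    geo <- build_geometry(seed = 2)
    acq <- acq_scheme()
    model <- compartment_model(noise_sd = 0)
    sim <- simulate_participant(geo, acq, model, n_short = 2, n_long = 2,
                                seed = 11, noise = FALSE)
    list(sim = sim, metrics = participant_metrics(sim))
  })
}

# independent brute-force oracles -------------------------------------------

# per-timepoint mean over measured samples (falling back to all), written as
# plain loops
oracle_average_trials <- function(trials) {
  out <- list()
  for (d in sort(unique(trials$duration_s))) {
    td <- trials[trials$duration_s == d, ]
    for (tp in sort(unique(td$rel_time_s))) {
      rows <- td[td$rel_time_s == tp, ]
      vals <- if (any(rows$measured)) rows$value[rows$measured] else rows$value
      out[[length(out) + 1]] <- data.frame(
        duration_s = d, time_s = tp, value = sum(vals) / length(vals),
        n = sum(rows$measured))
    }
  }
  do.call(rbind, out)
}

# literal span-rule TTP scan as an index loop
oracle_ttp <- function(v, rel_tol = 0.01) {
  thr <- if (max(v) > 0) rel_tol * max(v) else 0
  i0 <- NA
  for (i in seq_along(v)) if (v[i] > thr) { i0 <- i; break }
  if (is.na(i0)) return(list(valid = FALSE))
  i1 <- length(v)
  if (i0 < length(v)) {
    for (i in (i0 + 1):length(v)) if (v[i] < -thr) { i1 <- i - 1; break }
  }
  best <- i0
  for (i in i0:i1) if (v[i] > v[best] + 1e-6 * abs(max(v[i0:i1]))) best <- i
  list(valid = TRUE, index = best, peak = v[best])
}

# normal-equations OLS
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
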