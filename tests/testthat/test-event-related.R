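test_that("trial windows run from onset to the end of the rest period", {
  # one trial, onset at sample 41 of the 0.785 s grid, 2 s stimulus + 10 s rest
  n <- 120
  s <- sampled_series(rnorm(n), "vaso", 0.785, origin_s = 0.785)
  acq <- acq_scheme()
  des <- tibble::tibble(run = 1L, trial = 1L, onset_s = 0.785 * 41,
                        duration_s = 2, jitter = 0L, iti_s = 10,
                        iti_class = "short")
  tw <- extract_trials(s, des)
  expect_equal(nrow(tw), floor(12 / 0.785))   # 15 samples
  expect_equal(tw$rel_time_s[1], 0)
  expect_equal(tw$value, s$values[41:55])
  expect_false(any(tw$truncated))
  # a trial running past the run end is truncated and flagged
  des2 <- dplyr::mutate(des, onset_s = 0.785 * (n - 5))
  tw2 <- extract_trials(s, des2)
  expect_lt(nrow(tw2), 15)
  expect_true(all(tw2$truncated))
  # empty design gives an empty trial set
  expect_equal(nrow(extract_trials(s, des[0, ])), 0)
})

test_that("four jitters of one duration differ in onset phase by one block", {
  f <- small_noisefree_run()
  d1 <- f$design[f$design$duration_s == 12, ]
  phases <- sort((d1$onset_s %% cycle_s(f$acq)) / f$acq$block_s)
  expect_equal(round(phases), 0:3)
})

test_that("trial averaging matches a brute-force loop and cancels +x/-x", {
  set.seed(10)
  for (rep in 1:25) {
    n_tr <- sample(2:6, 1)
    n_tp <- sample(4:12, 1)
    rows <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
      data.frame(run = 1L, trial = i,
                 duration_s = sample(c(2, 4), 1),
                 jitter = 0L, rel_time_s = (seq_len(n_tp) - 1) * 0.785,
                 value = rnorm(n_tp),
                 measured = sample(c(TRUE, FALSE), n_tp, replace = TRUE),
                 truncated = FALSE)
    }))
    trials <- structure(tibble::new_tibble(rows, class = "trial_set"),
                        dt_s = 0.785, contrast = "vaso")
    era <- average_trials(trials)
    ora <- oracle_average_trials(trials)
    ord <- order(ora$duration_s, ora$time_s)
    expect_equal(era$value, ora$value[ord], tolerance = 1e-12)
    expect_equal(era$n, ora$n[ord])
  }
  # +x and -x average to zero
  base <- data.frame(run = 1L, trial = 1L, duration_s = 2, jitter = 0L,
                     rel_time_s = (0:5) * 0.785, value = rnorm(6),
                     measured = TRUE, truncated = FALSE)
  neg <- base; neg$trial <- 2L; neg$value <- -base$value
  trials <- structure(tibble::new_tibble(rbind(base, neg), class = "trial_set"),
                      dt_s = 0.785, contrast = "vaso")
  expect_equal(average_trials(trials)$value, rep(0, 6))
})

test_that("jittered averaging reconstructs a smooth response at 4x the rate", {
  # noise-free vessel time course from the small simulated run
  f <- small_noisefree_run()
  pre <- boco_run(f$sim)
  ser <- roi_mean_series(pre$vaso, f$geo$compartments == 4L)
  trials <- extract_trials(ser, f$design)
  era <- average_trials(trials)
  expect_equal(unique(round(diff(sort(unique(era$time_s))), 6)), 0.785)
  p <- default_compartment_params()
  i <- which(p$compartment == "vessel" & p$contrast == "cbv")
  for (d in c(1, 4, 24)) {
    e <- era[era$duration_s == d, ]
    truthc <- (1 - p$amplitude[i] *
                 pmin(vasodyn:::boxcar_gamma(e$time_s, d, p$mean_s[i],
                                             p$sd_s[i], p$delay_s[i]),
                      p$cap[i])) * 70 / 100
    # measured-sample interleaving: exact up to previous-trial carryover
    expect_lt(max(abs(e$value - truthc)), 5e-4)
  }
})

test_that("baseline uses the first and final 30 s of every run", {
  s <- sampled_series(rep(100, 100), "vaso", 1)
  expect_equal(baseline_signal(s), 100)
  # task bump mid-run leaves the edge baseline untouched
  bump <- c(rep(100, 35), rep(140, 30), rep(100, 35))
  expect_equal(baseline_signal(sampled_series(bump, "vaso", 1)), 100)
  # two runs with edge means 90 and 110 average to 100
  r1 <- sampled_series(rep(90, 100), "vaso", 1)
  r2 <- sampled_series(rep(110, 100), "vaso", 1)
  expect_equal(baseline_signal(list(r1, r2)), 100)
  expect_error(baseline_signal(sampled_series(rep(1, 50), "vaso", 1)),
               "shorter")
  # volume series path gives a voxelwise map
  vs <- volume_series(array(rep(c(90, 110, 90, 110), 80), c(2, 2, 1, 80)),
                      "vaso", 1)
  bm <- baseline_signal(vs, window_s = 10)
  expect_equal(as.vector(bm), c(90, 110, 90, 110))
})

test_that("percent signal change divides by baseline and inverts VASO", {
  era <- structure(tibble::new_tibble(
    tibble::tibble(duration_s = 2, time_s = (0:3) * 0.785,
                   value = c(0.70, 0.686, 0.693, 0.70),
                   n = 4L, n_total = 4L), class = "era"),
    dt_s = 0.785, contrast = "vaso")
  out <- zero_first(percent_signal_change(era, baseline = 0.70))
  expect_equal(out$value[1], 0)
  expect_equal(out$value[2], 2, tolerance = 1e-9)   # 2% CBV becomes +2
  # doubling the baseline halves the magnitude
  out2 <- percent_signal_change(era, baseline = 1.4)
  expect_equal(out2$value, -100 * era$value / 1.4)
  bold <- structure(era, contrast = "bold")
  expect_equal(percent_signal_change(bold, 0.7)$value, 100 * era$value / 0.7)
  expect_error(percent_signal_change(era, baseline = 0), "invalid")
})

test_that("ITI stitching equalises the junction pair and fixes the offset", {
  mk_era <- function(t, v, d = 12) structure(
    tibble::new_tibble(tibble::tibble(duration_s = d, time_s = t, value = v,
                                      n = 1L, n_total = 1L), class = "era"),
    dt_s = 1, contrast = "vaso")
  t_short <- 0:9; t_long <- 0:19
  v_true <- sin(t_long / 6)
  v_true[11] <- v_true[10]   # continuous junction: zero-offset case is identity
  era_s <- mk_era(t_short, v_true[1:10])
  era_l <- mk_era(t_long, v_true + 0.3)       # long segment offset by +0.3
  st <- stitch_iti(era_s, era_l)
  expect_equal(nrow(st), 20)
  expect_equal(st$value[st$time_s == 10], st$value[st$time_s == 9])
  expect_equal(st$value[st$time_s <= 9], v_true[1:10])
  expect_equal(unique(st$segment[st$time_s > 9]), "long_only")
  # zero offset is the identity on the long-only tail
  st0 <- stitch_iti(era_s, mk_era(t_long, v_true))
  expect_equal(st0$value[st0$time_s > 10], v_true[12:20])
  expect_error(stitch_iti(era_s, mk_era(0:9, v_true[1:10])), "long-only")
})

test_that("zeroing subtracts the first timepoint", {
  expect_equal(zero_first(c(100, 102, 101)), c(0, 2, 1))
  expect_equal(zero_first(c(0, 5, -2)), c(0, 5, -2))
})

test_that("a stitched two-class pipeline matches the single-class curve", {
  geo <- small_geometry()
  acq <- acq_scheme()
  model <- compartment_model(noise_sd = 0)
  sim <- simulate_participant(geo, acq, model, n_short = 1, n_long = 1,
                              seed = 31, noise = FALSE)
  mask <- geo$compartments == 2L
  era <- era_pipeline(sim, mask)
  sim_long <- simulate_participant(geo, acq, model, n_short = 0, n_long = 1,
                                   seed = 31, noise = FALSE)
  era_l <- era_pipeline(sim_long, mask)
  m <- dplyr::inner_join(era, era_l, by = c("duration_s", "time_s"))
  expect_lt(max(abs(m$value.x - m$value.y)), 0.05)
  expect_true("segment" %in% names(era))
})

test_that("noise-free ERA recovery is exact and noise shrinks as 1/sqrt(runs)", {
  f <- small_noisefree_run()
  sim1 <- list(design_long = f$design, runs = list(
    c(f$sim, list(iti_class = "long", design_run = 1))),
    acq = f$acq, model = f$model, geometry = f$geo)
  mask <- f$geo$compartments == 2L
  era <- era_pipeline(sim1, mask)
  p <- default_compartment_params()
  i <- which(p$compartment == "gm_middle" & p$contrast == "cbv")
  for (d in c(1, 2, 4, 12, 24)) {
    e <- era[era$duration_s == d, ]
    truthc <- 100 * p$amplitude[i] *
      vasodyn:::boxcar_gamma(e$time_s, d, p$mean_s[i], p$sd_s[i], p$delay_s[i])
    expect_lt(max(abs(e$value - truthc)), 0.05)
  }
  # with noise, residual error shrinks roughly as 1/sqrt(n_runs)
  err_for <- function(n_runs, seed) {
    geo <- f$geo
    model <- compartment_model(tsnr_target = 50)
    sim <- simulate_participant(geo, f$acq, model, n_short = 0,
                                n_long = n_runs, seed = seed, noise = TRUE)
    e <- era_pipeline(sim, mask)
    e24 <- e[e$duration_s == 24, ]
    truthc <- 100 * p$amplitude[i] *
      vasodyn:::boxcar_gamma(e24$time_s, 24, p$mean_s[i], p$sd_s[i],
                             p$delay_s[i])
    sqrt(mean((e24$value - truthc)^2))
  }
  e1 <- err_for(1, 41); e16 <- err_for(16, 42)
  expect_lt(e16, e1 / 2)
})
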