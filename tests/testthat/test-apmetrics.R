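# Per-beat metric pipeline against constructed fixtures and oracle truth.

test_that("capture flags follow delivered stimuli: clean APs yes, flat no", {
  p <- waveform_params(amplitude = 0.5, t_activation = 30, t_repol = 330,
                       duration_ms = 900)
  prot <- stim_protocol(cycle_length_ms = 2000, first_pulse_ms = 500,
                        recording_duration_ms = 10000)
  t_ms <- seq(0, 10000, by = 1000 / 979)
  y <- cardiomapr:::eval_ap_train(p, prot, t_ms, skip_beats = 5L)
  beats <- detect_beats(tibble::tibble(time_ms = t_ms, df_f = y), prot)
  expect_equal(beats$captured, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(excitability(beats), 80)
})

test_that("an upstroke later than the capture window is not captured", {
  p <- waveform_params(t_activation = 350, t_repol = 600, duration_ms = 1200)
  wf <- make_ap_waveform(p)
  prot <- stim_protocol(cycle_length_ms = 1200, first_pulse_ms = 0,
                        recording_duration_ms = 1200)
  beats <- detect_beats(
    dplyr::mutate(wf$trace, df_f = value), prot, capture_window_ms = 300)
  expect_false(beats$captured[1])
})

test_that("excitability is the exact percentage of captured stimuli", {
  b <- tibble::tibble(captured = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(excitability(b), 100)
  b$captured[3] <- FALSE
  expect_equal(excitability(b), 80)
  expect_equal(excitability(tibble::tibble(captured = rep(FALSE, 5))), 0)
})

test_that("rise time of a linear 20 ms ramp is 16 ms", {
  fs <- 2000
  t <- seq(0, 400, by = 1000 / fs)
  y <- pmin(pmax((t - 100) / 20, 0), 1) # ramp 0 -> 1 over 100..120 ms
  y[t > 300] <- 0
  up <- upstroke_metrics(t, y, stimulus_time_ms = 90, baseline = 0,
                         amplitude = 1)
  expect_equal(up$rise_time_ms, 16, tolerance = 0.01)
})

test_that("a square pulse yields equal APD30/50/80 at the pulse width", {
  fs <- 10000
  t <- seq(0, 500, by = 1000 / fs)
  y <- as.numeric(t >= 100 & t < 300)
  apds <- apd_levels(t, y, t_act_ms = 100, baseline = 0, amplitude = 1)
  expect_equal(unname(apds), rep(200, 3), tolerance = 0.2)
})

test_that("pipeline metrics match oracle truth over 50 random waveforms", {
  ps <- random_waveform_params(50, seed = 42)
  sample_ms <- 1000 / 979
  for (p in ps) {
    wf <- make_ap_waveform(p)
    bm <- beat_metrics(as_trace(wf), one_beat_protocol(p))
    expect_lt(abs(bm$apd30_ms[1] - wf$truth$apd30_ms), sample_ms)
    expect_lt(abs(bm$apd50_ms[1] - wf$truth$apd50_ms), sample_ms)
    expect_lt(abs(bm$apd80_ms[1] - wf$truth$apd80_ms), sample_ms)
    expect_lt(abs(bm$apd_mxr_ms[1] - wf$truth$apd_mxr_ms), 2 * sample_ms)
    # exact definitional identity
    expect_identical(bm$apd_tri_ms[1], bm$apd_mxr_ms[1] - bm$apd50_ms[1])
  }
})

test_that("stimulation delay recovers the programmed latency", {
  p <- waveform_params(t_activation = 100) # pulse at 70 -> delay 30 ms
  wf <- make_ap_waveform(p)
  bm <- beat_metrics(as_trace(wf), one_beat_protocol(p, first_pulse_ms = 70))
  expect_lt(abs(bm$stim_delay_ms[1] - 30), 1000 / 979)
})

test_that("a slope break in piecewise-linear repolarization pins APD_MxR", {
  fs <- 979
  t <- seq(0, 800, by = 1000 / fs)
  # upstroke at 100, plateau, then two-slope repolarization with a sharp
  # break 250 ms after activation
  y <- rep(0, length(t))
  y[t >= 100] <- 1
  seg1 <- t >= 150 & t < 350
  y[seg1] <- 1 - 0.9 * (t[seg1] - 150) / 200
  seg2 <- t >= 350
  y[seg2] <- pmax(0.1 - 5e-4 * (t[seg2] - 350), 0)
  mxr <- apd_mxr(t, y, t_act_ms = 100, apd50_ms = 100)
  expect_lt(abs(mxr - 250), 6) # smoothing blurs the break by a few samples
})

test_that("late-slowing repolarization gives APD_MxR below APD80", {
  # rapid phase-3 ends at a 25% pedestal that drains slowly: the end of
  # rapid repolarization precedes the 80% crossing by construction
  fs <- 979
  t <- seq(0, 1200, by = 1000 / fs)
  y <- rep(0, length(t))
  y[t >= 100] <- 1
  seg1 <- t >= 150 & t < 330
  y[seg1] <- 1 - 0.75 * (t[seg1] - 150) / 180
  seg2 <- t >= 330
  y[seg2] <- pmax(0.25 - 4e-4 * (t[seg2] - 330), 0)
  apds <- apd_levels(t, y, t_act_ms = 100, baseline = 0, amplitude = 1)
  mxr <- apd_mxr(t, y, t_act_ms = 100, apd50_ms = apds[["apd50_ms"]])
  expect_lt(mxr, apds[["apd80_ms"]])
  expect_lt(abs(mxr - 230), 6)
})

test_that("EAD-bearing beats are flagged and keep their APD values", {
  p <- waveform_params(t_repol = 450, duration_ms = 1000,
                       ead = list(t_onset_ms = 330, amp_frac = 0.15,
                                  width_ms = 45))
  wf <- make_ap_waveform(p)
  bm <- beat_metrics(as_trace(wf), one_beat_protocol(p))
  expect_equal(nrow(bm), 1) # EADs do not split beats
  expect_true(bm$ead[1])
  expect_false(is.na(bm$apd80_ms[1]))
  # clean beat of the same shape is not flagged
  p0 <- waveform_params(t_repol = 450, duration_ms = 1000)
  bm0 <- beat_metrics(as_trace(make_ap_waveform(p0)), one_beat_protocol(p0))
  expect_false(bm0$ead[1])
})

test_that("EAD detector is specific on noisy clean beats", {
  set.seed(21)
  fp <- replicate(200, {
    p <- waveform_params(t_repol = stats::runif(1, 250, 500),
                         duration_ms = 1000)
    wf <- make_ap_waveform(p)
    y <- wf$trace$value + rnorm(nrow(wf$trace), 0, 0.02)
    detect_ead(wf$trace$time_ms, y, 0, 1)
  })
  expect_lte(mean(fp), 0.05)
})

test_that("metrics are stable between 979 Hz and 2 kHz sampling", {
  ps <- random_waveform_params(10, seed = 33)
  for (p in ps) {
    p2 <- p
    p2$sampling_rate_hz <- 2000
    bm1 <- beat_metrics(as_trace(make_ap_waveform(p)), one_beat_protocol(p))
    bm2 <- beat_metrics(as_trace(make_ap_waveform(p2)), one_beat_protocol(p2))
    for (m in c("apd30_ms", "apd50_ms", "apd80_ms", "apd_mxr_ms")) {
      expect_lt(abs(bm1[[m]][1] - bm2[[m]][1]), 1.5)
    }
  }
})

test_that("tissue summaries report means, beat-to-beat SDs and EAD presence", {
  bm <- tibble::tibble(
    tissue = 1L, beat = 1:3, stimulus_time_ms = c(0, 1000, 2000),
    captured = TRUE, amplitude = 1,
    stim_delay_ms = 30, rise_time_ms = 10,
    apd30_ms = 100, apd50_ms = 150, apd80_ms = c(200, 202, 198),
    apd_mxr_ms = 180, apd_tri_ms = 30, ead = c(FALSE, TRUE, FALSE))
  sm <- summarize_tissues(bm)
  expect_equal(sm$apd80_ms_mean, 200)
  expect_equal(sm$apd80_ms_sd, 2)
  expect_equal(sm$excitability_pct, 100)
  expect_true(sm$ead_present)
  # single captured beat: mean defined, SD not
  sm1 <- summarize_tissues(bm[1, ])
  expect_equal(sm1$apd80_ms_mean, 200)
  expect_true(is.na(sm1$apd80_ms_sd))
  # fully non-excitable tissue: no metric summaries
  bm$captured <- FALSE
  bm[, c("stim_delay_ms", "rise_time_ms", "apd30_ms", "apd50_ms", "apd80_ms",
         "apd_mxr_ms", "apd_tri_ms")] <- NA_real_
  bm$ead <- NA
  sm0 <- summarize_tissues(bm)
  expect_equal(sm0$excitability_pct, 0)
  expect_true(is.na(sm0$apd80_ms_mean))
})

test_that("generator APD80 increases with pacing cycle length (restitution)", {
  apd <- vapply(c(800, 1000, 2000), function(cl) {
    simulate_ionic_ap(ionic_scales(pacing_cl_ms = cl,
                                   n_beats_to_steady = 6))$metrics$apd80_ms[1]
  }, numeric(1))
  expect_true(all(diff(apd) > 0))
})
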