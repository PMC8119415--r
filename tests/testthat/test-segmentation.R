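test_that("a pure pacing-frequency sinusoid scores near 1", {
  fs <- 100
  T_ <- 1600 # 16 s at 100 Hz, 8 pacing periods at 0.5 Hz
  t <- (seq_len(T_) - 1) / fs
  frames <- array(0, dim = c(T_, 2, 2))
  frames[, 1, 1] <- sin(2 * pi * 0.5 * t)
  frames[, 1, 2] <- rnorm(T_)
  mv <- list(frames = frames, frame_rate_hz = fs)
  act <- pixel_activity(mv, 0.5)
  expect_gt(act[1, 1], 0.99)
  expect_lt(act[1, 2], 0.3)
})

test_that("white-noise pixels score near the flat-spectrum band fraction", {
  fs <- 100; T_ <- 2000
  set.seed(4)
  frames <- array(rnorm(T_ * 8 * 8), dim = c(T_, 8, 8))
  mv <- list(frames = frames, frame_rate_hz = fs)
  act <- pixel_activity(mv, 0.5)
  # 4 bands x 3 bins out of T/2 = 1000 one-sided bins
  expected <- 12 / 1000
  expect_lt(abs(mean(act) - expected) / expected, 0.25)
})

test_that("recordings shorter than two pacing periods are rejected", {
  mv <- list(frames = array(0, dim = c(100, 2, 2)), frame_rate_hz = 100)
  expect_error(pixel_activity(mv, 0.5), "2 pacing periods")
})

test_that("in-tissue pixels outscore all background pixels at SNR >= 5", {
  sc <- demo_scene(noise_sd = 20, n_frames = 3916) # SNR 5
  mv <- render_movie(sc, seed = 5)
  act <- pixel_activity(mv, 0.5)
  expect_gt(min(act[mv$labels > 0]), max(act[mv$labels == 0]))
})

test_that("size filter retains only components strictly larger than 60 px", {
  sc <- demo_scene(noise_sd = 10, n_frames = 3916, distractors = TRUE)
  mv <- render_movie(sc, seed = 6)
  truth_areas <- tabulate(mv$labels)
  expect_equal(sort(truth_areas[5:7]), c(59, 60, 61))
  act <- pixel_activity(mv, 0.5)
  rois <- segment_rois(act, min_pixels = 60)
  expect_equal(nrow(rois), 5) # 4 main tissues + the 61-px distractor
  expect_true(all(rois$area_px > 60))
  expect_true(61 %in% rois$area_px)
})

test_that("segmented regions match truth ROIs with high Jaccard at SNR 10", {
  sc <- demo_scene(noise_sd = 10, n_frames = 3916)
  mv <- render_movie(sc, seed = 8)
  rois <- segment_rois(pixel_activity(mv, 0.5))
  lab <- attr(rois, "labels")
  for (k in 1:4) expect_gte(jaccard_vs_truth(lab, mv$labels, k), 0.9)
  # retained ROIs are pairwise disjoint by construction of the label image
  expect_equal(sum(lab > 0), sum(rois$area_px))
})

test_that("an all-noise movie under a fixed threshold yields no regions", {
  set.seed(10)
  frames <- array(rnorm(3916 * 16 * 16, 1000, 10), dim = c(3916, 16, 16))
  mv <- list(frames = frames, frame_rate_hz = 979)
  act <- pixel_activity(mv, 0.5)
  rois <- segment_rois(act, threshold = 0.5)
  expect_equal(nrow(rois), 0)
})

test_that("label assignment is 8-connected", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE # diagonal neighbours
  lab <- cardiomapr:::label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
})

test_that("noiseless extraction recovers the waveform up to normalization", {
  sc <- demo_scene(noise_sd = 0, n_frames = 1958)
  mv <- render_movie(sc, seed = 1)
  tr <- extract_traces(mv, mv$labels)
  t1 <- dplyr::filter(tr, tissue == 1)
  truth <- dplyr::filter(mv$truth_traces, tissue == 1)
  # affine-align the truth to the extracted trace and compare
  fit <- lm(t1$df_f ~ truth$value)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  # upstroke positive after polarity correction
  expect_gt(max(t1$df_f), 0.05)
  expect_lt(abs(median(t1$df_f[truth$value < 1e-6])), 1e-6)
})

test_that("pixel averaging reduces noise by roughly sqrt(N)", {
  sc <- demo_scene(noise_sd = 10, n_frames = 1958)
  mv <- render_movie(sc, seed = 12)
  tr <- extract_traces(mv, mv$labels)
  npx <- attr(tr, "n_pixels")
  t1 <- dplyr::filter(tr, tissue == 1)
  truth <- dplyr::filter(mv$truth_traces, tissue == 1)
  resid <- residuals(lm(t1$df_f ~ truth$value))
  # residual SD in dF/F units: (sigma / sqrt(N)) / baseline
  expected <- 10 / sqrt(npx[["1"]]) / 1000
  expect_lt(abs(sd(resid) - expected) / expected, 0.15)
})

test_that("identical movie and config give identical ROIs and traces", {
  sc <- demo_scene(noise_sd = 10, n_frames = 3916)
  mv <- render_movie(sc, seed = 13)
  r1 <- segment_rois(pixel_activity(mv, 0.5))
  r2 <- segment_rois(pixel_activity(mv, 0.5))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(extract_traces(mv, r1), extract_traces(mv, r2))
})
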