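# Synthetic optical-mapping movies with ground truth.

#' Scene specification for a synthetic optical-mapping movie
#'
#' Describes a camera field holding circular microtissues, each carrying a
#' parametric AP waveform. Defaults emulate a typical acquisition: 64 x 64
#' pixels at 18.7 um/px (1.2 x 1.2 mm field) and 979 frames/s, with the
#' voltage-sensitive dye signal inverted (fluorescence dips on
#' depolarization).
#'
#' @param tissues List of tissue descriptions; each a list with `center`
#'   (row, col, px), `radius_px` and `params` (a [waveform_params()] object).
#' @param field_size_px Integer vector (rows, cols).
#' @param pixel_size_um Pixel size, micrometres.
#' @param dye_polarity `"inverted"` (default) or `"direct"`.
#' @param baseline_intensity Diastolic intensity, camera counts.
#' @param noise_sd Additive i.i.d. Gaussian noise SD per pixel per frame,
#'   counts.
#' @param n_frames Number of frames.
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param protocol A [stim_protocol()]; each tissue fires one AP per pulse
#'   (minus its `skip_beats`), with the waveform's `t_activation` read as
#'   the latency from pulse onset. Defaults to 0.5 Hz pacing over the movie
#'   duration.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(tissues, field_size_px = c(64, 64), pixel_size_um = 18.7,
                       dye_polarity = c("inverted", "direct"),
                       baseline_intensity = 1000, noise_sd = 0,
                       n_frames = 7832, frame_rate_hz = 979,
                       protocol = NULL) {
  dye_polarity <- match.arg(dye_polarity)
  if (is.null(protocol)) {
    protocol <- stim_protocol(cycle_length_ms = 2000, first_pulse_ms = 500,
                              recording_duration_ms = n_frames / frame_rate_hz * 1000)
  }
  stopifnot(inherits(protocol, "stim_protocol"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (baseline_intensity <= 0) abort("`baseline_intensity` must be > 0.")
  for (ts in tissues) {
    if (ts$radius_px <= 0) abort("tissue radius must be > 0.")
    if (ts$center[1] - ts$radius_px < 1 || ts$center[1] + ts$radius_px > field_size_px[1] ||
        ts$center[2] - ts$radius_px < 1 || ts$center[2] + ts$radius_px > field_size_px[2]) {
      abort("tissues must lie inside the field.")
    }
    stopifnot(inherits(ts$params, "waveform_params"))
  }
  structure(
    list(tissues = tissues, field_size_px = field_size_px,
         pixel_size_um = pixel_size_um, dye_polarity = dye_polarity,
         baseline_intensity = baseline_intensity, noise_sd = noise_sd,
         n_frames = n_frames, frame_rate_hz = frame_rate_hz,
         protocol = protocol),
    class = "scene_spec"
  )
}

# Paced AP train: one waveform per stimulus pulse (t_activation acts as the
# pulse-to-upstroke latency), optionally skipping beats (loss of capture).
eval_ap_train <- function(params, protocol, t_ms, skip_beats = integer(0)) {
  out <- numeric(length(t_ms))
  for (b in seq_along(protocol$pulse_times_ms)) {
    if (b %in% skip_beats) next
    out <- out + eval_waveform(params, t_ms - protocol$pulse_times_ms[b])
  }
  out
}

# Integer pixels inside a circle; returns 2-column matrix (row, col).
circle_pixels <- function(center, radius, field) {
  rr <- max(1, floor(center[1] - radius)):min(field[1], ceiling(center[1] + radius))
  cc <- max(1, floor(center[2] - radius)):min(field[2], ceiling(center[2] + radius))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Render a synthetic optical-mapping movie
#'
#' Builds a T x H x W frame stack: in-tissue pixels carry
#' `baseline +/- amplitude_counts * waveform` (sign per dye polarity, where
#' `amplitude_counts = params$amplitude * baseline_intensity`, i.e. the
#' waveform amplitude is a Delta-F/F fraction of baseline) plus i.i.d.
#' Gaussian noise; all other pixels carry baseline plus noise. Ground truth
#' (ROI label image and per-tissue clean unit traces) is returned alongside.
#'
#' @param scene A [scene_spec()] object.
#' @param seed Integer seed for the pixel noise.
#' @return A list of class `"movie_stack"` with `frames` (array T x H x W),
#'   `frame_rate_hz`, `pixel_size_um`, `dye_polarity`, plus truth components
#'   `labels` (H x W integer matrix, 0 = background) and `truth_traces`
#'   (tibble `tissue`, `time_ms`, `value` — clean unit waveform).
#' @export
render_movie <- function(scene, seed = 1) {
  stopifnot(inherits(scene, "scene_spec"))
  H <- scene$field_size_px[1]; W <- scene$field_size_px[2]
  T_ <- scene$n_frames
  t_ms <- (seq_len(T_) - 1) * 1000 / scene$frame_rate_hz
  labels <- matrix(0L, H, W)
  pix_list <- list()
  for (k in seq_along(scene$tissues)) {
    ts <- scene$tissues[[k]]
    px <- circle_pixels(ts$center, ts$radius_px, c(H, W))
    if (any(labels[px] != 0L)) abort("tissues overlap; microtissues must be spatially distinct.")
    labels[px] <- k
    pix_list[[k]] <- px
  }
  sgn <- if (scene$dye_polarity == "inverted") -1 else 1
  set.seed(seed)
  frames <- array(rnorm(T_ * H * W, mean = 0, sd = scene$noise_sd),
                  dim = c(T_, H, W)) + scene$baseline_intensity
  truth <- list()
  for (k in seq_along(scene$tissues)) {
    ts <- scene$tissues[[k]]
    w_unit <- eval_ap_train(ts$params, scene$protocol, t_ms,
                            ts$skip_beats %||% integer(0)) / ts$params$amplitude
    sig <- sgn * ts$params$amplitude * scene$baseline_intensity * w_unit
    for (i in seq_len(nrow(pix_list[[k]]))) {
      frames[, pix_list[[k]][i, 1], pix_list[[k]][i, 2]] <-
        frames[, pix_list[[k]][i, 1], pix_list[[k]][i, 2]] + sig
    }
    truth[[k]] <- tibble(tissue = k, time_ms = t_ms, value = w_unit)
  }
  structure(
    list(frames = frames, frame_rate_hz = scene$frame_rate_hz,
         pixel_size_um = scene$pixel_size_um, dye_polarity = scene$dye_polarity,
         labels = labels, truth_traces = bind_rows(truth)),
    class = "movie_stack"
  )
}
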