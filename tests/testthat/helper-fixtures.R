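# Shared fixtures, built in code at test time.

# Default single-beat waveform for metric tests.
default_params <- function(...) {
  waveform_params(amplitude = 1, t_activation = 100, tau_up = 2,
                  t_repol = 350, tau_repol = 15, plateau_decay = 5e-4, ...)
}

# One-tissue trace tibble from a waveform, ready for beat_metrics().
as_trace <- function(wf) {
  dplyr::mutate(wf$trace, tissue = 1L, df_f = .data$value)[, c("tissue", "time_ms", "df_f")]
}

# Single-pulse protocol covering one waveform.
one_beat_protocol <- function(params, first_pulse_ms = 60) {
  stim_protocol(cycle_length_ms = params$duration_ms,
                first_pulse_ms = first_pulse_ms,
                recording_duration_ms = params$duration_ms)
}

# Small 4-tissue scene (plus optional distractors) for segmentation tests.
# SNR = waveform amplitude fraction * baseline / noise_sd.
demo_scene <- function(noise_sd = 10, n_frames = 3916, distractors = FALSE,
                       skip_beats_tissue1 = integer(0)) {
  wp <- waveform_params(amplitude = 0.1, t_activation = 30, t_repol = 330,
                        duration_ms = 900)
  mk <- function(ctr, r = 7.4, skip = integer(0)) {
    list(center = ctr, radius_px = r, params = wp, skip_beats = skip)
  }
  tissues <- list(mk(c(16, 16), skip = skip_beats_tissue1), mk(c(16, 48)),
                  mk(c(48, 16)), mk(c(48, 48)))
  if (distractors) {
    tissues <- c(tissues, list(mk(c(32, 12.2), 4.295),   # 59 px
                               mk(c(32.5, 32), 4.275),   # 60 px
                               mk(c(32, 52), 4.3)))      # 61 px
  }
  scene_spec(tissues, noise_sd = noise_sd, n_frames = n_frames)
}

# Jaccard index of a segmented label against a truth label image.
jaccard_vs_truth <- function(seg_labels, truth_labels, truth_id) {
  best <- 0
  for (j in setdiff(unique(as.vector(seg_labels)), 0L)) {
    jac <- sum(seg_labels == j & truth_labels == truth_id) /
      sum(seg_labels == j | truth_labels == truth_id)
    best <- max(best, jac)
  }
  best
}
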