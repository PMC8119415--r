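# Per-beat action potential metrics.
#
# All durations are referenced to t_act, the time of maximum dF/dt within the
# capture window, and repolarization levels to the per-beat amplitude above
# the diastolic baseline (optical signals are uncalibrated, so absolute
# levels are meaningless). Level crossings are linearly interpolated between
# samples; derivatives come from a zero-phase Savitzky-Golay polynomial
# filter so the second derivative is not noise-dominated.

# Odd Savitzky-Golay window length (samples) for a window in ms; at least
# p + 2 and odd.
sg_window <- function(window_ms, fs_hz, p = 3) {
  n <- max(round(window_ms * fs_hz / 1000), p + 2)
  if (n %% 2 == 0) n <- n + 1
  n
}

sg_smooth <- function(y, fs_hz, window_ms, p = 3, m = 0) {
  n <- sg_window(window_ms, fs_hz, p)
  if (length(y) <= n) return(if (m == 0) y else rep(0, length(y)))
  ts <- 1 / fs_hz
  signal::sgolayfilt(y, p = p, n = n, m = m, ts = ts * 1000) # per-ms derivatives
}

#' Detect stimulus-locked beats in a trace
#'
#' Splits a per-tissue trace into one analysis window per stimulus pulse
#' (from pulse onset to the next onset or trace end) and decides whether the
#' stimulus captured: a beat is captured when a positive deflection with
#' amplitude at least `capture_amp_frac` times the median candidate amplitude
#' has its maximum upstroke velocity (dF/dt max) within `capture_window_ms`
#' of the pulse onset. Amplitude is the window maximum above the diastolic
#' baseline (median of the last 10% of the preceding window). Spontaneous
#' beats not locked to a stimulus are ignored.
#'
#' @param trace Data frame with `time_ms` and `df_f` for one tissue.
#' @param protocol A [stim_protocol()] object.
#' @param capture_window_ms Maximum stimulus-to-upstroke latency, ms.
#' @param capture_amp_frac Minimum amplitude relative to the median candidate
#'   beat amplitude.
#' @param smooth_window_ms Savitzky-Golay window for the upstroke-velocity
#'   scan, ms.
#' @return Tibble, one row per stimulus: `beat`, `stimulus_time_ms`,
#'   `t_start_ms`, `t_end_ms`, `captured`, `amplitude`, `baseline`.
#' @export
detect_beats <- function(trace, protocol, capture_window_ms = 300,
                         capture_amp_frac = 0.5, smooth_window_ms = 5) {
  stopifnot(inherits(protocol, "stim_protocol"))
  t <- trace$time_ms
  y <- trace$df_f
  fs <- 1000 / stats::median(diff(t))
  pulses <- protocol$pulse_times_ms
  if (!length(pulses)) abort("protocol contains no stimulus pulses.")
  ends <- c(pulses[-1], max(t) + 1e-9)
  dy <- sg_smooth(y, fs, smooth_window_ms, m = 1)

  rows <- purrr::map(seq_along(pulses), function(b) {
    w <- which(t >= pulses[b] & t < ends[b])
    if (length(w) < 4) {
      return(tibble(beat = b, stimulus_time_ms = pulses[b],
                    t_start_ms = pulses[b], t_end_ms = ends[b],
                    captured = FALSE, amplitude = NA_real_,
                    baseline = NA_real_))
    }
    pre <- which(t < pulses[b] & t >= (if (b == 1) min(t) else pulses[b - 1]))
    baseline <- if (length(pre) >= 4) {
      k <- max(1L, ceiling(0.1 * length(pre)))
      median(y[tail(pre, k)])
    } else {
      mean(sort(y[w])[seq_len(max(1L, floor(length(w) / 4)))])
    }
    amp <- max(y[w]) - baseline
    # location of the beat's max upstroke velocity anywhere in the window;
    # capture requires it to fall inside the capture window
    t_dvmax <- t[w[which.max(dy[w])]]
    tibble(beat = b, stimulus_time_ms = pulses[b], t_start_ms = pulses[b],
           t_end_ms = ends[b], captured = NA, amplitude = amp,
           baseline = baseline, t_dvmax = t_dvmax)
  }) %>% bind_rows()

  med_amp <- median(rows$amplitude, na.rm = TRUE)
  rows %>%
    mutate(captured = !is.na(.data$amplitude) & .data$amplitude > 0 &
             .data$amplitude >= capture_amp_frac * med_amp &
             !is.na(.data$t_dvmax) &
             .data$t_dvmax <= .data$stimulus_time_ms + capture_window_ms) %>%
    select(-"t_dvmax")
}

#' Excitability of a tissue
#'
#' Percentage of delivered stimuli that evoked a captured action potential.
#'
#' @param beats Tibble from [detect_beats()] (one row per delivered stimulus).
#' @return Percentage in \[0, 100\].
#' @export
excitability <- function(beats) {
  if (!nrow(beats)) abort("no beats supplied.")
  100 * sum(beats$captured) / nrow(beats)
}

#' Upstroke metrics for one beat
#'
#' `t_act` is the time of the maximum smoothed first derivative within the
#' capture window; `stim_delay_ms` is its latency from the pulse onset and
#' `rise_time_ms` the 10-90% upstroke time (linearly interpolated).
#'
#' @param t,y Time (ms) and signal samples of the beat window.
#' @param stimulus_time_ms Pulse onset, ms.
#' @param baseline,amplitude Diastolic baseline and beat amplitude.
#' @param capture_window_ms Search window for the upstroke, ms.
#' @param smooth_window_ms Savitzky-Golay window, ms.
#' @return List with `stim_delay_ms`, `rise_time_ms`, `t_act_ms`.
#' @export
upstroke_metrics <- function(t, y, stimulus_time_ms, baseline, amplitude,
                             capture_window_ms = 300, smooth_window_ms = 5) {
  fs <- 1000 / stats::median(diff(t))
  dy <- sg_smooth(y, fs, smooth_window_ms, m = 1)
  wc <- which(t <= stimulus_time_ms + capture_window_ms)
  if (!length(wc)) return(list(stim_delay_ms = NA_real_, rise_time_ms = NA_real_,
                               t_act_ms = NA_real_))
  i_act <- wc[which.max(dy[wc])]
  t_act <- t[i_act]
  i_pk <- which.max(y)
  up <- seq_len(i_pk)
  t10 <- cross_up(t[up], y[up], baseline + 0.10 * amplitude)
  t90 <- cross_up(t[up], y[up], baseline + 0.90 * amplitude)
  list(stim_delay_ms = t_act - stimulus_time_ms,
       rise_time_ms = t90 - t10, t_act_ms = t_act)
}

#' Action potential durations at repolarization levels
#'
#' APD_x is the time from `t_act` to the first post-peak downward crossing of
#' `baseline + (1 - x/100) * amplitude`, linearly interpolated.
#'
#' @inheritParams upstroke_metrics
#' @param t_act_ms Activation time (max dF/dt), ms.
#' @param levels Repolarization percentages.
#' @return Named numeric vector of durations (ms); `NA` where the level is
#'   never crossed within the window.
#' @export
apd_levels <- function(t, y, t_act_ms, baseline, amplitude,
                       levels = c(30, 50, 80)) {
  if (is.na(amplitude) || amplitude <= 0) {
    return(setNames(rep(NA_real_, length(levels)), paste0("apd", levels, "_ms")))
  }
  i_pk <- which.max(y)
  out <- vapply(levels, function(x) {
    lev <- baseline + (1 - x / 100) * amplitude
    tc <- cross_down(t, y, lev, from = i_pk)
    tc - t_act_ms
  }, numeric(1))
  setNames(out, paste0("apd", levels, "_ms"))
}

#' APD to the maximum repolarization rate
#'
#' Locates the end of rapid (phase-3) repolarization as the arg-max of the
#' second derivative of the smoothed trace in the window from the APD50
#' crossing to the end of the beat, and returns its latency from `t_act`.
#'
#' @inheritParams apd_levels
#' @param apd50_ms APD50 of the same beat, ms (defines the search start).
#' @param smooth_window_ms Savitzky-Golay window for the second derivative, ms.
#' @param baseline,amplitude Optional diastolic baseline and beat amplitude;
#'   when supplied, the search stops where the trace first completes
#'   repolarization (falls below `baseline + 0.02 * amplitude`), so that
#'   curvature fluctuations of the flat diastolic tail cannot outscore the
#'   phase-3 curvature peak on noisy traces.
#' @return APD_MxR in ms, or `NA` when the search window is empty.
#' @export
apd_mxr <- function(t, y, t_act_ms, apd50_ms, smooth_window_ms = 11,
                    baseline = NULL, amplitude = NULL) {
  if (is.na(apd50_ms)) return(NA_real_)
  fs <- 1000 / stats::median(diff(t))
  d2 <- sg_smooth(y, fs, smooth_window_ms, m = 2)
  n_edge <- (sg_window(smooth_window_ms, fs) - 1) / 2 # filter edge transient
  from <- t_act_ms + apd50_ms
  t_stop <- max(t)
  if (!is.null(baseline) && !is.null(amplitude) && !is.na(amplitude)) {
    ys <- sg_smooth(y, fs, smooth_window_ms)
    i_pk <- which.max(ys)
    t_end <- cross_down(t, ys, baseline + 0.02 * amplitude, from = i_pk)
    if (!is.na(t_end)) t_stop <- t_end
  }
  cand <- which(t >= from & t <= t_stop &
                  seq_along(t) <= length(t) - n_edge)
  if (!length(cand)) return(NA_real_)
  t[cand[which.max(d2[cand])]] - t_act_ms
}

#' Action potential triangulation
#'
#' Triangulation is the exact difference APD_MxR - APD50; delayed phase-3
#' repolarization (an I_Kr-block signature) increases it.
#'
#' @param apd_mxr_ms,apd50_ms Durations in ms.
#' @return APD_tri in ms.
#' @export
apd_tri <- function(apd_mxr_ms, apd50_ms) apd_mxr_ms - apd50_ms

#' Early-afterdepolarization detector
#'
#' Flags a beat when, between the beat peak and 90% repolarization, the
#' smoothed derivative turns from negative to positive and the subsequent
#' re-depolarization rises at least `min_amp_frac` of the beat amplitude
#' above its local minimum and persists for at least `min_duration_ms`.
#'
#' @inheritParams apd_levels
#' @param min_amp_frac Minimum EAD amplitude as a fraction of beat amplitude.
#' @param min_duration_ms Minimum duration of the re-depolarized excursion, ms.
#' @param smooth_window_ms Savitzky-Golay window, ms.
#' @return Logical flag.
#' @export
detect_ead <- function(t, y, baseline, amplitude, min_amp_frac = 0.05,
                       min_duration_ms = 20, smooth_window_ms = 11) {
  if (is.na(amplitude) || amplitude <= 0) return(FALSE)
  fs <- 1000 / stats::median(diff(t))
  ys <- sg_smooth(y, fs, smooth_window_ms)
  # anchor at the primary AP peak (the first major local maximum), not the
  # global max: a large EAD bump riding the plateau can exceed the AP peak
  n <- length(ys)
  loc_max <- which(ys[2:(n - 1)] >= ys[1:(n - 2)] & ys[2:(n - 1)] > ys[3:n]) + 1L
  big <- loc_max[ys[loc_max] >= baseline + 0.8 * amplitude]
  i_pk <- if (length(big)) big[1] else which.max(ys)
  lev90 <- baseline + 0.10 * amplitude
  t_end <- cross_down(t, ys, lev90, from = i_pk)
  if (is.na(t_end)) t_end <- max(t)
  win <- which(t > t[i_pk] & t <= t_end)
  if (length(win) < 4) return(FALSE)
  dy <- sg_smooth(y, fs, smooth_window_ms, m = 1)
  sgn <- sign(dy[win])
  flips <- which(sgn[-length(sgn)] < 0 & sgn[-1] > 0)
  for (f in flips) {
    i_min <- win[f]
    after <- win[win >= i_min]
    y_min <- ys[i_min]
    rise <- max(ys[after]) - y_min
    if (rise < min_amp_frac * amplitude) next
    above <- after[ys[after] >= y_min + 0.5 * rise]
    if (length(above) && (t[max(above)] - t[min(above)]) >= min_duration_ms) {
      return(TRUE)
    }
  }
  FALSE
}

#' Per-beat metric table for one or more tissues
#'
#' Runs the complete per-beat analysis: beat detection and capture
#' classification, upstroke metrics, APD30/50/80, APD_MxR, triangulation and
#' EAD flag. Metrics of non-captured beats are `NA`. EAD-bearing beats keep
#' their APD values (EADs can dramatically prolong APD and must stay in the
#' summaries).
#'
#' @param traces Long tibble with columns `tissue`, `time_ms`, `df_f`.
#' @param protocol A [stim_protocol()] object.
#' @param capture_window_ms,capture_amp_frac Capture rule, see
#'   [detect_beats()].
#' @param smooth_window_ms Window for upstroke-derivative smoothing, ms.
#' @param mxr_smooth_window_ms Window for the second derivative, ms.
#' @param ead_min_amp_frac,ead_min_duration_ms EAD detector thresholds.
#' @return Tibble, one row per tissue x stimulus, with columns `tissue`,
#'   `beat`, `stimulus_time_ms`, `captured`, `amplitude`, `stim_delay_ms`,
#'   `rise_time_ms`, `apd30_ms`, `apd50_ms`, `apd80_ms`, `apd_mxr_ms`,
#'   `apd_tri_ms`, `ead`.
#' @export
beat_metrics <- function(traces, protocol, capture_window_ms = 300,
                         capture_amp_frac = 0.5, smooth_window_ms = 5,
                         mxr_smooth_window_ms = 11, ead_min_amp_frac = 0.05,
                         ead_min_duration_ms = 20) {
  stopifnot(all(c("tissue", "time_ms", "df_f") %in% names(traces)))
  traces %>%
    group_by(.data$tissue) %>%
    dplyr::group_modify(function(tr, key) {
      beats <- detect_beats(tr, protocol, capture_window_ms,
                            capture_amp_frac, smooth_window_ms)
      purrr::map(seq_len(nrow(beats)), function(b) {
        row <- beats[b, ]
        base <- tibble(beat = row$beat, stimulus_time_ms = row$stimulus_time_ms,
                       captured = row$captured, amplitude = row$amplitude)
        if (!row$captured) {
          return(mutate(base, stim_delay_ms = NA_real_, rise_time_ms = NA_real_,
                        apd30_ms = NA_real_, apd50_ms = NA_real_,
                        apd80_ms = NA_real_, apd_mxr_ms = NA_real_,
                        apd_tri_ms = NA_real_, ead = NA))
        }
        w <- which(tr$time_ms >= row$t_start_ms & tr$time_ms < row$t_end_ms)
        t <- tr$time_ms[w]
        y <- tr$df_f[w]
        up <- upstroke_metrics(t, y, row$stimulus_time_ms, row$baseline,
                               row$amplitude, capture_window_ms,
                               smooth_window_ms)
        apds <- apd_levels(t, y, up$t_act_ms, row$baseline, row$amplitude)
        mxr <- apd_mxr(t, y, up$t_act_ms, apds[["apd50_ms"]],
                       mxr_smooth_window_ms, baseline = row$baseline,
                       amplitude = row$amplitude)
        mutate(base,
               stim_delay_ms = up$stim_delay_ms,
               rise_time_ms = up$rise_time_ms,
               apd30_ms = apds[["apd30_ms"]], apd50_ms = apds[["apd50_ms"]],
               apd80_ms = apds[["apd80_ms"]], apd_mxr_ms = mxr,
               apd_tri_ms = apd_tri(mxr, apds[["apd50_ms"]]),
               ead = detect_ead(t, y, row$baseline, row$amplitude,
                                ead_min_amp_frac, ead_min_duration_ms,
                                mxr_smooth_window_ms))
      }) %>% bind_rows()
    }) %>%
    ungroup()
}

#' Per-tissue summary of beat metrics
#'
#' Excitability, per-metric mean and beat-to-beat sample SD over captured
#' beats, and an EAD-presence flag. Tissues with no captured beat report
#' `NA` metric summaries (when excitability is lost, the other metrics
#' cannot be measured).
#'
#' @param per_beat Tibble from [beat_metrics()].
#' @return Tibble, one row per tissue.
#' @export
summarize_tissues <- function(per_beat) {
  metric_cols <- c("stim_delay_ms", "rise_time_ms", "apd30_ms", "apd50_ms",
                   "apd80_ms", "apd_mxr_ms", "apd_tri_ms")
  per_beat %>%
    group_by(.data$tissue) %>%
    summarise(
      n_stimuli = dplyr::n(),
      n_captured = sum(.data$captured),
      excitability_pct = 100 * sum(.data$captured) / dplyr::n(),
      across(all_of(metric_cols),
             list(mean = ~ if (sum(!is.na(.x)) >= 1) mean(.x, na.rm = TRUE) else NA_real_,
                  sd = ~ if (sum(!is.na(.x)) >= 2) sd(.x, na.rm = TRUE) else NA_real_)),
      ead_present = any(.data$ead, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(ead_present = ifelse(.data$n_captured == 0, NA, .data$ead_present))
}
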