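#' Conductance scales for the minimal ionic action-potential model
#'
#' Dimensionless multipliers on the three currents of the minimal
#' four-variable ventricular model (epicardial parameter set) used for
#' property-level simulation: `g_kr_scale` scales the supra-threshold
#' (phase 2-3) outward current as a rapid delayed-rectifier (I_Kr) surrogate,
#' `g_to_scale` the sub-threshold outward current (transient-outward / inward
#' rectifier surrogate), and `g_cal_scale` the slow inward (L-type calcium)
#' current. `1.0` is baseline; values below 1 model channel block.
#'
#' @param g_kr_scale,g_to_scale,g_cal_scale Conductance multipliers (>= 0).
#' @param pacing_cl_ms Pacing cycle length, ms (>= 400).
#' @param n_beats_to_steady Beats paced before the analysed beat.
#' @return A list of class `"ionic_scales"`.
#' @export
ionic_scales <- function(g_kr_scale = 1, g_to_scale = 1, g_cal_scale = 1,
                         pacing_cl_ms = 2000, n_beats_to_steady = 8) {
  if (any(c(g_kr_scale, g_to_scale, g_cal_scale) < 0)) {
    abort("conductance scales must be >= 0.")
  }
  if (pacing_cl_ms < 400) abort("`pacing_cl_ms` must be >= 400 ms.")
  if (n_beats_to_steady < 1) abort("`n_beats_to_steady` must be >= 1.")
  structure(
    list(g_kr_scale = g_kr_scale, g_to_scale = g_to_scale,
         g_cal_scale = g_cal_scale, pacing_cl_ms = pacing_cl_ms,
         n_beats_to_steady = n_beats_to_steady),
    class = "ionic_scales"
  )
}

#' Simulate a steady-state paced action potential
#'
#' Integrates the minimal four-variable ventricular model (epicardial
#' parameters, forward Euler at `dt_ms`) under the given conductance scales,
#' paces `n_beats_to_steady` beats to reach a period-1 steady state, and
#' returns the last beat with its metrics computed by the measurement
#' pipeline ([beat_metrics()]).
#'
#' @param scales An [ionic_scales()] object.
#' @param dt_ms Integration step, ms.
#' @param out_rate_hz Output sampling rate, Hz.
#' @return A list with `trace` (tibble `time_ms`, `value`: the final paced
#'   beat, diastole near 0) and `metrics` (one-row tibble from
#'   [beat_metrics()]).
#' @export
#' @examples
#' ap <- simulate_ionic_ap(ionic_scales(pacing_cl_ms = 1000, n_beats_to_steady = 4))
#' ap$metrics[, c("apd50_ms", "apd80_ms", "apd_tri_ms")]
simulate_ionic_ap <- function(scales = ionic_scales(), dt_ms = 0.02,
                              out_rate_hz = 2000) {
  stopifnot(inherits(scales, "ionic_scales"))
  sim <- bocf_pace_cpp(scales$g_to_scale, scales$g_kr_scale,
                       scales$g_cal_scale, scales$pacing_cl_ms,
                       scales$n_beats_to_steady + 1L, dt_ms, out_rate_hz)
  tt <- sim$time_ms
  uu <- sim$u
  # keep the final beat only
  t0 <- scales$n_beats_to_steady * scales$pacing_cl_ms
  keep <- tt >= t0 & tt < t0 + scales$pacing_cl_ms
  trace <- tibble(time_ms = tt[keep] - t0, value = uu[keep])
  protocol <- stim_protocol(
    cycle_length_ms = scales$pacing_cl_ms,
    first_pulse_ms = 0,
    recording_duration_ms = scales$pacing_cl_ms
  )
  traces <- dplyr::mutate(trace, tissue = 1L, df_f = .data$value)
  bm <- beat_metrics(traces[, c("tissue", "time_ms", "df_f")], protocol)
  list(trace = trace, metrics = bm)
}

#' Steady-state APD80 trajectory across paced beats
#'
#' Helper for convergence checks: APD80 of each successive paced beat.
#'
#' @inheritParams simulate_ionic_ap
#' @param n_beats Number of beats to pace and measure.
#' @return Tibble with `beat` and `apd80_ms`.
#' @export
ionic_beat_series <- function(scales = ionic_scales(), n_beats = 8,
                              dt_ms = 0.02, out_rate_hz = 2000) {
  sim <- bocf_pace_cpp(scales$g_to_scale, scales$g_kr_scale,
                       scales$g_cal_scale, scales$pacing_cl_ms,
                       n_beats, dt_ms, out_rate_hz)
  protocol <- stim_protocol(
    cycle_length_ms = scales$pacing_cl_ms, first_pulse_ms = 0,
    recording_duration_ms = n_beats * scales$pacing_cl_ms
  )
  traces <- tibble(tissue = 1L, time_ms = sim$time_ms, df_f = sim$u)
  bm <- beat_metrics(traces, protocol)
  tibble(beat = seq_len(nrow(bm)), apd80_ms = bm$apd80_ms)
}

#' Simulate an ionic dose series for the triangulation-slope analysis
#'
#' Generates per-tissue (APD_MxR, APD_tri) points across a graded
#' conductance-block dose series: every tissue receives independent
#' lognormal jitter (coefficient of variation `jitter_cv`) on all three
#' conductance scales — cell-line and tissue-to-tissue variability — and the
#' dose multiplies the targeted conductance. Feeding the result to
#' [tri_mxr_slopes()] reproduces the hERG-block slope indicator: graded
#' I_Kr-surrogate block steepens the APD_tri-vs-APD_MxR slope, while
#' transient-outward block or moderate L-type calcium augmentation does not.
#'
#' @param which One of `"gkr"`, `"gto"`, `"gcal"`: the conductance the dose
#'   series targets.
#' @param dose_scales Conductance multipliers, first entry the control (1).
#' @param n_tissues Tissues per dose.
#' @param seed Integer seed.
#' @param jitter_cv Lognormal CV of tissue-level conductance variability.
#' @param pacing_cl_ms,n_beats_to_steady,dt_ms Passed to the integrator.
#' @return Tibble with `dose` (0 = control, then 1, 2, ...), `scale`,
#'   `tissue`, `apd_mxr_ms`, `apd_tri_ms`, `apd80_ms`.
#' @export
simulate_dose_slope_data <- function(which = c("gkr", "gto", "gcal"),
                                     dose_scales = c(1, 0.75, 0.55, 0.4),
                                     n_tissues = 12, seed = 1,
                                     jitter_cv = 0.10, pacing_cl_ms = 2000,
                                     n_beats_to_steady = 6, dt_ms = 0.025) {
  which <- match.arg(which)
  set.seed(seed)
  out <- list()
  for (d in seq_along(dose_scales)) {
    for (i in seq_len(n_tissues)) {
      g <- exp(rnorm(3, 0, jitter_cv))
      names(g) <- c("gkr", "gto", "gcal")
      g[which] <- g[which] * dose_scales[d]
      m <- simulate_ionic_ap(
        ionic_scales(g_kr_scale = g[["gkr"]], g_to_scale = g[["gto"]],
                     g_cal_scale = g[["gcal"]], pacing_cl_ms = pacing_cl_ms,
                     n_beats_to_steady = n_beats_to_steady),
        dt_ms = dt_ms)$metrics
      out[[length(out) + 1]] <- tibble(
        dose = d - 1L, scale = dose_scales[d], tissue = i,
        apd_mxr_ms = m$apd_mxr_ms[1], apd_tri_ms = m$apd_tri_ms[1],
        apd80_ms = m$apd80_ms[1])
    }
  }
  bind_rows(out)
}
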