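#' Parametric action-potential waveform specification
#'
#' Describes an idealised optical action potential as the product of two
#' logistic sigmoids (upstroke and phase-3 repolarization) and an exponential
#' plateau decay, optionally carrying an early-afterdepolarization (EAD) bump
#' during repolarization. The family is chosen so that APD30/50/80, the point
#' of maximum repolarization rate and triangulation can be steered
#' independently.
#'
#' @param amplitude Peak deflection (dimensionless ΔF/F). Must be > 0.
#' @param t_activation Time of the upstroke midpoint (time of maximum dF/dt),
#'   ms from trace start.
#' @param tau_up Upstroke steepness time constant, ms. `0` gives a hard step.
#' @param t_repol Phase-3 repolarization midpoint, ms.
#' @param tau_repol Phase-3 steepness time constant, ms. `0` gives a hard step.
#' @param plateau_decay Exponential plateau decay rate, 1/ms.
#' @param ead Optional EAD description: a list with `t_onset_ms` (bump centre,
#'   must lie between the AP peak and `t_repol`), `amp_frac` (bump height as a
#'   fraction of `amplitude`) and `width_ms` (full width at half maximum).
#' @param sampling_rate_hz Sampling rate used by [make_ap_waveform()], Hz.
#' @param duration_ms Trace length, ms; defaults to
#'   `t_repol + 8 * tau_repol + 150` so the tail is fully covered.
#'
#' @return A list of class `"waveform_params"`.
#' @export
#' @examples
#' p <- waveform_params(t_repol = 350)
#' wf <- make_ap_waveform(p)
#' wf$truth
waveform_params <- function(amplitude = 1,
                            t_activation = 100,
                            tau_up = 2,
                            t_repol = 350,
                            tau_repol = 15,
                            plateau_decay = 5e-4,
                            ead = NULL,
                            sampling_rate_hz = 979,
                            duration_ms = NULL) {
  if (amplitude <= 0) abort("`amplitude` must be > 0.")
  if (tau_up < 0 || tau_repol < 0) abort("time constants must be >= 0.")
  if (plateau_decay < 0) abort("`plateau_decay` must be >= 0.")
  if (t_repol <= t_activation + 5 * tau_up) {
    abort("upstroke must complete before `t_repol` (t_repol > t_activation + 5 * tau_up).")
  }
  if (sampling_rate_hz <= 0) abort("`sampling_rate_hz` must be > 0.")
  if (is.null(duration_ms)) duration_ms <- t_repol + 8 * tau_repol + 150
  if (duration_ms < t_repol + 5 * tau_repol) {
    abort("`duration_ms` must cover t_repol + 5 * tau_repol.")
  }
  if (!is.null(ead)) {
    need <- c("t_onset_ms", "amp_frac", "width_ms")
    if (!all(need %in% names(ead))) {
      abort("`ead` needs fields t_onset_ms, amp_frac, width_ms.")
    }
    if (ead$t_onset_ms <= t_activation + 5 * tau_up || ead$t_onset_ms >= t_repol) {
      abort("EAD onset must lie between the AP peak and `t_repol`.")
    }
    if (ead$amp_frac <= 0 || ead$width_ms <= 0) abort("EAD amplitude and width must be > 0.")
  }
  structure(
    list(amplitude = amplitude, t_activation = t_activation, tau_up = tau_up,
         t_repol = t_repol, tau_repol = tau_repol, plateau_decay = plateau_decay,
         ead = ead, sampling_rate_hz = sampling_rate_hz, duration_ms = duration_ms),
    class = "waveform_params"
  )
}

# Evaluate the analytic waveform on arbitrary times (ms); diastole = 0,
# depolarization positive, peak ~ amplitude.
eval_waveform <- function(params, t_ms) {
  p <- params
  up <- if (p$tau_up > 0) plogis((t_ms - p$t_activation) / p$tau_up) else
    as.numeric(t_ms >= p$t_activation)
  rep_ <- if (p$tau_repol > 0) plogis(-(t_ms - p$t_repol) / p$tau_repol) else
    as.numeric(t_ms < p$t_repol)
  plat <- exp(-p$plateau_decay * pmax(t_ms - p$t_activation, 0))
  w <- p$amplitude * up * rep_ * plat
  if (!is.null(p$ead)) {
    sigma <- p$ead$width_ms / (2 * sqrt(2 * log(2)))
    w <- w + p$amplitude * p$ead$amp_frac *
      exp(-(t_ms - p$ead$t_onset_ms)^2 / (2 * sigma^2)) * rep_
  }
  w
}

# First time y crosses `level` downward after index `from`, linearly
# interpolated; NA if never crossed.
cross_down <- function(t, y, level, from = 1L) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- which(y[from:(n - 1)] > level & y[(from + 1):n] <= level)
  if (!length(idx)) return(NA_real_)
  i <- from + idx[1] - 1L
  frac <- (y[i] - level) / (y[i] - y[i + 1])
  t[i] + frac * (t[i + 1] - t[i])
}

# First upward crossing of `level` at or after index `from`.
cross_up <- function(t, y, level, from = 1L) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- which(y[from:(n - 1)] < level & y[(from + 1):n] >= level)
  if (!length(idx)) return(NA_real_)
  i <- from + idx[1] - 1L
  frac <- (level - y[i]) / (y[i + 1] - y[i])
  t[i] + frac * (t[i + 1] - t[i])
}

# Brute-force metric oracle by direct definition scan on a dense grid.
# Used as ground truth against the sampled-trace pipeline.
waveform_oracle <- function(params, oracle_rate_hz = 1e4) {
  dt <- 1000 / oracle_rate_hz
  t <- seq(0, params$duration_ms, by = dt)
  y <- eval_waveform(params, t)
  amp <- max(y)
  i_pk <- which.max(y)
  d1 <- diff(y)
  i_act <- which.max(d1[seq_len(i_pk)])
  t_act <- (t[i_act] + t[i_act + 1]) / 2
  t10 <- cross_up(t, y, 0.10 * amp)
  t90 <- cross_up(t, y, 0.90 * amp)
  apd <- vapply(c(30, 50, 80), function(x) {
    tc <- cross_down(t, y, (1 - x / 100) * amp, from = i_pk)
    tc - t_act
  }, numeric(1))
  # maximum repolarization rate: arg-max of the second difference in the
  # window from the APD50 crossing to the end of the trace
  t50_abs <- apd[2] + t_act
  n <- length(y)
  d2c <- c(NA, y[1:(n - 2)] - 2 * y[2:(n - 1)] + y[3:n], NA) # centred, time t[i]
  i_from <- max(2L, which(t >= t50_abs)[1])
  cand <- i_from:(n - 1L)
  i_mxr <- cand[which.max(d2c[cand])]
  apd_mxr <- t[i_mxr] - t_act
  tibble(
    apd30_ms = apd[1], apd50_ms = apd[2], apd80_ms = apd[3],
    apd_mxr_ms = apd_mxr, apd_tri_ms = apd_mxr - apd[2],
    rise_time_ms = t90 - t10, t_act_ms = t_act, amplitude = amp,
    has_ead = !is.null(params$ead)
  )
}

#' Generate a sampled action-potential waveform with ground truth
#'
#' Samples the analytic waveform described by a [waveform_params()] object at
#' its stated sampling rate and computes ground-truth metrics
#' (APD30/50/80, APD at maximum repolarization rate, triangulation, rise time)
#' with a brute-force dense-grid scan of the analytic waveform at
#' `oracle_rate_hz` (default 10 kHz), independent of the measurement pipeline.
#'
#' @param params A [waveform_params()] object.
#' @param oracle_rate_hz Grid rate for the truth scan, Hz (>= 10 kHz advised).
#' @return A list with `trace` (tibble: `time_ms`, `value`) and `truth`
#'   (one-row tibble of oracle metrics).
#' @export
make_ap_waveform <- function(params, oracle_rate_hz = 1e4) {
  stopifnot(inherits(params, "waveform_params"))
  dt <- 1000 / params$sampling_rate_hz
  t <- seq(0, params$duration_ms, by = dt)
  trace <- tibble(time_ms = t, value = eval_waveform(params, t))
  list(trace = trace, truth = waveform_oracle(params, oracle_rate_hz))
}

#' Draw random waveform parameter sets
#'
#' Samples waveform parameters spanning the physiological APD range
#' (roughly 100-600 ms) for oracle-equivalence testing.
#'
#' @param n Number of parameter sets.
#' @param seed Integer seed.
#' @param with_ead Fraction of draws carrying an EAD bump (default 0).
#' @return A list of [waveform_params()] objects.
#' @export
random_waveform_params <- function(n, seed, with_ead = 0) {
  set.seed(seed)
  purrr::map(seq_len(n), function(i) {
    t_act <- 100
    apd_target <- stats::runif(1, 100, 600)
    tau_rep <- stats::runif(1, 8, 35)
    tau_up <- stats::runif(1, 1, 4)
    lam <- stats::runif(1, 0, 8e-4)
    ead <- NULL
    if (stats::runif(1) < with_ead) {
      ead <- list(
        t_onset_ms = t_act + 0.55 * apd_target,
        amp_frac = stats::runif(1, 0.08, 0.25),
        width_ms = stats::runif(1, 30, 60)
      )
    }
    waveform_params(
      amplitude = stats::runif(1, 0.5, 1.5), t_activation = t_act,
      tau_up = tau_up, t_repol = t_act + apd_target, tau_repol = tau_rep,
      plateau_decay = lam, ead = ead
    )
  })
}
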