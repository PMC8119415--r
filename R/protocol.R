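#' Stimulation protocol
#'
#' Describes the field-stimulation pacing protocol of a recording. Pulse
#' times may be given explicitly; otherwise they are derived from the cycle
#' length and first-pulse offset over the recording duration.
#'
#' @param cycle_length_ms Basic pacing cycle length, ms (default 2000 ms,
#'   i.e. 0.5 Hz).
#' @param first_pulse_ms Onset of the first pulse, ms.
#' @param pulse_duration_ms Pulse width, ms.
#' @param recording_duration_ms Recording length, ms.
#' @param pulse_times_ms Optional explicit pulse onsets, ms (overrides the
#'   derived train).
#' @return A list of class `"stim_protocol"` with the resolved
#'   `pulse_times_ms`.
#' @export
stim_protocol <- function(cycle_length_ms = 2000, first_pulse_ms = 500,
                          pulse_duration_ms = 4, recording_duration_ms = 10000,
                          pulse_times_ms = NULL) {
  if (cycle_length_ms <= 0) abort("`cycle_length_ms` must be > 0.")
  if (recording_duration_ms <= 0) abort("`recording_duration_ms` must be > 0.")
  if (is.null(pulse_times_ms)) {
    pulse_times_ms <- seq(first_pulse_ms, recording_duration_ms,
                          by = cycle_length_ms)
    pulse_times_ms <- pulse_times_ms[pulse_times_ms < recording_duration_ms]
  } else {
    pulse_times_ms <- sort(pulse_times_ms)
  }
  if (!length(pulse_times_ms)) abort("protocol contains no stimulus pulses.")
  if (any(pulse_times_ms < 0) || any(pulse_times_ms >= recording_duration_ms)) {
    abort("stimulus pulses must lie within the recording.")
  }
  structure(
    list(cycle_length_ms = cycle_length_ms,
         pulse_duration_ms = pulse_duration_ms,
         recording_duration_ms = recording_duration_ms,
         pulse_times_ms = pulse_times_ms),
    class = "stim_protocol"
  )
}
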