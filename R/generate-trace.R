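#' Generate a synthetic umbilical velocity waveform
#'
#' Produces a periodic velocity trace with a half-rectified raised-cosine
#' systolic peak atop a diastolic baseline:
#' \deqn{v(t) = EDV + (PSV - EDV)\,\max(0, \cos(2\pi f_H t - \pi)) + \epsilon,}
#' so each cycle has maximum `psv`, minimum `edv`, and analytic time-averaged
#' velocity \eqn{EDV + (PSV - EDV)/\pi}. The trace starts in diastole, so
#' every systolic peak lies in the interior of the recording (peak times
#' `(k + 1/2) / heart_rate`). The shape is a documented modelling choice —
#' any waveform with controllable max/min/mean would do — not a
#' physiological claim.
#'
#' @param psv Peak systolic velocity (mm/s); `psv >= edv >= 0`.
#' @param edv End-diastolic (minimum) velocity (mm/s).
#' @param heart_rate Cardiac frequency (Hz), > 0.
#' @param duration Trace length (s); must cover at least 3 cycles.
#' @param sampling_rate Samples per second (Hz).
#' @param noise_sd Additive Gaussian velocity noise SD (mm/s).
#' @param trace_id Identifier recorded on the trace.
#' @param seed Optional integer seed.
#'
#' @return Tibble of class `velocity_trace` with columns `trace_id`, `time`
#'   (s) and `velocity` (mm/s); attributes record the generator inputs.
#' @export
#' @examples
#' tr <- generate_velocity_trace(80, 15, heart_rate = 2, duration = 3)
#' aggregate_trace(tr)
generate_velocity_trace <- function(psv, edv, heart_rate, duration,
                                    sampling_rate = 200, noise_sd = 0,
                                    trace_id = "trace1", seed = NULL) {
  if (psv < edv || edv < 0) abort("need `psv` >= `edv` >= 0.")
  check_number(heart_rate, "heart_rate", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (duration * heart_rate < 3) {
    abort("`duration` must cover at least 3 cardiac cycles at `heart_rate`.")
  }
  t <- seq(0, duration, by = 1 / sampling_rate)
  t <- t[t < duration]
  draw <- function() {
    v <- edv + (psv - edv) * pmax(0, cos(2 * pi * heart_rate * t - pi))
    if (noise_sd > 0) v <- v + noise_sd * rnorm(length(t))
    out <- tibble::tibble(trace_id = trace_id, time = t, velocity = v)
    structure(out,
              class = c("velocity_trace", class(out)),
              psv = psv, edv = edv, heart_rate = heart_rate,
              mv_analytic = edv + (psv - edv) / pi)
    }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Analytic cycle mean of the synthetic waveform
#'
#' Time-averaged velocity of one cycle of the half-rectified raised-cosine
#' waveform used by [generate_velocity_trace()]: `edv + (psv - edv) / pi`.
#'
#' @inheritParams generate_velocity_trace
#' @return Mean velocity (mm/s).
#' @export
analytic_cycle_mean <- function(psv, edv) edv + (psv - edv) / pi
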