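#' Detect cardiac cycles in a velocity trace
#'
#' Locates systolic peaks as the maxima of contiguous excursions above a
#' prominence threshold (`min(v) + prominence * (max(v) - min(v))`), then
#' delimits cycles peak-to-peak. A trace with `n` detected peaks therefore
#' yields `n - 1` full segments; this peak-to-peak convention is deliberate
#' so every segment spans exactly one full cardiac cycle.
#'
#' @param trace Tibble with `time` (s, strictly increasing, near-uniform) and
#'   `velocity` (mm/s) columns, e.g. from [generate_velocity_trace()] or
#'   [read_trace_table()].
#' @param prominence Fraction of the trace amplitude a systolic excursion
#'   must exceed, in (0, 1); default 0.2.
#' @param min_cycles Minimum number of full segments for a reportable trace.
#'
#' @return Tibble with one row per full cycle segment: `cycle`, `start`,
#'   `end` (s) and `peak_time`; attribute `n_peaks` carries the raw peak
#'   count. Errors if fewer than `min_cycles` segments are found (including
#'   the degenerate constant trace, which has no periodicity).
#' @export
#' @examples
#' tr <- generate_velocity_trace(80, 15, heart_rate = 2, duration = 3)
#' detect_cycles(tr)
detect_cycles <- function(trace, prominence = 0.2, min_cycles = 3) {
  check_trace(trace)
  check_number(prominence, "prominence", lower = 0, upper = 1,
               strict_lower = TRUE)
  v <- trace$velocity
  tm <- trace$time
  amp <- max(v) - min(v)
  if (amp <= 0) {
    abort("constant trace: no cardiac cycles detectable.")
  }
  thr <- min(v) + prominence * amp
  above <- v > thr
  # contiguous above-threshold runs; each systolic excursion is one run
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  peak_idx <- purrr::map_int(which(run$values), function(i) {
    span <- starts[i]:ends[i]
    span[which.max(v[span])]
  })
  # an excursion whose maximum sits on the first or last sample is truncated
  # by the recording window; its true peak may lie outside, so drop it
  peak_idx <- peak_idx[peak_idx > 1L & peak_idx < length(v)]
  n_peaks <- length(peak_idx)
  n_segments <- max(0L, n_peaks - 1L)
  if (n_segments < min_cycles) {
    abort(sprintf(
      "only %d full cycle(s) detected; at least %d cardiac cycles required.",
      n_segments, min_cycles))
  }
  segs <- tibble::tibble(
    cycle = seq_len(n_segments),
    start = tm[peak_idx[-n_peaks]],
    end = tm[peak_idx[-1L]],
    peak_time = tm[peak_idx[-n_peaks]]
  )
  attr(segs, "n_peaks") <- n_peaks
  segs
}

#' Velocimetry measures of one cycle segment
#'
#' PSV is the segment maximum, MDV the minimum, and MV the trapezoidal
#' time-average of velocity over the segment.
#'
#' @param time,velocity Numeric vectors covering one cycle (>= 4 samples).
#' @return Tibble with one row: `psv`, `mdv`, `mv` (mm/s).
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' cycle_measures(t, 100 * t)   # linear ramp: mv = 50
cycle_measures <- function(time, velocity) {
  if (length(time) < 4 || length(time) != length(velocity)) {
    abort("a cycle segment needs >= 4 (time, velocity) samples.")
  }
  dt <- diff(time)
  mv <- sum(dt * (head(velocity, -1) + velocity[-1]) / 2) / (max(time) - min(time))
  tibble::tibble(psv = max(velocity), mdv = min(velocity), mv = mv)
}

#' Pulsatility index
#'
#' `PI = (PSV - MDV) / MV`, with PSV the peak systolic velocity, MDV the
#' minimum (end-)diastolic velocity and MV the time-averaged velocity. PI is
#' dimensionless and invariant under rescaling of all three velocities.
#'
#' @param psv,mdv,mv Velocities (mm/s); `mv` must be > 0.
#' @return Numeric PI (vectorised).
#' @export
#' @examples
#' pulsatility_index(100, 20, 60)  # 1.3333
pulsatility_index <- function(psv, mdv, mv) {
  if (any(mv <= 0)) abort("mean velocity must be > 0 (non-physiological trace).")
  (psv - mdv) / mv
}

#' Aggregate per-cycle velocimetry over a trace
#'
#' Detects cycles, computes per-cycle PSV/MDV/MV, averages them across cycles,
#' and reports the pulsatility index two ways: `pi` from the cycle-averaged
#' PSV/MDV/MV (the default interpretation, matching a formula applied to
#' single summary values) and `pi_per_cycle_mean`, the mean of per-cycle PIs.
#' On identical cycles the two coincide.
#'
#' @inheritParams detect_cycles
#' @return One-row tibble: `trace_id`, `n_cycles`, `psv`, `mdv`, `mv`, `pi`,
#'   `pi_per_cycle_mean`.
#' @export
#' @examples
#' tr <- generate_velocity_trace(80, 15, heart_rate = 2, duration = 3)
#' aggregate_trace(tr)
aggregate_trace <- function(trace, prominence = 0.2, min_cycles = 3) {
  check_trace(trace)
  segs <- detect_cycles(trace, prominence = prominence,
                        min_cycles = min_cycles)
  per_cycle <- purrr::pmap_dfr(
    segs[c("start", "end")],
    function(start, end) {
      keep <- trace$time >= start & trace$time <= end
      cycle_measures(trace$time[keep], trace$velocity[keep])
    }
  )
  means <- dplyr::summarise(per_cycle,
                            psv = mean(.data$psv), mdv = mean(.data$mdv),
                            mv = mean(.data$mv))
  tibble::tibble(
    trace_id = if ("trace_id" %in% names(trace)) trace$trace_id[1] else NA_character_,
    n_cycles = nrow(segs),
    psv = means$psv, mdv = means$mdv, mv = means$mv,
    pi = pulsatility_index(means$psv, means$mdv, means$mv),
    pi_per_cycle_mean = mean(
      pulsatility_index(per_cycle$psv, per_cycle$mdv, per_cycle$mv))
  )
}

check_trace <- function(trace) {
  if (!is.data.frame(trace) ||
      !all(c("time", "velocity") %in% names(trace))) {
    abort("`trace` must be a data frame with `time` and `velocity` columns.")
  }
  if (nrow(trace) < 4 || any(diff(trace$time) <= 0)) {
    abort("`trace$time` must be strictly increasing with >= 4 samples.")
  }
  invisible(trace)
}
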