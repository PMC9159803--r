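#' Compute eye movement speed from a gaze trace
#'
#' Positions are first passed through a 3-sample median filter (suppressing
#' single-sample tracker spikes without blurring saccade onsets), then
#' differentiated with a central difference. Speed is the magnitude of the
#' (x, y) derivative in degrees/s. Invalid samples propagate: the speed at a
#' sample is NA if the sample itself or either neighbor used by the central
#' difference is invalid, and the first and last samples are NA.
#'
#' @param trace a [gaze_trace()].
#' @return Numeric vector of speeds (degrees/s), NA where undefined.
#' @export
compute_speed <- function(trace) {
  n <- nrow(trace)
  if (n < 3 || sum(trace$valid) < 3) return(rep(NA_real_, n))
  xm <- median3(trace$x_deg)
  ym <- median3(trace$y_deg)
  t <- trace$time_ms
  lag <- function(v) c(NA, v[-n])
  lead <- function(v) c(v[-1], NA)
  dtm <- lead(t) - lag(t)            # ms
  vx <- (lead(xm) - lag(xm)) / dtm * 1000
  vy <- (lead(ym) - lag(ym)) / dtm * 1000
  sp <- sqrt(vx^2 + vy^2)
  bad <- !trace$valid
  sp[bad | c(FALSE, bad[-n]) | c(bad[-1], FALSE)] <- NA_real_
  sp
}

# vectorized 3-point running median; an NA neighbor falls back to the
# center value, an NA center stays NA
median3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  a <- c(NA, v[-n])
  b <- v
  c_ <- c(v[-1], NA)
  a[is.na(a)] <- b[is.na(a)]
  c_[is.na(c_)] <- b[is.na(c_)]
  a + b + c_ - pmax(a, b, c_) - pmin(a, b, c_)
}

#' Dynamic saccade detection threshold
#'
#' Threshold for one trial: mean plus `noise_multiplier` (2.5) standard
#' deviations of the background speed noise during fixation, floored at
#' `min_threshold` (20 degrees/s). With fewer than `min_fixation_samples`
#' valid fixation speed samples the floor is returned and a warning raised.
#'
#' @param fixation_speeds speed samples (degrees/s) from the fixation epoch;
#'   NAs are dropped.
#' @param params a [detection_params()].
#' @return Threshold in degrees/s.
#' @export
dynamic_threshold <- function(fixation_speeds, params = detection_params()) {
  s <- fixation_speeds[!is.na(fixation_speeds)]
  if (length(s) < params$min_fixation_samples) {
    warning("insufficient fixation samples; using minimum threshold")
    return(params$min_threshold)
  }
  max(mean(s) + params$noise_multiplier * stats::sd(s), params$min_threshold)
}

#' Detect saccades in a gaze trace
#'
#' Computes per-sample speed, estimates the trial's dynamic threshold from
#' the fixation epoch (FP onset + `fixation_guard` through FP offset, valid
#' samples only), and returns every maximal run of consecutive
#' supra-threshold samples lasting at least `min_duration` ms (5 samples at
#' 500 Hz, inclusive) as a saccade. Runs are split by sub-threshold or
#' invalid samples, so a saccade never spans a blink. Onsets/offsets are the
#' first/last sample of the run; start/end positions are the raw positions
#' at those samples.
#'
#' @param trace a [gaze_trace()].
#' @param params a [detection_params()].
#' @param threshold optional precomputed threshold (degrees/s), bypassing the
#'   fixation-epoch estimate.
#' @return A data.frame of class `saccade_events` with one row per saccade:
#'   `onset_ms`, `offset_ms`, `start_x`, `start_y`, `end_x`, `end_y`,
#'   `amplitude`, `peak_speed`; zero rows when nothing qualifies.
#' @export
detect_saccades <- function(trace, params = detection_params(),
                            threshold = NULL) {
  speed <- compute_speed(trace)
  if (is.null(threshold)) {
    ev <- attr(trace, "events")
    fix <- trace$time_ms >= ev$fp_on + params$fixation_guard &
      trace$time_ms <= ev$fp_off
    threshold <- dynamic_threshold(speed[fix], params)
  }
  events_from_speed(trace, speed, threshold, params)
}

# shared run-extraction core: maximal supra-threshold runs of sufficient
# duration become events
events_from_speed <- function(trace, speed, threshold, params) {
  dt <- if (nrow(trace) > 1) stats::median(diff(trace$time_ms)) else NA_real_
  min_samples <- ceiling(params$min_duration / dt)
  above <- !is.na(speed) & speed > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_samples
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      start_x = numeric(0), start_y = numeric(0),
                      end_x = numeric(0), end_y = numeric(0),
                      amplitude = numeric(0), peak_speed = numeric(0))
  class(empty) <- c("saccade_events", "data.frame")
  if (!any(keep)) return(empty)
  i0 <- starts[keep]
  i1 <- ends[keep]
  out <- data.frame(
    onset_ms = trace$time_ms[i0],
    offset_ms = trace$time_ms[i1],
    start_x = trace$x_deg[i0], start_y = trace$y_deg[i0],
    end_x = trace$x_deg[i1], end_y = trace$y_deg[i1],
    peak_speed = vapply(seq_along(i0),
                        function(k) max(speed[i0[k]:i1[k]]), numeric(1))
  )
  out$amplitude <- sqrt((out$end_x - out$start_x)^2 + (out$end_y - out$start_y)^2)
  out <- out[, c("onset_ms", "offset_ms", "start_x", "start_y",
                 "end_x", "end_y", "amplitude", "peak_speed")]
  class(out) <- c("saccade_events", "data.frame")
  attr(out, "threshold") <- threshold
  out
}
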