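# Feature extraction from per-second driving signals.  All extractors
# canonicalize the trace to 1 Hz first (whole-second averages; the brake
# flag counts a second as braking if engaged at any sample) and are
# invariant to re-timestamping since only sample order matters.

# returns list of per-second series
canonical_1hz <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  hz <- trace$hz
  if (hz == 1L) {
    return(list(speed = trace$speed, angle = trace$steering_angle,
                brake = trace$brake_engaged, limit = trace$speed_limit))
  }
  n_sec <- length(trace$speed) %/% hz
  if (n_sec < 1) stop("trace must cover at least 1 full second")
  idx <- rep(seq_len(n_sec), each = hz)
  keep <- seq_len(n_sec * hz)
  avg <- function(v) as.numeric(tapply(v[keep], idx, mean))
  list(speed = avg(trace$speed),
       angle = avg(trace$steering_angle),
       brake = as.numeric(tapply(trace$brake_engaged[keep], idx, any)) > 0,
       limit = avg(trace$speed_limit))
}

#' Steering ratio of a trip
#'
#' Fraction of the trip during which the driver was turning the steering
#' wheel: the share of seconds whose absolute steering-angle change
#' exceeds `angle_rate_threshold`.
#'
#' @param trace a [signal_trace()].
#' @param angle_rate_threshold degrees per second above which a second
#'   counts as turning (default 2).
#' @return fraction in `[0, 1]`.
#' @export
steering_ratio <- function(trace, angle_rate_threshold = 2) {
  s <- canonical_1hz(trace)
  rate <- c(0, diff(s$angle))
  mean(abs(rate) > angle_rate_threshold)
}

#' Braking ratio of a trip
#'
#' Ratio of the seconds in which the brake pedal was engaged to the total
#' duration of the trip.
#'
#' @param trace a [signal_trace()].
#' @return fraction in `[0, 1]`.
#' @export
braking_ratio <- function(trace) {
  s <- canonical_1hz(trace)
  mean(s$brake)
}

#' Sudden-event rate of a trip
#'
#' Counts sudden accelerations/decelerations and sudden steering: local
#' maxima of the absolute longitudinal acceleration (derived from the
#' speed series) exceeding `accel_threshold`, and of the absolute
#' steering rate exceeding `steer_threshold`.  Peaks from both channels
#' are pooled and peaks closer together than `min_separation` seconds are
#' merged into one event.  The count is normalized to events per hour of
#' driving.
#'
#' @param trace a [signal_trace()].
#' @param accel_threshold m/s^2 (default 2.5).
#' @param steer_threshold degrees/s (default 90).
#' @param min_separation seconds; peaks closer than this merge
#'   (default 2).
#' @return events per hour (nonnegative).
#' @export
count_sudden_events <- function(trace, accel_threshold = 2.5,
                                steer_threshold = 90,
                                min_separation = 2) {
  stopifnot(accel_threshold > 0, steer_threshold > 0)
  s <- canonical_1hz(trace)
  accel <- c(0, diff(s$speed)) / 3.6          # km/h per s -> m/s^2
  srate <- c(0, diff(s$angle))
  peaks <- c(local_peaks(abs(accel), accel_threshold),
             local_peaks(abs(srate), steer_threshold))
  peaks <- sort(peaks)
  count <- 0L
  last <- -Inf
  for (t in peaks) {
    if (t - last >= min_separation) {
      count <- count + 1L
      last <- t
    }
  }
  hours <- length(s$speed) / 3600
  count / hours
}

# indices of strict-threshold local maxima (plateau samples all qualify)
local_peaks <- function(v, threshold) {
  n <- length(v)
  if (n == 0) return(integer(0))
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  which(v > threshold & v >= left & v >= right)
}

#' Flow, trip length and mean speed
#'
#' `flow` is the per-second mean of the ratio of actual speed to the
#' prevailing maximum permissible speed, with each second's ratio capped
#' at 1 (speeding does not raise flow); a standstill second contributes
#' 0.  `trip_length` is the duration in seconds and `mean_speed` the
#' average speed in km/h.
#'
#' @param trace a [signal_trace()].
#' @return `flow()`: fraction in `[0, 1]`; `trip_length()`: seconds;
#'   `mean_speed()`: km/h.
#' @export
flow <- function(trace) {
  s <- canonical_1hz(trace)
  if (any(s$limit <= 0 & s$speed > 0))
    stop("zero or negative speed limit while moving")
  ratio <- ifelse(s$speed <= 0, 0,
                  pmin(s$speed / s$limit, 1))
  mean(ratio)
}

#' @rdname flow
#' @export
trip_length <- function(trace) {
  s <- canonical_1hz(trace)
  length(s$speed)
}

#' @rdname flow
#' @export
mean_speed <- function(trace) {
  s <- canonical_1hz(trace)
  mean(s$speed)
}

#' Extract the study's trip-level features from a signal trace
#'
#' One row per trip with the analysis's driving-behavior and
#' trip-dependent variables: `steering`, `braking`, `sudden_events`
#' (per hour), `length` (s), `speed` (km/h), `flow`.
#'
#' @param trace a [signal_trace()].
#' @param angle_rate_threshold,accel_threshold,steer_threshold,min_separation
#'   passed to the individual extractors.
#' @return one-row data.frame.
#' @export
extract_trip_features <- function(trace, angle_rate_threshold = 2,
                                  accel_threshold = 2.5,
                                  steer_threshold = 90,
                                  min_separation = 2) {
  data.frame(
    steering = steering_ratio(trace, angle_rate_threshold),
    braking = braking_ratio(trace),
    sudden_events = count_sudden_events(trace, accel_threshold,
                                        steer_threshold, min_separation),
    length = trip_length(trace),
    speed = mean_speed(trace),
    flow = flow(trace)
  )
}

#' Extract features for many signal-trace CSVs
#'
#' @param paths character vector of long-format signal CSVs
#'   (see [write_signal_trace()]).
#' @param ... passed to [extract_trip_features()].
#' @return data.frame with one row per trace, `trip` column first.
#' @export
features_from_files <- function(paths, ...) {
  rows <- lapply(paths, function(pp) {
    feats <- extract_trip_features(read_signal_trace(pp), ...)
    cbind(data.frame(trip = basename(pp)), feats)
  })
  do.call(rbind, rows)
}
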