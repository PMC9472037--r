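#' Per-second driving signal trace
#'
#' In-vehicle sensor series for one trip: speed (km/h), steering-wheel
#' angle (degrees), brake-pedal engagement (logical), and the prevailing
#' speed limit (km/h).  All series share one sampling rate `hz`; feature
#' extraction canonicalizes to 1 Hz by averaging whole seconds.
#' Longitudinal acceleration is derived from the speed series.
#'
#' @param speed numeric series, km/h.
#' @param steering_angle numeric series, degrees.
#' @param brake_engaged logical series.
#' @param speed_limit numeric series, km/h (recycled if length 1).
#' @param hz integer samples per second (default 1).
#' @return list of class `signal_trace`.
#' @export
signal_trace <- function(speed, steering_angle, brake_engaged,
                         speed_limit, hz = 1L) {
  n <- length(speed)
  if (length(speed_limit) == 1) speed_limit <- rep(speed_limit, n)
  if (length(steering_angle) != n || length(brake_engaged) != n ||
      length(speed_limit) != n)
    stop("all series must share the same length")
  hz <- as.integer(hz)
  if (hz < 1) stop("`hz` must be a positive integer")
  if (n < hz) stop("trace must cover at least 1 second")
  structure(
    list(speed = as.numeric(speed),
         steering_angle = as.numeric(steering_angle),
         brake_engaged = as.logical(brake_engaged),
         speed_limit = as.numeric(speed_limit),
         hz = hz),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("signal_trace: %.0f s at %d Hz, mean speed %.1f km/h\n",
              length(x$speed) / x$hz, x$hz, mean(x$speed)))
  invisible(x)
}

#' Simulate a driving signal trace with known ground truth
#'
#' Builds a per-second trace from a scenario description so that feature
#' extractors can be validated against construction-time truth: braking
#' episodes with a prescribed total engagement time, steering episodes
#' that turn the wheel at a moderate rate (above the turning threshold,
#' below the sudden-steering threshold), and injected super-threshold
#' spikes in acceleration and steering rate.  Episodes and spikes are
#' placed deterministically with idle gaps so they never overlap; spikes
#' are at least `min_separation`-plus-gap apart so each counts as exactly
#' one sudden event.
#'
#' The ground truth is attached as `attr(trace, "ground_truth")`: a list
#' with `duration_s`, `braking_seconds`, `braking_ratio`,
#' `steering_seconds`, `steering_ratio`, `sudden_events` (a count),
#' `events_per_hour`, `flow` and `mean_speed`.
#'
#' @param trip_params list with entries (all optional except none):
#'   `duration` seconds (default 3600), `base_speed` km/h (50),
#'   `speed_limit` km/h (50), `braking_seconds` total braking time (0),
#'   `n_braking_episodes` (1 if braking requested), `steering_seconds`
#'   total turning time (0; split over `n_steering_episodes`, each an
#'   up-then-down ramp at `steering_rate` deg/s, default 10),
#'   `n_sudden_accel` and `n_sudden_steer` injected spike events (0),
#'   `accel_spike` m/s^2 (5), `steer_spike` deg/s (120), `hz` (1).
#' @param seed optional seed; only used when `speed_jitter_sd > 0` adds
#'   smooth sub-threshold speed noise.
#' @return a [signal_trace()] with a `ground_truth` attribute.
#' @examples
#' tr <- simulate_signals(list(duration = 3600, braking_seconds = 360))
#' attr(tr, "ground_truth")$braking_ratio  # 0.10
#' @export
simulate_signals <- function(trip_params = list(), seed = NULL) {
  p <- trip_params
  duration <- p$duration %||% 3600
  if (duration < 1) stop("`duration` must be at least 1 second")
  hz <- as.integer(p$hz %||% 1L)
  n <- as.integer(round(duration * hz))
  base_speed <- p$base_speed %||% 50
  limit <- p$speed_limit %||% 50
  braking_seconds <- p$braking_seconds %||% 0
  n_brake_ep <- p$n_braking_episodes %||% (if (braking_seconds > 0) 1L else 0L)
  steering_seconds <- p$steering_seconds %||% 0
  n_steer_ep <- p$n_steering_episodes %||% (if (steering_seconds > 0) 1L else 0L)
  steering_rate <- p$steering_rate %||% 10
  n_sudden_accel <- p$n_sudden_accel %||% 0
  n_sudden_steer <- p$n_sudden_steer %||% 0
  accel_spike <- p$accel_spike %||% 5      # m/s^2
  steer_spike <- p$steer_spike %||% 120    # deg/s
  jitter_sd <- p$speed_jitter_sd %||% 0

  speed <- rep(base_speed, n)
  angle <- rep(0, n)
  brake <- rep(FALSE, n)

  gap <- 5L * hz
  cursor <- gap + 1L
  place <- function(len) {
    if (cursor + len + gap > n)
      stop("scenario does not fit in the trace; increase `duration`")
    idx <- cursor:(cursor + len - 1L)
    cursor <<- cursor + len + gap
    idx
  }

  # steering episodes: ramp up then down at steering_rate; every sample in
  # the episode changes the angle by steering_rate/hz, so each counts as a
  # turning second at the default turning threshold
  steer_samp_total <- as.integer(round(steering_seconds * hz))
  turning_samples <- 0L
  if (n_steer_ep > 0 && steer_samp_total > 0) {
    per <- steer_samp_total %/% n_steer_ep
    per <- max(2L, per - per %% 2L)  # even length so the ramp closes
    for (ep in seq_len(n_steer_ep)) {
      idx <- place(per)
      half <- per %/% 2L
      step <- steering_rate / hz
      delta <- c(rep(step, half), rep(-step, half))
      angle[idx] <- angle[idx[1] - 1L] + cumsum(delta)
      turning_samples <- turning_samples + per
    }
  }

  # braking episodes: brake flag raised, speed held (flag-only braking
  # keeps acceleration ground truth clean)
  brake_samp_total <- as.integer(round(braking_seconds * hz))
  braking_samples <- 0L
  if (n_brake_ep > 0 && brake_samp_total > 0) {
    per <- brake_samp_total %/% n_brake_ep
    rem <- brake_samp_total - per * n_brake_ep
    for (ep in seq_len(n_brake_ep)) {
      len <- per + (if (ep <= rem) 1L else 0L)
      if (len == 0L) next
      idx <- place(len)
      brake[idx] <- TRUE
      braking_samples <- braking_samples + len
    }
  }

  # sudden accelerations: one-sample speed bump of accel_spike m/s^2 and
  # immediate return; the up and down peaks are 1/hz s apart and merge
  # into a single event at any min_separation above that
  if (n_sudden_accel > 0) {
    bump <- accel_spike * 3.6 / hz  # km/h change per sample
    for (ev in seq_len(n_sudden_accel)) {
      idx <- place(2L)
      speed[idx[1]] <- speed[idx[1]] + bump
    }
  }

  # sudden steering: one-sample angle pulse at steer_spike deg/s; the two
  # super-threshold rate samples are also turning samples
  if (n_sudden_steer > 0) {
    pulse <- steer_spike / hz
    for (ev in seq_len(n_sudden_steer)) {
      idx <- place(2L)
      angle[idx[1]] <- angle[idx[1]] + pulse
      turning_samples <- turning_samples + 2L
    }
  }

  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    speed <- speed + stats::rnorm(n, sd = jitter_sd)
  }

  trace <- signal_trace(speed, angle, brake, limit, hz = hz)
  dur_s <- n / hz
  attr(trace, "ground_truth") <- list(
    duration_s = dur_s,
    braking_seconds = braking_samples / hz,
    braking_ratio = braking_samples / n,
    steering_seconds = turning_samples / hz,
    steering_ratio = turning_samples / n,
    sudden_events = as.integer(n_sudden_accel + n_sudden_steer),
    events_per_hour = (n_sudden_accel + n_sudden_steer) / (dur_s / 3600),
    flow = mean(pmin(speed / limit, 1)),
    mean_speed = mean(speed)
  )
  trace
}

#' Write / read a signal trace as long-format CSV
#'
#' Columns `second`, `channel`, `value`; channels `speed`,
#' `steering_angle`, `brake_engaged` (0/1), `speed_limit`.
#'
#' @param trace a [signal_trace()].
#' @param path file path.
#' @export
write_signal_trace <- function(trace, path) {
  n <- length(trace$speed)
  second <- (seq_len(n) - 1) / trace$hz
  long <- rbind(
    data.frame(second = second, channel = "speed", value = trace$speed),
    data.frame(second = second, channel = "steering_angle",
               value = trace$steering_angle),
    data.frame(second = second, channel = "brake_engaged",
               value = as.numeric(trace$brake_engaged)),
    data.frame(second = second, channel = "speed_limit",
               value = trace$speed_limit)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_trace
#' @export
read_signal_trace <- function(path) {
  long <- utils::read.csv(path)
  need <- c("second", "channel", "value")
  if (!all(need %in% names(long)))
    stop("signal CSV must have columns second, channel, value")
  get <- function(ch) {
    sub <- long[long$channel == ch, , drop = FALSE]
    sub$value[order(sub$second)]
  }
  sec <- sort(unique(long$second))
  hz <- if (length(sec) > 1) round(1 / min(diff(sec))) else 1
  signal_trace(get("speed"), get("steering_angle"),
               get("brake_engaged") > 0.5, get("speed_limit"),
               hz = max(1L, as.integer(hz)))
}
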