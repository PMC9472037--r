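flat_trace <- function(n = 3600, speed = 50, limit = 50) {
  signal_trace(rep(speed, n), rep(0, n), rep(FALSE, n), limit)
}

test_that("steering ratio covers the boundary and fixture cases", {
  expect_equal(steering_ratio(flat_trace(100)), 0)
  # angle changing every second above threshold (first diff is defined 0)
  tr <- signal_trace(rep(50, 100), cumsum(rep(5, 100)), rep(FALSE, 100), 50)
  expect_equal(steering_ratio(tr), 0.99)
  tr2 <- simulate_signals(list(duration = 3600, steering_seconds = 900,
                               n_steering_episodes = 3))
  expect_equal(steering_ratio(tr2), 0.25)
})

test_that("braking ratio covers the boundary and fixture cases", {
  expect_equal(braking_ratio(flat_trace(100)), 0)
  tr <- signal_trace(rep(30, 60), rep(0, 60), rep(TRUE, 60), 50)
  expect_equal(braking_ratio(tr), 1)
  tr2 <- simulate_signals(list(duration = 3600, braking_seconds = 360,
                               n_braking_episodes = 4))
  expect_equal(braking_ratio(tr2), 0.10)
})

test_that("sudden events: smooth trace counts zero, spikes count exactly", {
  expect_equal(count_sudden_events(flat_trace()), 0)
  tr <- simulate_signals(list(duration = 3600, n_sudden_accel = 3,
                              n_sudden_steer = 2))
  expect_equal(count_sudden_events(tr), 5)
})

test_that("peaks closer than the separation window merge into one event", {
  # a 2 Hz trace with an up-spike and a down-spike in steering rate half a
  # second apart (one single-sample pulse); after 1 Hz canonicalization
  # the two super-threshold peaks sit on adjacent seconds and a 2 s window
  # merges them into one event
  n <- 7200
  angle <- rep(0, n)
  angle[3000] <- 300
  tr <- signal_trace(rep(50, n), angle, rep(FALSE, n), 50, hz = 2L)
  expect_equal(count_sudden_events(tr), 1)

  # two such pulses 10 s apart stay two events
  angle2 <- angle
  angle2[3020] <- 300
  tr2 <- signal_trace(rep(50, n), angle2, rep(FALSE, n), 50, hz = 2L)
  expect_equal(count_sudden_events(tr2), 2)
})

test_that("flow averages the capped speed/limit ratio", {
  expect_equal(flow(flat_trace()), 1)
  expect_equal(flow(signal_trace(rep(0, 100), rep(0, 100),
                                 rep(FALSE, 100), 50)), 0)
  sp <- c(rep(50, 50), rep(0, 50))
  expect_equal(flow(signal_trace(sp, rep(0, 100), rep(FALSE, 100), 50)), 0.5)
  # speeding does not raise flow above 1
  expect_equal(flow(signal_trace(rep(80, 100), rep(0, 100),
                                 rep(FALSE, 100), 50)), 1)
  expect_error(flow(signal_trace(rep(10, 10), rep(0, 10),
                                 rep(FALSE, 10), 0)), "speed limit")
})

test_that("every extractor reproduces the generator's ground truth", {
  scenarios <- list(
    list(duration = 1800),
    list(duration = 3600, braking_seconds = 360, steering_seconds = 600,
         n_steering_episodes = 2, n_braking_episodes = 3),
    list(duration = 3600, n_sudden_accel = 5),
    list(duration = 3600, n_sudden_steer = 4, steering_seconds = 200,
         braking_seconds = 100),
    list(duration = 7200, base_speed = 30, speed_limit = 60,
         braking_seconds = 1000, n_braking_episodes = 5,
         n_sudden_accel = 2, n_sudden_steer = 2, steering_seconds = 400,
         n_steering_episodes = 4)
  )
  for (sc in scenarios) {
    tr <- simulate_signals(sc)
    gt <- attr(tr, "ground_truth")
    expect_equal(count_sudden_events(tr) * gt$duration_s / 3600,
                 gt$sudden_events)
    expect_equal(steering_ratio(tr), gt$steering_ratio, tolerance = 1e-9)
    expect_equal(braking_ratio(tr), gt$braking_ratio, tolerance = 1e-9)
    expect_equal(flow(tr), gt$flow, tolerance = 1e-9)
    expect_equal(mean_speed(tr), gt$mean_speed, tolerance = 1e-9)
    expect_equal(trip_length(tr), gt$duration_s)
  }
})

test_that("feature extraction is invariant to the CSV round trip", {
  tr <- simulate_signals(list(duration = 1200, braking_seconds = 120,
                              steering_seconds = 100, n_sudden_accel = 2))
  path <- tempfile(fileext = ".csv")
  write_signal_trace(tr, path)
  back <- read_signal_trace(path)
  expect_equal(extract_trip_features(back), extract_trip_features(tr))
})

test_that("scenario and trace validation errors fire", {
  expect_error(simulate_signals(list(duration = 0)), "duration")
  expect_error(signal_trace(1:5, 1:4, rep(FALSE, 5), 50), "length")
  expect_error(simulate_signals(list(duration = 10, braking_seconds = 3600)),
               "does not fit")
})
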