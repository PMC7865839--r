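test_that("low-pass filter has unit DC gain", {
  x <- rep(3.7, 400)
  expect_equal(lowpass_filter(x), x, tolerance = 1e-8)
})

test_that("bidirectional filter attenuation matches the transfer-function oracle", {
  t <- seq(0, 10, by = 1 / 200)
  # 50 Hz: squared magnitude response applied twice
  y50 <- lowpass_filter(sin(2 * pi * 50 * t))
  amp50 <- max(abs(y50[800:1200])) # steady-state region
  expect_equal(amp50, butter_gain_bidirectional(50), tolerance = 1e-4)
  expect_lt(amp50, 0.05)
  # 1 Hz passes essentially unchanged
  y1 <- lowpass_filter(sin(2 * pi * 1 * t))
  amp1 <- max(abs(y1[800:1200]))
  expect_equal(amp1, butter_gain_bidirectional(1), tolerance = 1e-4)
  expect_gt(amp1, 0.99)
})

test_that("too-short series are rejected", {
  expect_error(lowpass_filter(rnorm(5)), "too short")
})

test_that("a 256-sample recording with a centered speed sample yields one window", {
  rec <- tiny_recording(n_imu = 256)
  w <- extract_windows(rec)
  expect_equal(nrow(w$meta), 1)
  expect_equal(nrow(w$channels$poll$acc_x), 256)
})

test_that("admissible window centers follow the stated support rule", {
  # 10 s at 200 Hz (2000 samples), speed at 0, 0.2, ..., 9.8 (50 samples):
  # centers need full 256-sample support, so timestamps 0.8 .. 9.2 remain
  rec <- tiny_recording(n_imu = 2000, speed_t = seq(0, 9.8, by = 0.2))
  rec$speed$speed <- rep(2, 50)
  w <- extract_windows(rec)
  n_expected <- local({ # enumeration oracle, independent of the implementation
    centers <- round(seq(0, 9.8, by = 0.2) * 200) + 1
    sum(centers - 127 >= 1 & centers + 128 <= 2000)
  })
  expect_equal(n_expected, 43)
  expect_equal(nrow(w$meta), n_expected)
  expect_equal(w$meta$center_time[1], 0.8)
  expect_equal(max(w$meta$center_time), 9.2)
})

test_that("consecutive windows overlap by 216 samples", {
  rec <- tiny_recording(n_imu = 2000, speed_t = seq(0, 9.8, by = 0.2),
                        signal_fun = function(t) t) # ramp: sample index/200
  rec$speed$speed <- rep(2, 50)
  w <- extract_windows(rec)
  w1 <- w$channels$sacrum$acc_z[, 1]
  w2 <- w$channels$sacrum$acc_z[, 2]
  # 256 - 200/5 = 216 shared samples
  expect_equal(w1[41:256], w2[1:216])
})

test_that("windows crossing a gait boundary are dropped and labels are unambiguous", {
  gaits <- data.frame(start = c(0, 5), end = c(5, 10), gait = c("walk", "trot"))
  rec <- tiny_recording(n_imu = 2000, speed_t = seq(0, 9.8, by = 0.2),
                        gaits = gaits)
  rec$speed$speed <- rep(2, 50)
  w <- extract_windows(rec)
  # centers within 0.635 s of the 5 s boundary lose their window
  expect_false(any(w$meta$center_time > 5 - 0.64 & w$meta$center_time < 5 + 0.64))
  expect_setequal(unique(w$meta$gait), c("walk", "trot"))
  expect_true(all(w$meta$gait[w$meta$center_time < 5] == "walk"))
})

test_that("window count never exceeds speed-sample count; all lengths 256", {
  w <- small_windows()
  co <- small_cohort()
  expect_lte(nrow(w$meta), sum(vapply(co, function(r) nrow(r$speed), numeric(1))))
  for (loc in sensor_locations())
    for (ch in imu_channels())
      expect_equal(nrow(w$channels[[loc]][[ch]]), 256)
  expect_equal(ncol(w$channels$LH$gyr_z), nrow(w$meta))
})

test_that("filtering commutes with windowing (filter-then-window order)", {
  rec <- simulate_recording(schedule = data.frame(gait = "trot", duration = 8),
                            seed = 4)
  filtered <- preprocess_recording(rec)
  w <- extract_windows(filtered)
  # the window content is a verbatim slice of the filtered full series
  c1 <- round(w$meta$center_time[1] * 200) + 1
  expect_equal(w$channels$RF$gyr_z[, 1],
               filtered$imu$RF[(c1 - 127):(c1 + 128), "gyr_z"])
})

test_that("empty speed series is rejected", {
  rec <- tiny_recording(n_imu = 512, speed_t = 0.64)
  rec$speed <- rec$speed[0, ]
  expect_error(extract_windows(rec), "empty speed series")
})
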