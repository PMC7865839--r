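# Shared synthetic fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# Minimal hand-built recording: one location set, deterministic content.
tiny_recording <- function(n_imu = 256, speed_t = NULL, gaits = NULL,
                           signal_fun = function(t) sin(2 * pi * 2 * t)) {
  t_imu <- (seq_len(n_imu) - 1) / 200
  if (is.null(speed_t)) speed_t <- t_imu[n_imu / 2]
  total <- n_imu / 200
  if (is.null(gaits)) gaits <- data.frame(start = 0, end = total, gait = "walk")
  imu <- lapply(setNames(nm = sensor_locations()), function(loc) {
    m <- matrix(rep(signal_fun(t_imu), 6), ncol = 6)
    colnames(m) <- imu_channels()
    m
  })
  structure(list(
    subject_id = "T1", breed = "icelandic", imu = imu, t_imu = t_imu,
    speed = data.frame(t = speed_t, speed = rep(2, length(speed_t))),
    gait_segments = gaits, rate_imu = 200, rate_speed = 5,
    units = c(acc = "m/s^2", gyr = "deg/s", speed = "m/s"), seed = 0L
  ), class = "imu_recording")
}

# Small multi-gait cohort + pooled windows, shared across test files.
small_cohort <- function() memo("small_cohort", function() {
  simulate_cohort(4, schedule_template = default_schedule(10), seed = 101)
})

small_windows <- function() memo("small_windows", function() {
  cohort_windows(small_cohort())
})

# Feature matrix with a known planted signal for selection/model tests:
# speed is a noiseless or near-noiseless function of named columns.
planted_feature_matrix <- function(n = 200, n_subjects = 5, n_noise = 5,
                                   noise_sd = 0, seed = 1) {
  set.seed(seed)
  subject <- sprintf("P%d", rep_len(seq_len(n_subjects), n))
  signal <- runif(n, 1, 8)
  fm <- data.frame(
    window_id = sprintf("w%03d", seq_len(n)),
    subject_id = subject,
    breed = "icelandic",
    gait = "walk",
    speed = signal + rnorm(n, 0, noise_sd),
    sig = signal,
    check.names = FALSE
  )
  for (j in seq_len(n_noise)) fm[[paste0("noise", j)]] <- rnorm(n)
  class(fm) <- c("feature_matrix", "data.frame")
  attr(fm, "feature_set") <- "planted"
  fm
}
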