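#' Simulate one synthetic IMU + speed recording
#'
#' Generates a multi-gait recording for a single subject: tri-axial
#' accelerometer and gyroscope streams for the seven body locations at
#' 200 Hz, a ground-truth speed series at 5 Hz, and the gait segment
#' schedule. Within each segment the instantaneous speed follows a
#' mean-reverting (Ornstein-Uhlenbeck) process with the gait's configured
#' mean and SD, sampled at 5 Hz and held piecewise-constant at 200 Hz.
#' Each channel is a sum of the first three harmonics of the stride
#' frequency f(v) = a + b * v, with amplitudes scaled by (1 + c * v) so
#' that signal energy carries speed information, plus white Gaussian
#' sensor noise. Per-subject amplitude multipliers, phase offsets and a
#' stride-cadence offset are drawn once per subject.
#'
#' @param params Named list of [gait_params()] objects, one per gait used
#'   in `schedule` (default [default_gait_params()]).
#' @param schedule Data frame with columns `gait` and `duration` (s),
#'   played back in order; every duration must exceed 2 s.
#' @param subject_id Character scalar.
#' @param breed Character scalar (metadata only).
#' @param seed Integer seed; identical inputs give identical recordings.
#'
#' @return An object of class `imu_recording`: a list with elements
#'   `subject_id`, `breed`, `imu` (per location, an n x 6 matrix with
#'   columns `acc_x..gyr_z`), `t_imu` (s), `speed` (data frame `t`,
#'   `speed`), `gait_segments` (data frame `start`, `end`, `gait`),
#'   sampling rates and channel units.
#' @examples
#' rec <- simulate_recording(schedule = data.frame(gait = "walk", duration = 10),
#'                           subject_id = "h1", seed = 1)
#' str(rec$speed)
#' @export
simulate_recording <- function(params = default_gait_params(),
                               schedule,
                               subject_id = "subject1",
                               breed = "icelandic",
                               seed) {
  stopifnot(is.data.frame(schedule), all(c("gait", "duration") %in% names(schedule)))
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  schedule$gait <- as.character(schedule$gait)
  bad <- setdiff(schedule$gait, names(params))
  if (length(bad) > 0) stop("unknown gait label(s): ", paste(bad, collapse = ", "))
  if (any(schedule$duration <= 2)) stop("all segment durations must exceed 2 s")

  set.seed(seed)
  n_seg <- nrow(schedule)
  seg_end <- cumsum(schedule$duration)
  seg_start <- c(0, head(seg_end, -1))
  total <- seg_end[n_seg]

  n_speed <- floor(total * SPEED_RATE)
  t_speed <- (seq_len(n_speed) - 1) / SPEED_RATE
  n_imu <- n_speed * (IMU_RATE / SPEED_RATE)
  t_imu <- (seq_len(n_imu) - 1) / IMU_RATE

  # subject-level effects, drawn once (shared across gaits: same horse,
  # same sensors)
  p1 <- params[[1]]
  sdw <- array(rep(subject_sd_weights(), 3), dim = c(7, 6, 3))
  amp_mult <- array(exp(rnorm(7 * 6 * 3, 0, p1$subject_sd * sdw)),
                    dim = c(7, 6, 3),
                    dimnames = dimnames(p1$harmonic_amplitudes))
  phase_off <- array(runif(7 * 6 * 3, 0, 2 * pi), dim = c(7, 6, 3),
                     dimnames = dimnames(p1$harmonic_amplitudes))
  freq_off <- rnorm(1, 0, p1$subject_freq_sd)

  # speed process at 5 Hz, per segment
  seg_of_speed <- findInterval(t_speed, seg_start)
  v <- numeric(n_speed)
  for (s in seq_len(n_seg)) {
    gp <- params[[schedule$gait[s]]]
    idx <- which(seg_of_speed == s)
    v[idx] <- ou_process(length(idx), gp$speed_mean, gp$speed_sd,
                         theta = 0.8, dt = 1 / SPEED_RATE)
  }
  v <- pmax(v, 0.05)

  # piecewise-constant hold at 200 Hz
  hold <- IMU_RATE / SPEED_RATE
  v200 <- rep(v, each = hold)
  seg200 <- rep(seg_of_speed, each = hold)

  # instantaneous stride frequency and cumulative phase
  f200 <- numeric(n_imu)
  coupling200 <- matrix(0, n_imu, 7) # (1 + c_loc * v) per location
  for (s in seq_len(n_seg)) {
    gp <- params[[schedule$gait[s]]]
    idx <- seg200 == s
    f200[idx] <- (gp$stride_intercept + freq_off) + gp$stride_slope * v200[idx]
    for (l in seq_along(SENSOR_LOCATIONS)) {
      cl <- gp$speed_coupling[[SENSOR_LOCATIONS[l]]]
      coupling200[idx, l] <- 1 + cl * v200[idx]
    }
  }
  phase <- 2 * pi * cumsum(f200) / IMU_RATE

  imu <- vector("list", 7)
  names(imu) <- SENSOR_LOCATIONS
  for (l in seq_along(SENSOR_LOCATIONS)) {
    loc <- SENSOR_LOCATIONS[l]
    m <- matrix(0, n_imu, 6, dimnames = list(NULL, CHANNELS))
    for (ch in seq_along(CHANNELS)) {
      kind <- if (grepl("^acc", CHANNELS[ch])) "acc" else "gyr"
      x <- numeric(n_imu)
      for (s in seq_len(n_seg)) {
        gp <- params[[schedule$gait[s]]]
        idx <- seg200 == s
        for (h in 1:3) {
          a <- gp$harmonic_amplitudes[loc, CHANNELS[ch], h] * amp_mult[loc, ch, h]
          if (a > 0) {
            x[idx] <- x[idx] + a * coupling200[idx, l] *
              sin(h * phase[idx] + phase_off[loc, ch, h])
          }
        }
        nsd <- gp$noise_sd[[kind]]
        if (nsd > 0) x[idx] <- x[idx] + rnorm(sum(idx), 0, nsd)
      }
      # slow non-locomotor motion (head wander on the poll by default):
      # smooth disturbance in the gait band, unrelated to speed
      wmult <- p1$wander_sd[[loc]]
      if (wmult > 0) {
        wbase <- if (kind == "acc") 2.5 else 12
        x <- x + ou_process(n_imu, 0, wmult * wbase,
                            theta = 1 / 0.3, dt = 1 / IMU_RATE)
      }
      m[, ch] <- x
    }
    imu[[loc]] <- m
  }

  structure(list(
    subject_id = as.character(subject_id),
    breed = as.character(breed),
    imu = imu,
    t_imu = t_imu,
    speed = data.frame(t = t_speed, speed = v),
    gait_segments = data.frame(start = seg_start, end = seg_end,
                               gait = schedule$gait,
                               stringsAsFactors = FALSE),
    rate_imu = IMU_RATE,
    rate_speed = SPEED_RATE,
    units = c(acc = "m/s^2", gyr = "deg/s", speed = "m/s"),
    seed = seed
  ), class = "imu_recording")
}

# Stationary Ornstein-Uhlenbeck sample path: mean mu, stationary SD
# sigma, mean-reversion rate theta (1/s), step dt (s).
ou_process <- function(n, mu, sigma, theta, dt) {
  a <- exp(-theta * dt)
  z0 <- rnorm(1, 0, sigma)
  if (n == 1) return(mu + z0)
  eps <- rnorm(n - 1, 0, sigma * sqrt(1 - a^2))
  z <- stats::filter(eps, a, method = "recursive", init = z0)
  mu + c(z0, as.numeric(z))
}

#' Validate the structural invariants of a recording
#'
#' Checks channel lengths, timestamp monotonicity, non-negative speed,
#' non-overlapping gait segments and the 40:1 IMU-to-speed rate ratio.
#'
#' @param rec An `imu_recording`.
#' @return `rec`, invisibly; stops on violation.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- length(rec$t_imu)
  for (loc in names(rec$imu)) {
    if (nrow(rec$imu[[loc]]) != n)
      stop("channel length mismatch at ", loc)
    if (!identical(colnames(rec$imu[[loc]]), CHANNELS))
      stop("channel columns malformed at ", loc)
  }
  if (any(diff(rec$t_imu) <= 0) || any(diff(rec$speed$t) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(rec$speed$speed < 0)) stop("speed must be non-negative")
  gs <- rec$gait_segments
  if (nrow(gs) > 1 && any(gs$start[-1] < gs$end[-nrow(gs)]))
    stop("gait segments overlap")
  if (rec$rate_imu != 40 * rec$rate_speed)
    stop("IMU rate must be 40x the speed rate")
  invisible(rec)
}

#' Simulate a cohort of subjects
#'
#' Draws one recording per subject with per-subject seeds derived
#' deterministically from the master seed, so the whole cohort is
#' reproducible. Breeds are assigned by `breed_mix` (counts summing to
#' `n_subjects`, or proportions).
#'
#' @param n_subjects Number of subjects (at least 2; leave-one-subject-out
#'   CV is undefined below that).
#' @param breed_mix Named numeric vector of breed counts or proportions.
#' @param schedule_template Data frame `gait`, `duration` applied to every
#'   subject.
#' @param seed Master integer seed.
#' @inheritParams simulate_recording
#' @return A list of `imu_recording` objects with distinct subject ids.
#' @export
simulate_cohort <- function(n_subjects,
                            breed_mix = c(icelandic = 15, fm = 25),
                            schedule_template = default_schedule(),
                            params = default_gait_params(),
                            seed) {
  if (missing(seed)) stop("a master seed is required")
  if (n_subjects < 2) stop("n_subjects must be at least 2 (LOSO needs >= 2 subjects)")
  stopifnot(length(breed_mix) >= 1, all(breed_mix >= 0), sum(breed_mix) > 0)

  if (sum(breed_mix) == n_subjects && all(breed_mix == round(breed_mix))) {
    counts <- breed_mix
  } else {
    prop <- breed_mix / sum(breed_mix)
    counts <- diff(c(0, round(cumsum(prop) * n_subjects)))
    names(counts) <- names(breed_mix)
  }
  breeds <- rep(names(counts), counts)

  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    simulate_recording(params = params,
                       schedule = schedule_template,
                       subject_id = sprintf("S%02d", i),
                       breed = breeds[i],
                       seed = subject_seeds[i])
  })
}

#' @rdname simulate_cohort
#' @param duration Per-gait segment duration (s) of the default schedule,
#'   which plays the five gaits in sequence.
#' @export
default_schedule <- function(duration = 24) {
  data.frame(gait = GAITS, duration = duration, stringsAsFactors = FALSE)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s (%s): %.1f s, %d IMU samples x 7 locations, %d speed samples\n",
              x$subject_id, x$breed, max(x$t_imu) + 1 / x$rate_imu,
              length(x$t_imu), nrow(x$speed)))
  cat("  gaits:", paste(sprintf("%s (%.0fs)", x$gait_segments$gait,
                                x$gait_segments$end - x$gait_segments$start),
                        collapse = ", "), "\n")
  invisible(x)
}
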