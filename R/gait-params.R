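#' Per-gait simulation parameters
#'
#' Builds the parameter block controlling synthetic signal generation for
#' one gait: the target speed distribution, the linear stride-frequency
#' law f(v) = a + b * v (Hz), harmonic amplitudes of the first three
#' stride harmonics for every location x channel, sensor noise, and
#' between-subject variability.
#'
#' Default speed means and SDs follow the per-gait speed distributions of
#' the study cohort (walk 1.70 +/- 0.17, trot 3.30 +/- 0.23,
#' tolt 3.90 +/- 0.23, canter 4.95 +/- 0.43, pace 7.52 +/- 1.43 m/s).
#' Stride-frequency coefficients are simulator defaults chosen so that f
#' spans roughly 0.85-2.1 Hz across those speed ranges, increasing with
#' speed within every gait.
#'
#' @param gait One of `gait_levels()`.
#' @param speed_mean,speed_sd Mean and SD of the within-gait speed
#'   process (m/s).
#' @param stride_intercept,stride_slope Coefficients of the
#'   stride-frequency law (Hz, Hz per m/s); the slope must be positive.
#' @param amp_scale Global multiplier applied to the default harmonic
#'   amplitude table.
#' @param noise_sd Named vector, additive Gaussian noise SD for
#'   accelerometer (m/s^2) and gyroscope (deg/s) channels.
#' @param subject_sd SD of the per-subject log-normal amplitude
#'   multipliers (unitless). The effective SD per channel is
#'   `subject_sd` scaled by `subject_sd_weights()`: limb gyr_z (0.3) and
#'   upper-body acc_z (0.6) vary least between horses, because swing
#'   amplitude and vertical displacement are constrained by the gait
#'   mechanics themselves, while the remaining axes reflect looser
#'   individual habitus.
#' @param speed_coupling Named vector (per location) of the coupling
#'   coefficient c in the amplitude term (1 + c * v); the poll is given a
#'   deliberately weak coupling so head-mounted signals carry the least
#'   speed information beyond stride frequency.
#' @param subject_freq_sd SD (Hz) of the per-subject offset added to the
#'   stride-frequency intercept, emulating between-horse differences in
#'   cadence at a given speed.
#' @param wander_sd Named vector (per location) scaling a slow,
#'   non-locomotor motion component (smooth mean-reverting disturbance,
#'   ~0.3 s correlation time, base SD 2.5 m/s^2 / 12 deg/s). By default
#'   only the poll carries it: voluntary head movements overlap the gait
#'   band and are unrelated to speed, which is what makes head-mounted
#'   sensors the least informative placement.
#'
#' @return An object of class `gait_params` (a list).
#' @export
gait_params <- function(gait,
                        speed_mean,
                        speed_sd,
                        stride_intercept,
                        stride_slope,
                        amp_scale = 1,
                        noise_sd = c(acc = 0.5, gyr = 8),
                        subject_sd = 0.15,
                        speed_coupling = default_speed_coupling(),
                        subject_freq_sd = 0.05,
                        wander_sd = default_wander_sd()) {
  gait <- match.arg(gait, GAITS)
  stopifnot(speed_sd > 0, stride_slope > 0, speed_mean > 0, amp_scale >= 0)
  amps <- default_harmonic_amplitudes() * amp_scale
  stopifnot(all(amps >= 0))
  structure(list(
    gait = gait,
    speed_mean = speed_mean,
    speed_sd = speed_sd,
    stride_intercept = stride_intercept,
    stride_slope = stride_slope,
    harmonic_amplitudes = amps,
    noise_sd = noise_sd,
    subject_sd = subject_sd,
    speed_coupling = speed_coupling,
    subject_freq_sd = subject_freq_sd,
    wander_sd = wander_sd
  ), class = "gait_params")
}

#' @rdname gait_params
#' @details `default_gait_params()` returns the full named list of
#'   defaults for the five gaits, the configuration under which all
#'   package-level properties are asserted.
#' @export
default_gait_params <- function() {
  list(
    walk   = gait_params("walk",   1.70, 0.17, 0.50, 0.25, amp_scale = 0.7),
    trot   = gait_params("trot",   3.30, 0.23, 0.80, 0.18, amp_scale = 1.2),
    tolt   = gait_params("tolt",   3.90, 0.23, 0.90, 0.18, amp_scale = 1.0),
    pace   = gait_params("pace",   7.52, 1.43, 1.10, 0.13, amp_scale = 1.1),
    canter = gait_params("canter", 4.95, 0.43, 1.00, 0.16, amp_scale = 1.3)
  )
}

# Base amplitude of the stride fundamental per location x channel.
# Limb gyr_z dominates (reciprocating limb rotation); upper-body acc_z
# dominates among upper-body channels (vertical displacement); the poll
# is weakest overall. Accelerometer rows in m/s^2, gyroscope in deg/s.
default_harmonic_amplitudes <- function() {
  base <- rbind(
    poll    = c(acc_x = 1.2, acc_y = 0.8, acc_z = 2.2, gyr_x = 6,  gyr_y = 8,  gyr_z = 5),
    withers = c(          3.0,          1.8,          6.0,        12,         16,         10),
    sacrum  = c(          3.5,          2.0,          7.0,        14,         18,         12),
    RF      = c(          9.0,          4.0,          6.0,        30,         45,        120),
    LF      = c(          9.0,          4.0,          6.0,        30,         45,        120),
    RH      = c(          8.0,          3.5,          5.5,        28,         40,        110),
    LH      = c(          8.0,          3.5,          5.5,        28,         40,        110)
  )
  colnames(base) <- CHANNELS
  decay <- c(1, 0.4, 0.18) # harmonics 1..3
  out <- array(0, dim = c(nrow(base), ncol(base), 3),
               dimnames = list(SENSOR_LOCATIONS, CHANNELS, paste0("h", 1:3)))
  for (h in 1:3) out[, , h] <- base * decay[h]
  out
}

# per-channel scaling of the between-subject amplitude SD
subject_sd_weights <- function() {
  w <- matrix(1, 7, 6, dimnames = list(SENSOR_LOCATIONS, CHANNELS))
  w[LIMB_LOCATIONS, "gyr_z"] <- 0.3
  w[UPPER_LOCATIONS, "acc_z"] <- 0.6
  w
}

default_wander_sd <- function() {
  c(poll = 1, withers = 0, sacrum = 0, RF = 0, LF = 0, RH = 0, LH = 0)
}

default_speed_coupling <- function() {
  c(poll = 0.03, withers = 0.15, sacrum = 0.15,
    RF = 0.15, LF = 0.15, RH = 0.15, LH = 0.15)
}

#' @export
print.gait_params <- function(x, ...) {
  cat(sprintf("<gait_params: %s>  speed %.2f (+/- %.2f) m/s,  f(v) = %.2f + %.2f v Hz\n",
              x$gait, x$speed_mean, x$speed_sd,
              x$stride_intercept, x$stride_slope))
  invisible(x)
}
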