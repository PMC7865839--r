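#' Detect hoof-on events from a limb gyroscope channel
#'
#' A transparent peak detector standing in for dedicated gait-event
#' methods: the z-axis angular velocity of a limb is band-pass filtered
#' (2nd-order Butterworth, 0.5-8 Hz), and local maxima above an adaptive
#' threshold — a fraction of the rolling signal maximum over a 2 s
#' window — are taken as hoof-on events, with a 0.25 s refractory period
#' between events.
#'
#' @param gyr_z Numeric series (deg/s) at `rate` Hz; at least 2 s.
#' @param rate Sampling rate, Hz.
#' @param thresh_frac Threshold as a fraction of the rolling maximum.
#' @param refractory Minimum inter-event separation, s.
#' @param band Band-pass edges, Hz.
#' @param min_amplitude Absolute peak floor (same units as the input,
#'   deg/s for a gyroscope). Limb swing produces angular velocities far
#'   above sensor noise at every gait, so peaks below this floor are
#'   noise, not strides.
#' @return Numeric vector of event times (s); empty (with a warning) when
#'   nothing crosses the threshold.
#' @export
detect_hoof_on <- function(gyr_z, rate = IMU_RATE, thresh_frac = 0.6,
                           refractory = 0.25, band = c(0.5, 8),
                           min_amplitude = 20) {
  if (length(gyr_z) < 2 * rate) stop("need at least 2 s of signal")
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  x <- filtfilt_padded(bf, gyr_z, pad = 30)

  # adaptive threshold on the positive envelope: harmonic mixtures can
  # have asymmetric lobes, so the signed rolling maximum is used
  roll <- ceiling(2 * rate)
  amp <- zoo::rollapply(zoo::zoo(x), width = roll,
                        FUN = max, fill = NA, partial = TRUE, align = "center")
  thresh <- pmax(thresh_frac * pmax(as.numeric(amp), 0), min_amplitude)

  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                      x[2:(n - 1)] >= x[3:n], FALSE)
  cand <- which(is_peak & x > thresh & x > 0)
  if (length(cand) == 0) {
    warning("no hoof-on events detected")
    return(numeric(0))
  }
  gap <- refractory * rate
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= gap) keep <- c(keep, i)
  }
  (keep - 1) / rate
}

#' Stride frequency paired with speed
#'
#' Computes stride frequency as the reciprocal of the interval between
#' consecutive hoof-on events of the right front limb, and pairs every
#' stride with the speed sample nearest its midpoint.
#'
#' @param rec An `imu_recording`.
#' @param limb Limb whose gyroscope is used (default right front).
#' @param ... Passed to [detect_hoof_on()].
#' @return A data frame (class `stride_series`) with columns `t` (stride
#'   midpoint, s), `stride_frequency` (Hz), `speed` (m/s), `gait`, and
#'   `subject_id`.
#' @export
stride_series <- function(rec, limb = "RF", ...) {
  validate_recording(rec)
  events <- detect_hoof_on(rec$imu[[limb]][, "gyr_z"], rate = rec$rate_imu, ...)
  if (length(events) < 2)
    return(structure(data.frame(t = numeric(0), stride_frequency = numeric(0),
                                speed = numeric(0), gait = character(0),
                                subject_id = character(0)),
                     class = c("stride_series", "data.frame")))
  iv <- diff(events)
  mid <- head(events, -1) + iv / 2
  freq <- 1 / iv
  nearest <- vapply(mid, function(m) which.min(abs(rec$speed$t - m)), integer(1))
  gs <- rec$gait_segments
  seg <- findInterval(mid, gs$start)
  # drop strides spanning a gait boundary
  same_seg <- findInterval(head(events, -1), gs$start) ==
    findInterval(events[-1] - 1e-9, gs$start)
  out <- data.frame(t = mid, stride_frequency = freq,
                    speed = rec$speed$speed[nearest],
                    gait = gs$gait[pmin(pmax(seg, 1), nrow(gs))],
                    subject_id = rec$subject_id,
                    stringsAsFactors = FALSE)[same_seg, ]
  rownames(out) <- NULL
  class(out) <- c("stride_series", "data.frame")
  out
}

#' Polynomial speed model on stride frequency
#'
#' Least-squares fit of speed = P(stride frequency) with a 2nd- or
#' 3rd-degree polynomial; MAE, RMSE and R^2 are computed in-sample on the
#' fitted points.
#'
#' @param strides A `stride_series` (or any data frame with
#'   `stride_frequency` and `speed`), typically pooled over a cohort.
#' @param degree Polynomial degree, 2 or 3.
#' @return A `poly_fit` list: `degree`, `coefficients` (ascending
#'   powers), `mae`, `rmse`, `r_squared`, `n`, and `fitted`.
#' @export
fit_poly_speed <- function(strides, degree = 2) {
  stopifnot(degree %in% c(2, 3))
  f <- strides$stride_frequency
  v <- strides$speed
  if (length(f) < degree + 1) stop("need at least degree + 1 points")
  if (sd(f) == 0) stop("degenerate design: constant stride frequency")
  fit <- lm(v ~ poly(f, degree, raw = TRUE))
  pred <- unname(fitted(fit))
  ss_res <- sum((v - pred)^2)
  ss_tot <- sum((v - mean(v))^2)
  structure(list(
    degree = degree,
    coefficients = unname(coef(fit)),
    mae = mae(pred, v),
    rmse = rmse(pred, v),
    r_squared = 1 - ss_res / ss_tot,
    n = length(v),
    fitted = pred
  ), class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("<poly_fit degree %d> MAE %.3f, RMSE %.3f m/s, R^2 %.3f (n = %d)\n",
              x$degree, x$mae, x$rmse, x$r_squared, x$n))
  invisible(x)
}

#' Stride-frequency baseline over a cohort
#'
#' Pools the stride series of every recording and fits the polynomial
#' speed model — the simple baseline the ML pipeline is compared against.
#'
#' @param cohort List of `imu_recording`s.
#' @inheritParams fit_poly_speed
#' @inheritParams stride_series
#' @return List with `strides` (pooled `stride_series`) and `fit`
#'   (a `poly_fit`).
#' @export
stride_baseline <- function(cohort, degree = 2, limb = "RF", ...) {
  strides <- do.call(rbind, lapply(cohort, stride_series, limb = limb, ...))
  class(strides) <- c("stride_series", "data.frame")
  list(strides = strides, fit = fit_poly_speed(strides, degree = degree))
}
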