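#' Zero-phase low-pass filtering of an IMU channel
#'
#' Applies a fourth-order Butterworth low-pass filter with a 30 Hz cutoff
#' (at the 200 Hz IMU rate) forward and backward, so the output has zero
#' phase shift and window centers stay aligned with speed timestamps.
#'
#' @param x Numeric series sampled at `rate` Hz.
#' @param cutoff Cutoff frequency, Hz (must be below the Nyquist rate).
#' @param order Filter order.
#' @param rate Sampling rate, Hz.
#' @return Filtered series of the same length.
#' @export
lowpass_filter <- function(x, cutoff = 30, order = 4, rate = IMU_RATE) {
  stopifnot(cutoff > 0, cutoff < rate / 2, order >= 1)
  if (length(x) < 3 * (order + 1))
    stop("series too short for the filter's edge padding (need >= ",
         3 * (order + 1), " samples)")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  filtfilt_padded(bf, x, pad = 15 * order)
}

# forward-backward filtering with reflected end padding, so constants and
# slow components pass the edges without transients
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  as.numeric(signal::filtfilt(bf, xp))[(pad + 1):(pad + n)]
}

#' Filter every channel of a recording
#'
#' Runs [lowpass_filter()] over all 42 channel streams of a recording.
#' Filtering precedes windowing, so overlapping windows see a single
#' consistently filtered series.
#'
#' @param rec An `imu_recording`.
#' @inheritParams lowpass_filter
#' @return The recording with filtered channels (flagged via the
#'   `filtered` element).
#' @export
preprocess_recording <- function(rec, cutoff = 30, order = 4) {
  validate_recording(rec)
  for (loc in names(rec$imu)) {
    for (ch in CHANNELS) {
      rec$imu[[loc]][, ch] <- lowpass_filter(rec$imu[[loc]][, ch],
                                             cutoff = cutoff, order = order,
                                             rate = rec$rate_imu)
    }
  }
  rec$filtered <- TRUE
  rec
}

#' Cut speed-synchronized windows from a recording
#'
#' One 256-sample window is cut per speed sample: the window center is
#' the IMU sample nearest the speed timestamp and the window spans
#' samples center-127 .. center+128. Windows without full support inside
#' the recording, or crossing a gait-segment boundary, are dropped.
#' Consecutive admissible centers are 40 IMU samples apart (200/5 Hz), so
#' neighbouring windows share 216 samples.
#'
#' @param rec An `imu_recording` (normally already passed through
#'   [preprocess_recording()]).
#' @param n Window length in samples (default 256).
#' @return An object of class `speed_windows`: a list with
#'   * `meta` — data frame `window_id`, `subject_id`, `breed`, `gait`,
#'     `speed` (the target speed at the window center, m/s),
#'     `center_time` (s);
#'   * `channels` — for each location, for each channel, an `n` x W
#'     matrix whose columns are windows (column order = `meta` rows);
#'   * `n`, `rate`.
#' @export
extract_windows <- function(rec, n = 256) {
  validate_recording(rec)
  stopifnot(n %% 2 == 0, n >= 2)
  if (nrow(rec$speed) == 0) stop("empty speed series")

  n_imu <- length(rec$t_imu)
  left <- n / 2 - 1   # samples before the center
  right <- n / 2      # samples after the center

  # nearest IMU sample to each speed timestamp
  centers <- round(rec$speed$t * rec$rate_imu) + 1
  centers <- pmin(pmax(centers, 1), n_imu)

  ok <- (centers - left >= 1) & (centers + right <= n_imu)

  # gait label at the center; drop windows straddling a segment boundary
  gs <- rec$gait_segments
  seg_idx <- findInterval(rec$speed$t, gs$start)
  seg_idx[seg_idx < 1 | rec$speed$t >= gs$end[nrow(gs)] + 1e-9] <- NA
  t_lo <- (centers - left - 1) / rec$rate_imu
  t_hi <- (centers + right - 1) / rec$rate_imu
  inside <- !is.na(seg_idx) &
    t_lo >= gs$start[pmax(seg_idx, 1)] - 1e-9 &
    t_hi <= gs$end[pmax(seg_idx, 1)] + 1e-9
  keep <- which(ok & inside)
  if (length(keep) == 0) {
    warning("no admissible windows")
  }

  idx_mat <- outer(seq(-left, right), centers[keep], "+") # n x W index matrix
  channels <- lapply(rec$imu, function(m) {
    out <- lapply(CHANNELS, function(ch) {
      w <- matrix(m[idx_mat, ch], nrow = n)
      w
    })
    names(out) <- CHANNELS
    out
  })

  meta <- data.frame(
    window_id = sprintf("%s_w%04d", rec$subject_id, seq_along(keep)),
    subject_id = rec$subject_id,
    breed = rec$breed,
    gait = gs$gait[seg_idx[keep]],
    speed = rec$speed$speed[keep],
    center_time = rec$speed$t[keep],
    stringsAsFactors = FALSE
  )
  structure(list(meta = meta, channels = channels, n = n, rate = rec$rate_imu),
            class = "speed_windows")
}

#' Windows from every recording of a cohort
#'
#' Filters each recording and concatenates its windows.
#'
#' @param cohort List of `imu_recording` objects.
#' @param filter Apply [preprocess_recording()] first (default TRUE).
#' @inheritParams extract_windows
#' @return A single `speed_windows` object pooling all subjects.
#' @export
cohort_windows <- function(cohort, n = 256, filter = TRUE) {
  ws <- lapply(cohort, function(rec) {
    if (filter) rec <- preprocess_recording(rec)
    extract_windows(rec, n = n)
  })
  bind_windows(ws)
}

bind_windows <- function(ws) {
  stopifnot(length(ws) >= 1)
  meta <- do.call(rbind, lapply(ws, `[[`, "meta"))
  rownames(meta) <- NULL
  channels <- lapply(SENSOR_LOCATIONS, function(loc) {
    out <- lapply(CHANNELS, function(ch) {
      do.call(cbind, lapply(ws, function(w) w$channels[[loc]][[ch]]))
    })
    names(out) <- CHANNELS
    out
  })
  names(channels) <- SENSOR_LOCATIONS
  structure(list(meta = meta, channels = channels, n = ws[[1]]$n,
                 rate = ws[[1]]$rate),
            class = "speed_windows")
}

#' @export
print.speed_windows <- function(x, ...) {
  cat(sprintf("<speed_windows> %d windows of %d samples, %d subject(s), gaits: %s\n",
              nrow(x$meta), x$n, length(unique(x$meta$subject_id)),
              paste(unique(x$meta$gait), collapse = ", ")))
  invisible(x)
}
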