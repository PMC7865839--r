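#' Time-domain features of one window
#'
#' Nine descriptive statistics of the (filtered, unwindowed) samples:
#' maximum, minimum, mean, median, standard deviation (1/(N-1)
#' normalisation), first and third quartiles (linear interpolation
#' between order statistics), kurtosis and skewness. Kurtosis and
#' skewness use the 1/N moment estimators standardised by the (N-1) SD,
#' and kurtosis is raw (a Gaussian tends to 3), not excess.
#'
#' @param x Numeric window (any length for unit analysis; the pipeline
#'   uses 256).
#' @return Named numeric vector of length 9:
#'   `max, min, mean, mdn, sd, p25, p75, krt, skw`. For a zero-variance
#'   window, `krt` and `skw` are 0 and the result carries
#'   `attr(, "degenerate") = TRUE`.
#' @export
time_features <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  m <- mean(x)
  s <- sd(x)
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  degenerate <- (s == 0)
  if (degenerate) {
    krt <- 0
    skw <- 0
  } else {
    z <- (x - m) / s
    krt <- mean(z^4)
    skw <- mean(z^3)
  }
  out <- c(max = max(x), min = min(x), mean = m, mdn = q[2], sd = s,
           p25 = q[1], p75 = q[3], krt = krt, skw = skw)
  attr(out, "degenerate") <- degenerate
  out
}

# symmetric Hann window of length n
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Frequency-domain features of one window
#'
#' A Hann window is applied first (to reduce spectral leakage), then the
#' DFT X_k = sum_n x_n exp(-j 2 pi k n / N). The 14 features are:
#' * spectral entropy `ent`: -sum p_i ln p_i over the normalised power
#'   spectral distribution of the one-sided non-redundant bins
#'   (k = 0..N/2);
#' * spectral energy `enrg`: sum over all k of |X_k|^2;
#' * `fft1..fft6`: |X_k| for k = 1..6 (DC excluded);
#' * `ang1..ang6`: two-argument arctangent of
#'   (sum x_n sin(2 pi k n / N), sum x_n cos(2 pi k n / N)) for k = 1..6,
#'   computed on the Hann-windowed samples.
#'
#' @inheritParams time_features
#' @return Named numeric vector of length 14. An all-zero windowed signal
#'   has undefined entropy; it is set to 0 and the result carries
#'   `attr(, "degenerate") = TRUE`.
#' @export
freq_features <- function(x) {
  n <- length(x)
  stopifnot(n >= 16)
  w <- hann_window(n) * x
  X <- fft(w)
  P <- Mod(X)^2
  enrg <- sum(P)
  one_sided <- P[1:(n / 2 + 1)]
  degenerate <- (enrg == 0)
  if (degenerate) {
    ent <- 0
  } else {
    p <- one_sided / sum(one_sided)
    nz <- p > 0
    ent <- -sum(p[nz] * log(p[nz]))
  }
  k <- 2:7 # bins 1..6
  fftk <- Mod(X[k])
  # X_k = sum x cos - j sum x sin  =>  sum x sin = -Im, sum x cos = Re
  angk <- atan2(-Im(X[k]), Re(X[k]))
  out <- c(ent = ent, enrg = enrg,
           setNames(fftk, paste0("fft", 1:6)),
           setNames(angk, paste0("ang", 1:6)))
  attr(out, "degenerate") <- degenerate
  out
}

FEATURE_NAMES <- c("max", "min", "mean", "mdn", "sd", "p25", "p75", "krt",
                   "skw", "ent", "enrg", paste0("fft", 1:6), paste0("ang", 1:6))

#' The 23 feature names
#' @return Character vector of the 23 per-channel feature names, time
#'   domain first.
#' @export
feature_names <- function() FEATURE_NAMES

# channel tag used in column names: acc_x -> accx etc.
channel_tag <- function(ch) sub("_", "", ch)

#' All 23 features for every window of one channel
#'
#' Vectorised over windows: `m` holds one window per column.
#'
#' @param m Numeric matrix, N x W (windows in columns).
#' @return W x 23 matrix, columns named per [feature_names()], plus a
#'   `degenerate` attribute (logical length W).
#' @keywords internal
channel_features <- function(m) {
  n <- nrow(m)
  w <- ncol(m)
  mu <- colMeans(m)
  cm <- m - rep(mu, each = n)
  ss <- colSums(cm^2)
  sdev <- sqrt(ss / (n - 1))
  qs <- apply(m, 2, quantile, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  zero_var <- sdev == 0
  krt <- ifelse(zero_var, 0, colMeans(cm^4) / sdev^4)
  skw <- ifelse(zero_var, 0, colMeans(cm^3) / sdev^3)

  hw <- hann_window(n)
  Xw <- mvfft(m * hw)
  P <- Mod(Xw)^2
  enrg <- colSums(P)
  P1 <- P[1:(n / 2 + 1), , drop = FALSE]
  tot1 <- colSums(P1)
  zero_sig <- enrg == 0
  p <- sweep(P1, 2, ifelse(zero_sig, 1, tot1), "/")
  plogp <- p * log(p)
  plogp[!is.finite(plogp)] <- 0
  ent <- -colSums(plogp)
  ent[zero_sig] <- 0

  fftk <- t(Mod(Xw[2:7, , drop = FALSE]))
  angk <- t(atan2(-Im(Xw[2:7, , drop = FALSE]), Re(Xw[2:7, , drop = FALSE])))

  out <- cbind(apply(m, 2, max), apply(m, 2, min), mu, qs[2, ], sdev,
               qs[1, ], qs[3, ], krt, skw, ent, enrg, fftk, angk)
  colnames(out) <- FEATURE_NAMES
  rownames(out) <- NULL
  attr(out, "degenerate") <- zero_var | zero_sig
  out
}

#' The 11 feature-set definitions
#'
#' Feature sets name which IMU locations contribute features: `All`
#' (seven locations), `Limbs` (the four limb IMUs), `Sac/Wth`
#' (sacrum + withers), `Sac/RF` (sacrum + right front limb), and the
#' seven single-location sets.
#'
#' @return Named list mapping feature-set name to its location vector.
#' @export
feature_set_defs <- function() {
  list(
    "All" = SENSOR_LOCATIONS,
    "Limbs" = LIMB_LOCATIONS,
    "Sac/Wth" = c("sacrum", "withers"),
    "Sac/RF" = c("sacrum", "RF"),
    "Sacrum" = "sacrum",
    "Withers" = "withers",
    "Poll" = "poll",
    "RF" = "RF",
    "LF" = "LF",
    "RH" = "RH",
    "LH" = "LH"
  )
}

#' Build the feature matrix for a feature set
#'
#' Computes the 23 features for all 6 channels of every location in the
#' set, over every window: 138 columns per location (e.g. 966 for `All`,
#' 552 for `Limbs`). Columns are named `<feature>_<channel>(<location>)`,
#' e.g. `max_gyrz(LH)`. Metadata columns (`window_id`, `subject_id`,
#' `breed`, `gait`, `speed`) come first.
#'
#' @param windows A `speed_windows` object.
#' @param feature_set A feature-set name from [feature_set_defs()], or a
#'   character vector of locations.
#' @return A data frame (class `feature_matrix`): one row per window.
#'   Windows with a degenerate channel (zero variance or all-zero
#'   spectrum) are flagged in the logical `degenerate` attribute.
#' @export
build_feature_matrix <- function(windows, feature_set = "All") {
  stopifnot(inherits(windows, "speed_windows"))
  if (nrow(windows$meta) == 0) stop("no windows to featurise")
  if (length(feature_set) == 1 && feature_set %in% names(feature_set_defs())) {
    locations <- feature_set_defs()[[feature_set]]
    set_name <- feature_set
  } else {
    locations <- as.character(feature_set)
    set_name <- paste(locations, collapse = "+")
  }
  missing_loc <- setdiff(locations, names(windows$channels))
  if (length(missing_loc) > 0)
    stop("missing location stream(s): ", paste(missing_loc, collapse = ", "))

  nw <- nrow(windows$meta)
  degenerate <- rep(FALSE, nw)
  blocks <- list()
  for (loc in locations) {
    for (ch in CHANNELS) {
      f <- channel_features(windows$channels[[loc]][[ch]])
      degenerate <- degenerate | attr(f, "degenerate")
      colnames(f) <- sprintf("%s_%s(%s)", FEATURE_NAMES, channel_tag(ch), loc)
      blocks[[paste(loc, ch)]] <- f
    }
  }
  out <- cbind(windows$meta[c("window_id", "subject_id", "breed", "gait", "speed")],
               as.data.frame(do.call(cbind, blocks), check.names = FALSE))
  attr(out, "feature_set") <- set_name
  attr(out, "degenerate") <- degenerate
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Names of the feature columns of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Character vector (metadata columns excluded).
#' @export
feature_columns <- function(fm) {
  setdiff(names(fm), c("window_id", "subject_id", "breed", "gait", "speed"))
}
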