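# Independent oracles used across tests.

# Brute-force O(N^2) DFT: X_k = sum_n x_n exp(-j 2 pi k n / N)
dft_oracle <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    th <- 2 * pi * k * (0:(n - 1)) / n
    complex(real = sum(x * cos(th)), imaginary = -sum(x * sin(th)))
  }, complex(1))
}

# The 14 frequency features computed directly from the brute-force DFT
# of the Hann-windowed samples.
freq_features_oracle <- function(x) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))) * x
  X <- dft_oracle(w)
  P <- Mod(X)^2
  one_sided <- P[1:(n / 2 + 1)]
  p <- one_sided / sum(one_sided)
  nz <- p > 0
  ent <- -sum(p[nz] * log(p[nz]))
  # ang_k = atan2(sum x sin, sum x cos), computed from raw sums
  angk <- vapply(1:6, function(k) {
    th <- 2 * pi * k * (0:(n - 1)) / n
    atan2(sum(w * sin(th)), sum(w * cos(th)))
  }, numeric(1))
  c(ent = ent, enrg = sum(P),
    setNames(Mod(X[2:7]), paste0("fft", 1:6)),
    setNames(angk, paste0("ang", 1:6)))
}

# Time-domain features by direct formula evaluation.
time_features_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  c(max = max(x), min = min(x), mean = m,
    mdn = quantile(x, 0.5, names = FALSE), sd = s,
    p25 = quantile(x, 0.25, names = FALSE),
    p75 = quantile(x, 0.75, names = FALSE),
    krt = sum(((x - m) / s)^4) / n,
    skw = sum(((x - m) / s)^3) / n)
}

# Squared magnitude response of the digital 4th-order Butterworth
# low-pass (30 Hz cutoff at 200 Hz), applied twice for forward-backward
# filtering.
butter_gain_bidirectional <- function(f_hz, cutoff = 30, order = 4, rate = 200) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  z <- exp(1i * 2 * pi * f_hz / rate)
  H <- sum(bf$b * z^-(seq_along(bf$b) - 1)) / sum(bf$a * z^-(seq_along(bf$a) - 1))
  Mod(H)^2 # one magnitude per pass; two passes multiply magnitudes
}

# Dominant frequency of a series by direct-DFT periodogram.
dominant_freq_oracle <- function(x, rate) {
  n <- length(x)
  X <- fft(x) # periodogram location only; validated against dft_oracle elsewhere
  P <- Mod(X[2:(floor(n / 2))])^2
  which.max(P) / n * rate
}
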