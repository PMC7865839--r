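test_that("time features evaluate the defining formulas", {
  x <- c(1, 2, 3, 4)
  f <- time_features(x)
  expect_equal(unname(f[c("mean", "mdn", "sd")]), c(2.5, 2.5, 1.29099),
               tolerance = 1e-5)
  expect_equal(unname(f[c("max", "min", "p25", "p75")]), c(4, 1, 1.75, 3.25))
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(256, sd = runif(1, 0.1, 10))
    expect_equal(time_features(x), time_features_oracle(x), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("windows symmetric about their mean have zero skewness", {
  x <- c(-3, -1, 0, 1, 3) + 7
  expect_equal(unname(time_features(x)["skw"]), 0, tolerance = 1e-12)
})

test_that("Gaussian kurtosis approaches 3", {
  set.seed(42)
  x <- rnorm(2e5)
  k <- unname(time_features(x)["krt"])
  se <- sqrt(24 / length(x)) # asymptotic SE of sample kurtosis
  expect_lt(abs(k - 3), 3 * se + 0.02)
})

test_that("zero-variance windows are flagged with zeroed shape statistics", {
  f <- time_features(rep(2, 256))
  expect_true(attr(f, "degenerate"))
  expect_equal(unname(f[c("krt", "skw")]), c(0, 0))
  g <- freq_features(rep(0, 256))
  expect_true(attr(g, "degenerate"))
  expect_equal(unname(g[c("ent", "enrg")]), c(0, 0))
})

test_that("a single-bin spectrum has zero entropy", {
  p <- c(0, 1, rep(0, 127)) # synthetic one-sided power distribution
  nz <- p > 0
  expect_equal(-sum(p[nz] * log(p[nz])), 0)
  # a Hann-windowed constant concentrates power at DC: near-zero entropy
  f <- freq_features(rep(1, 256))
  expect_lt(unname(f["ent"]), 1.1) # leakage of the Hann window itself
})

test_that("a cosine at bin 5 dominates fft_1..6 and matches the DFT oracle", {
  n <- 256
  x <- cos(2 * pi * 5 * (0:(n - 1)) / n)
  f <- freq_features(x)
  mags <- f[paste0("fft", 1:6)]
  expect_equal(names(which.max(mags)), "fft5")
  expect_equal(unname(f["fft5"]), unname(freq_features_oracle(x)["fft5"]),
               tolerance = 1e-9)
})

test_that("all 14 frequency features agree with the brute-force DFT oracle", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(256, sd = runif(1, 0.1, 20))
    got <- freq_features(x)
    want <- freq_features_oracle(x)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-9)
  }
})

test_that("Parseval's identity pins the DFT convention of spectral energy", {
  set.seed(8)
  hw <- 0.5 * (1 - cos(2 * pi * (0:255) / 255))
  for (i in 1:10) {
    x <- rnorm(256)
    enrg <- unname(freq_features(x)["enrg"])
    expect_equal(enrg, 256 * sum((hw * x)^2), tolerance = 1e-6)
  }
})

test_that("entropy and quantile bounds hold on random windows", {
  set.seed(9)
  for (i in 1:30) {
    x <- rnorm(256)
    tf <- time_features(x)
    ff <- freq_features(x)
    expect_gte(unname(ff["ent"]), 0)
    expect_lte(unname(ff["ent"]), log(129)) # one-sided bin count for N = 256
    expect_lte(unname(tf["p25"]), unname(tf["mdn"]))
    expect_lte(unname(tf["mdn"]), unname(tf["p75"]))
    expect_lte(unname(tf["min"]), unname(tf["mean"]))
    expect_lte(unname(tf["mean"]), unname(tf["max"]))
  }
})

test_that("vectorised channel features equal the per-window functions", {
  set.seed(10)
  m <- matrix(rnorm(256 * 40), nrow = 256)
  f <- equispeed:::channel_features(m)
  for (j in c(1, 17, 40)) {
    expect_equal(f[j, feature_names()[1:9]], time_features(m[, j]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(f[j, feature_names()[10:23]], freq_features(m[, j]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("feature matrices have 138 columns per location and canonical names", {
  w <- small_windows()
  fm1 <- build_feature_matrix(w, "LH")
  expect_length(feature_columns(fm1), 138)
  expect_true("max_gyrz(LH)" %in% names(fm1))
  expect_true("ang6_accx(LH)" %in% names(fm1))
  fm_all <- build_feature_matrix(w, "All")
  expect_length(feature_columns(fm_all), 966)
  fm_limbs <- build_feature_matrix(w, "Limbs")
  expect_length(feature_columns(fm_limbs), 552)
  expect_equal(nrow(fm_all), nrow(w$meta))
  expect_identical(fm_all$window_id, w$meta$window_id)
  expect_false(anyNA(fm_all[feature_columns(fm_all)]))
})

test_that("the 11 feature sets are exactly the standard definitions", {
  defs <- feature_set_defs()
  expect_length(defs, 11)
  expect_setequal(defs$All, sensor_locations())
  expect_setequal(defs$Limbs, c("RF", "LF", "RH", "LH"))
  expect_setequal(defs[["Sac/Wth"]], c("sacrum", "withers"))
  expect_setequal(defs[["Sac/RF"]], c("sacrum", "RF"))
  singletons <- c("Sacrum", "Withers", "Poll", "RF", "LF", "RH", "LH")
  for (s in singletons) expect_length(defs[[s]], 1)
})

test_that("a missing location stream is reported by name", {
  w <- small_windows()
  w$channels$poll <- NULL
  expect_error(build_feature_matrix(w, "All"), "poll")
})
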