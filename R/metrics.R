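#' Regression error metrics
#'
#' `mae()` is the mean absolute error, `rmse()` the root-mean-square
#' error (both m/s here), and `nrmse()` the RMSE divided by the mean of
#' the measured speed vector, expressed as a percentage.
#'
#' @param estimated,measured Equal-length numeric vectors.
#' @return A single number.
#' @examples
#' mae(c(2, 4), c(1, 1))   # 2
#' nrmse(0.25, measured = c(3.25))  # 7.69...%
#' @export
mae <- function(estimated, measured) {
  check_paired(estimated, measured)
  mean(abs(estimated - measured))
}

#' @rdname mae
#' @export
rmse <- function(estimated, measured) {
  check_paired(estimated, measured)
  sqrt(mean((estimated - measured)^2))
}

#' @rdname mae
#' @param rmse_value A precomputed RMSE; alternatively supply
#'   `estimated` to compute it from predictions.
#' @export
nrmse <- function(rmse_value = NULL, measured, estimated = NULL) {
  if (is.null(rmse_value)) {
    rmse_value <- rmse(estimated, measured)
  }
  m <- mean(measured)
  if (m <= 0) stop("nRMSE undefined: mean measured speed must be positive")
  rmse_value / m * 100
}

check_paired <- function(estimated, measured) {
  if (length(estimated) != length(measured))
    stop("estimated and measured vectors must have equal length")
  if (length(measured) < 1) stop("need at least one pair")
  invisible(TRUE)
}
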