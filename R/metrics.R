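#' Validation metrics for paired estimate/reference series
#'
#' Given a series of estimates and the matching references (berry counts,
#' mean radii, or volumes), these functions compute the standard
#' validation metrics: mean error (ME), mean percentage error (MPE,
#' reported on the 0--100 scale), mean absolute error (MAE), root mean
#' squared error (RMSE) and the sample standard deviation of the errors.
#' Errors are always `est - ref`; standard deviations use the sample
#' (n - 1) denominator, the usual metrological (type-A) convention.
#'
#' @param est Numeric vector of estimated values.
#' @param ref Numeric vector of reference values, same length.
#' @return A single numeric value; `mean_percentage_error()` is a
#'   percentage.
#' @examples
#' mean_error(c(30, 28), c(31, 28))            # -0.5 berries
#' mean_percentage_error(c(2), c(1))           # +100 %
#' rmse(c(-3 + 1, 4 + 1), c(1, 1))             # sqrt(12.5)
#' @name validation-metrics
NULL

check_paired <- function(est, ref, min_n = 1L) {
  stopifnot(is.numeric(est), is.numeric(ref))
  if (length(est) != length(ref))
    stop("'est' and 'ref' must have the same length")
  if (length(est) < min_n)
    stop("need at least ", min_n, " pair(s)")
  if (anyNA(est) || anyNA(ref)) stop("missing values in paired series")
  invisible(NULL)
}

#' @rdname validation-metrics
#' @export
mean_error <- function(est, ref) {
  check_paired(est, ref)
  mean(est - ref)
}

#' @rdname validation-metrics
#' @export
mean_percentage_error <- function(est, ref) {
  check_paired(est, ref)
  if (any(ref == 0)) stop("MPE undefined: zero reference value")
  100 * mean((est - ref) / ref)
}

#' @rdname validation-metrics
#' @export
mae <- function(est, ref) {
  check_paired(est, ref)
  mean(abs(est - ref))
}

#' @rdname validation-metrics
#' @export
rmse <- function(est, ref) {
  check_paired(est, ref)
  sqrt(mean((est - ref)^2))
}

#' @rdname validation-metrics
#' @export
error_sd <- function(est, ref) {
  check_paired(est, ref, min_n = 2L)
  stats::sd(est - ref)
}

#' Coefficient of variability
#'
#' The ratio of the sample standard deviation to the mean of a series of
#' repeated measurements, as a percentage. Used to summarise the spread of
#' the three per-view volume estimates of one bunch.
#'
#' @param values Numeric vector, length >= 2, with non-zero mean.
#' @return Percentage.
#' @examples
#' coefficient_of_variability(c(8, 12))  # 28.28 %
#' @export
coefficient_of_variability <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("coefficient of variability undefined: zero mean")
  100 * stats::sd(values) / m
}
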