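#' Single-cluster counting-error model
#'
#' The counting error of the detector on images containing one grape
#' cluster is modelled as a normal random variable with mean `me` (ME)
#' and standard deviation `sigma_e`, both in berries. An image containing
#' `B` independent clusters then accumulates the sum of `B` such errors.
#'
#' @param me Mean error, berries (negative = under-counting).
#' @param sigma_e Standard deviation of the error, berries; >= 0.
#' @return An object of class `error_model`.
#' @examples
#' error_model(-1.57, 1.9)
#' @export
error_model <- function(me, sigma_e) {
  stopifnot(is.numeric(me), length(me) == 1L,
            is.numeric(sigma_e), length(sigma_e) == 1L)
  if (sigma_e < 0) stop("'sigma_e' must be >= 0")
  structure(list(me = me, sigma_e = sigma_e), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("counting error ~ N(%g, %g^2) berries\n", x$me, x$sigma_e))
  invisible(x)
}

check_bunches <- function(b) {
  if (length(b) != 1L || !is.numeric(b) || b < 1 || b != round(b))
    stop("'b' must be a single integer >= 1")
  as.integer(b)
}

#' Error distribution for an image with B clusters
#'
#' Assuming independent per-cluster errors, the error of an image with
#' `B` clusters is the sum of `B` iid normals, i.e.
#' `N(B * ME, B * sigma_e^2)`.
#'
#' @param model An [error_model()].
#' @param b Number of clusters per image, integer >= 1.
#' @return A list with `mu_b = b * me` and `sigma_b = sqrt(b) * sigma_e`.
#' @examples
#' extrapolate_error_pdf(error_model(-1.57, 1.9), b = 14)
#' @export
extrapolate_error_pdf <- function(model, b) {
  stopifnot(inherits(model, "error_model"))
  b <- check_bunches(b)
  list(mu_b = b * model$me, sigma_b = sqrt(b) * model$sigma_e)
}

folded_normal_mean <- function(mu, sigma) {
  if (sigma == 0) return(abs(mu))
  sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}

#' Closed-form extrapolated counting-error metrics
#'
#' For an image with `B` clusters the error distribution is
#' `N(mu_B, sigma_B^2)` with `mu_B = B * ME`, `sigma_B = sqrt(B) * sigma_E`
#' (see [extrapolate_error_pdf()]), and the three headline metrics have
#' closed forms:
#' \itemize{
#'   \item `me_b = mu_B` (first moment);
#'   \item `mae_b` = folded-normal mean
#'     `sigma_B * sqrt(2/pi) * exp(-mu_B^2 / (2 sigma_B^2)) +
#'      mu_B * (1 - 2 * pnorm(-mu_B / sigma_B))`;
#'   \item `rmse_b = sqrt(mu_B^2 + sigma_B^2)` — the square root of the
#'     second raw moment. The defining integral of the extrapolated RMSE
#'     is sometimes written without the root; the rooted form is the one
#'     in error units (berries) and the one used throughout here.
#' }
#'
#' @param model An [error_model()].
#' @param b Number of clusters per image, integer >= 1.
#' @param berries_per_cluster Optional reference count per cluster; when
#'   given, the normalized MAE (`mae_norm`, percent of the image's
#'   expected total `b * berries_per_cluster`) is included.
#' @return A list of class `extrapolated_metrics` with `b`, `me_b`,
#'   `mae_b`, `rmse_b` (berries) and, if requested, `mae_norm` (percent).
#' @examples
#' extrapolated_metrics(error_model(-1.57, 1.9), b = 14,
#'                      berries_per_cluster = 50)
#' @export
extrapolated_metrics <- function(model, b, berries_per_cluster = NULL) {
  p <- extrapolate_error_pdf(model, b)
  out <- list(b = as.integer(b),
              me_b = p$mu_b,
              mae_b = folded_normal_mean(p$mu_b, p$sigma_b),
              rmse_b = sqrt(p$mu_b^2 + p$sigma_b^2))
  if (!is.null(berries_per_cluster))
    out$mae_norm <- normalized_mae(out$mae_b, b, berries_per_cluster)
  structure(out, class = "extrapolated_metrics")
}

#' @export
print.extrapolated_metrics <- function(x, ...) {
  cat(sprintf("B = %d clusters: ME = %.4g, MAE = %.4g, RMSE = %.4g berries",
              x$b, x$me_b, x$mae_b, x$rmse_b))
  if (!is.null(x$mae_norm)) cat(sprintf(", MAE_norm = %.3g%%", x$mae_norm))
  cat("\n")
  invisible(x)
}

#' Quadrature oracle for the extrapolated metrics
#'
#' Evaluates the three defining integrals — the first moment, the mean of
#' `|x|`, and the root of the second raw moment of `N(B*ME, B*sigma_E^2)`
#' — by adaptive quadrature ([stats::integrate()]) instead of the closed
#' forms. Intended as an independent cross-check of
#' [extrapolated_metrics()].
#'
#' @inheritParams extrapolated_metrics
#' @param rel_tol Relative tolerance passed to the quadrature.
#' @return As [extrapolated_metrics()].
#' @export
extrapolated_metrics_quadrature <- function(model, b,
                                            berries_per_cluster = NULL,
                                            rel_tol = 1e-10) {
  p <- extrapolate_error_pdf(model, b)
  if (p$sigma_b == 0)
    stop("quadrature oracle requires sigma_e > 0 (degenerate distribution)")
  # integrate in the standardized variable x = mu + sigma * z so the
  # adaptive rule always sees the mass, however narrow or off-center
  quad <- function(f) {
    r <- stats::integrate(function(z)
      f(p$mu_b + p$sigma_b * z) * stats::dnorm(z), -Inf, Inf,
      rel.tol = rel_tol)
    if (r$message != "OK")
      stop("quadrature did not converge: ", r$message)
    r$value
  }
  out <- list(b = as.integer(b),
              me_b = quad(identity),
              mae_b = quad(abs),
              rmse_b = sqrt(quad(function(x) x^2)))
  if (!is.null(berries_per_cluster))
    out$mae_norm <- normalized_mae(out$mae_b, b, berries_per_cluster)
  structure(out, class = "extrapolated_metrics")
}

#' Normalized extrapolated MAE
#'
#' The extrapolated MAE expressed as a percentage of the expected number
#' of berries in the image, `b * berries_per_cluster`.
#'
#' @param mae_b Extrapolated MAE, berries.
#' @param b Number of clusters per image.
#' @param berries_per_cluster Average berries per cluster (> 0).
#' @return Percentage.
#' @examples
#' normalized_mae(21.98, 14, 50)  # ~3.14 %
#' @export
normalized_mae <- function(mae_b, b, berries_per_cluster) {
  b <- check_bunches(b)
  stopifnot(is.numeric(berries_per_cluster),
            length(berries_per_cluster) == 1L)
  if (berries_per_cluster <= 0) stop("'berries_per_cluster' must be > 0")
  100 * mae_b / (b * berries_per_cluster)
}
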