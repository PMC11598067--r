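#' Build a source table for a power-product uncertainty budget
#'
#' The estimated whole-bunch volume is a power product of its inputs:
#' `V = v_visible_px * d^3 * f^-3 * R` (the pixel-to-mm factor `d/f`
#' enters cubed). Each input is one uncertainty source, characterised by
#' its name, nominal value, standard uncertainty and the signed integer
#' power with which it enters the measurand.
#'
#' @param name Character vector of source labels.
#' @param value Nominal values (all non-zero).
#' @param sigma Standard uncertainties (>= 0).
#' @param exponent Signed integer powers.
#' @return A data frame of class `uncertainty_sources`.
#' @examples
#' volume_uncertainty_sources(1.96e6, 2.8e5, 500, 25, 1150, 2, 1.8, 0.32)
#' @export
uncertainty_sources <- function(name, value, sigma, exponent) {
  stopifnot(length(name) == length(value),
            length(value) == length(sigma),
            length(sigma) == length(exponent))
  if (any(value == 0)) stop("source nominal values must be non-zero")
  if (any(sigma < 0)) stop("source uncertainties must be >= 0")
  if (any(exponent != round(exponent)))
    stop("source exponents must be integers")
  structure(data.frame(name = as.character(name), value = value,
                       sigma = sigma, exponent = as.integer(exponent),
                       stringsAsFactors = FALSE),
            class = c("uncertainty_sources", "data.frame"))
}

#' @rdname uncertainty_sources
#' @param v_visible_px,sigma_v Estimated visible volume (px^3) and its
#'   uncertainty.
#' @param d,sigma_d Object distance (mm) and its uncertainty.
#' @param f,sigma_f Focal length (px) and its uncertainty.
#' @param r,sigma_r Occlusion ratio R and its uncertainty.
#' @export
volume_uncertainty_sources <- function(v_visible_px, sigma_v, d, sigma_d,
                                       f, sigma_f, r, sigma_r) {
  uncertainty_sources(
    name = c("v_visible_px", "d", "f", "R"),
    value = c(v_visible_px, d, f, r),
    sigma = c(sigma_v, sigma_d, sigma_f, sigma_r),
    exponent = c(1L, 3L, -3L, 1L))
}

#' First-order (GUM) uncertainty budget of a power product
#'
#' For a measurand `y = prod(x_i ^ p_i)` of mutually independent inputs,
#' the first-order law of propagation gives the relative combined
#' variance as the sum of the per-source terms
#' `p_i^2 * (sigma_i / x_i)^2`. Each source's uncertainty percentage
#' contribution (UPC) is its share of that combined variance — the only
#' definition under which the contributions sum to 100%.
#'
#' @param sources An [uncertainty_sources()] table.
#' @return A list of class `uncertainty_budget`: `value` (nominal
#'   measurand), `combined_sigma`, `rel_sigma`, `upc` (named percentages
#'   summing to 100) and the source table.
#' @examples
#' s <- volume_uncertainty_sources(1e6, 2.8e5, 500, 25, 1000, 2, 1.8, 0.32)
#' propagate_power_product(s)
#' @export
propagate_power_product <- function(sources) {
  stopifnot(inherits(sources, "uncertainty_sources"))
  if (nrow(sources) < 1L) stop("need at least one source")
  relvar <- sources$exponent^2 * (sources$sigma / sources$value)^2
  total <- sum(relvar)
  value <- prod(sources$value^sources$exponent)
  upc <- if (total > 0) 100 * relvar / total else rep(0, nrow(sources))
  names(upc) <- sources$name
  structure(list(value = value,
                 rel_sigma = sqrt(total),
                 combined_sigma = abs(value) * sqrt(total),
                 upc = upc,
                 sources = sources),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("measurand: %.6g, combined sigma: %.6g (rel. %.4g)\n",
              x$value, x$combined_sigma, x$rel_sigma))
  tab <- data.frame(source = x$sources$name, value = x$sources$value,
                    sigma = x$sources$sigma, exponent = x$sources$exponent,
                    upc_pct = round(unname(x$upc), 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Uncertainty of a sum of sphere volumes
#'
#' The reference volumes are sums of per-berry sphere volumes; with an
#' uncorrelated per-radius uncertainty `sigma_r` the first-order
#' sensitivity of each term `(4/3) pi r^3` is `4 pi r^2`, so
#' `sigma_V^2 = sum((4 pi r_k^2)^2) * sigma_r^2`.
#'
#' @param radii Per-berry radii (all > 0), px or mm.
#' @param sigma_r Standard uncertainty of a single radius measurement, in
#'   the same unit (e.g. `1/sqrt(3)` px for annotations on a 1 px grid,
#'   see [type_b_uniform_sigma()]).
#' @param unit `"px3"` or `"mm3"`, the unit of the resulting volume.
#' @return A [quantity()]: the summed volume with its uncertainty.
#' @examples
#' propagate_sphere_sum(25, 1 / sqrt(3), "px3")  # sigma ~ 4535 px^3
#' @export
propagate_sphere_sum <- function(radii, sigma_r, unit = c("px3", "mm3")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(radii), is.numeric(sigma_r), length(sigma_r) == 1L)
  if (length(radii) == 0L) stop("empty radius list")
  if (any(radii <= 0)) stop("radii must be > 0")
  if (sigma_r < 0) stop("'sigma_r' must be >= 0")
  quantity(sum(sphere_volume(radii)),
           sqrt(sum((4 * pi * radii^2)^2) * sigma_r^2),
           unit)
}

#' Type-A uncertainty of the volume estimator from paired residuals
#'
#' The uncertainty attached to the detector's visible-volume estimate is
#' the RMSE between the estimated and the reference visible pixel volumes
#' over a validation set.
#'
#' @param estimates Estimated volumes.
#' @param references Matching reference volumes.
#' @param unit Unit tag of the volumes.
#' @return A [quantity()] whose `sigma` is the RMSE; the value slot holds
#'   the mean estimate.
#' @export
estimator_rmse_sigma <- function(estimates, references,
                                 unit = c("px3", "mm3")) {
  unit <- match.arg(unit)
  check_paired(estimates, references)
  quantity(mean(estimates), rmse(estimates, references), unit)
}

#' Monte Carlo cross-check of a linear uncertainty budget
#'
#' Samples every source as an independent normal, evaluates the power
#' product, and reports the empirical standard deviation of the measurand
#' together with an empirical UPC obtained by one-at-a-time re-sampling
#' (each source varied alone, the others held at their nominals; the
#' resulting variances are normalised to percentages). Agreement with
#' [propagate_power_product()] validates the first-order approximation;
#' at large relative uncertainties the two legitimately diverge.
#'
#' @param sources An [uncertainty_sources()] table.
#' @param n_samples Number of draws, >= 1e4; default 1e6.
#' @param seed Integer seed; the sampler is deterministic given it.
#' @return A list of class `uncertainty_budget` (empirical `combined_sigma`,
#'   `rel_sigma` about the mean, `upc`, plus `mean` of the measurand).
#' @export
monte_carlo_budget <- function(sources, n_samples = 1e6, seed = 1L) {
  stopifnot(inherits(sources, "uncertainty_sources"))
  if (n_samples < 1e4) stop("'n_samples' must be >= 1e4")
  k <- nrow(sources)
  measurand <- function(x) {
    y <- rep(1, nrow(x))
    for (j in seq_len(k)) y <- y * x[, j]^sources$exponent[j]
    y
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- vapply(seq_len(k), function(j)
    stats::rnorm(n_samples, sources$value[j], sources$sigma[j]),
    numeric(n_samples))
  y <- measurand(draws)
  # one-at-a-time: vary source j only, others at nominal
  varj <- vapply(seq_len(k), function(j) {
    x <- matrix(rep(sources$value, each = n_samples), ncol = k)
    x[, j] <- stats::rnorm(n_samples, sources$value[j], sources$sigma[j])
    stats::var(measurand(x))
  }, numeric(1))
  upc <- if (sum(varj) > 0) 100 * varj / sum(varj) else rep(0, k)
  names(upc) <- sources$name
  m <- mean(y)
  structure(list(value = m, mean = m,
                 rel_sigma = stats::sd(y) / abs(m),
                 combined_sigma = stats::sd(y),
                 upc = upc,
                 sources = sources,
                 n_samples = n_samples, seed = seed),
            class = "uncertainty_budget")
}

#' Compatibility of a measurement with its reference
#'
#' A measured value is compatible with its reference when the difference
#' lies within `k` combined standard uncertainties; `k = 2` corresponds to
#' the conventional ~95% coverage band under normality.
#'
#' @param error Signed difference(s) measurement minus reference, mm^3.
#' @param sigma Combined standard uncertainty (same unit, > 0); recycled.
#' @param k Coverage factor, default 2.
#' @return Logical vector.
#' @examples
#' compatibility_check(c(0, 30), 10)  # TRUE, FALSE
#' @export
compatibility_check <- function(error, sigma, k = 2) {
  stopifnot(is.numeric(error), is.numeric(sigma), is.numeric(k))
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  if (k <= 0) stop("coverage factor 'k' must be > 0")
  abs(error) <= k * sigma
}
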