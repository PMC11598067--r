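#' Create a quantity with a standard uncertainty
#'
#' A `quantity` is the currency of uncertainty propagation in this package:
#' a numeric value, its standard uncertainty, and a unit tag. Units are
#' carried explicitly so that pixel and metric volumes cannot be mixed
#' silently.
#'
#' @param value Numeric value in the stated unit. May be `NA` for
#'   quantities that only carry an uncertainty (e.g. a type-B assignment).
#' @param sigma Standard uncertainty, in the same unit; must be >= 0.
#' @param unit Unit tag, one of `"px"`, `"mm"`, `"px3"`, `"mm3"`,
#'   `"dimensionless"`, `"mm_per_px"`.
#' @return An object of class `quantity`.
#' @examples
#' quantity(500, 25, "mm")
#' @export
quantity <- function(value, sigma = 0,
                     unit = c("dimensionless", "px", "mm", "px3", "mm3",
                              "mm_per_px")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(value), length(value) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (!is.na(sigma) && sigma < 0)
    stop("standard uncertainty 'sigma' must be >= 0")
  structure(list(value = as.numeric(value), sigma = as.numeric(sigma),
                 unit = unit),
            class = "quantity")
}

#' @export
print.quantity <- function(x, ...) {
  cat(sprintf("%g +/- %g %s\n", x$value, x$sigma, x$unit))
  invisible(x)
}

#' @export
format.quantity <- function(x, ...) {
  sprintf("%g +/- %g %s", x$value, x$sigma, x$unit)
}

#' Type-B standard uncertainty from a uniform half-width
#'
#' A quantity known only to lie within +/- `a` of its nominal value is
#' modelled as uniform on that interval; its standard uncertainty is
#' `a / sqrt(3)`. Typical uses here: half a pixel-grid resolution (a = 1 px
#' for manually annotated radii) and the repeatability half-width of a
#' caliper measurement (a = 0.3 mm).
#'
#' @param a Half-width of the uniform interval; must be >= 0.
#' @param unit Unit tag (see [quantity()]).
#' @return A `quantity` whose `sigma` is `a / sqrt(3)`; the value slot is
#'   `NA` because a type-B assignment carries no nominal value of its own.
#' @examples
#' type_b_uniform_sigma(1, "px")    # 0.5774 px
#' type_b_uniform_sigma(0.3, "mm")  # 0.1732 mm
#' @export
type_b_uniform_sigma <- function(a, unit = "dimensionless") {
  stopifnot(is.numeric(a), length(a) == 1L)
  if (a < 0) stop("half-width 'a' must be >= 0")
  quantity(NA_real_, a / sqrt(3), unit)
}
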