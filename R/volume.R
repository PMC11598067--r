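#' Spherical berry volume
#'
#' Berries of the round table-grape varieties this toolchain targets are
#' well approximated by spheres, so every volume in the package reduces to
#' sums of `(4/3) * pi * r^3` terms.
#'
#' @param r Radius (or vector of radii), any length unit; must be >= 0.
#' @return Volume(s) in the cube of the input unit.
#' @examples
#' sphere_volume(1)    # 4.18879
#' sphere_volume(9.5)  # 3591.364 (mm^3 for r in mm)
#' @export
sphere_volume <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0)) stop("radius must be >= 0")
  (4 / 3) * pi * r^3
}

set_volume_unit <- function(x, unit, approximation = NULL) {
  attr(x, "unit") <- unit
  if (!is.null(approximation)) attr(x, "approximation") <- approximation
  x
}

check_volume_unit <- function(x, expected, what) {
  u <- attr(x, "unit")
  if (!is.null(u) && u != expected)
    stop(what, " must be in ", expected, ", got ", u,
         "; convert units explicitly before mixing them")
  invisible(x)
}

#' Estimated visible bunch volume in pixels
#'
#' The detector reports a visible-berry count and a single mean radius per
#' image; the estimated visible volume is therefore
#' `n_est * (4/3) * pi * r_mean_est_px^3`, in cubic pixels.
#'
#' @param n_est Estimated number of visible berries (>= 0).
#' @param r_mean_est_px Estimated mean berry radius, px (> 0).
#' @return Volume in px^3, tagged with `unit = "px3"`.
#' @examples
#' visible_volume_estimated(30, 25)  # 1.9635e6 px^3
#' @export
visible_volume_estimated <- function(n_est, r_mean_est_px) {
  stopifnot(is.numeric(n_est), is.numeric(r_mean_est_px))
  if (any(n_est < 0)) stop("'n_est' must be >= 0")
  if (any(r_mean_est_px <= 0)) stop("'r_mean_est_px' must be > 0")
  set_volume_unit(n_est * sphere_volume(r_mean_est_px), "px3")
}

reference_volume <- function(radii, n, r_mean, unit, what) {
  if (!is.null(radii)) {
    if (length(radii) == 0L) {
      warning(what, ": empty radius list, volume is 0")
      return(set_volume_unit(0, unit, approximation = "empty"))
    }
    if (any(radii <= 0)) stop(what, ": radii must be > 0")
    return(set_volume_unit(sum(sphere_volume(radii)), unit))
  }
  if (is.null(n) || is.null(r_mean))
    stop(what, ": supply either per-berry 'radii' or both 'n' and 'r_mean'")
  if (n < 0) stop(what, ": 'n' must be >= 0")
  if (r_mean <= 0) stop(what, ": 'r_mean' must be > 0")
  set_volume_unit(n * sphere_volume(r_mean), unit,
                  approximation = "mean-radius")
}

#' Reference visible bunch volume in pixels
#'
#' Sum of the per-berry sphere volumes of the berries visible in one
#' image, from their manually annotated radii in pixels. When only the
#' mean radius is available (as in the packaged summary tables), pass `n`
#' and `r_mean_px` instead: the result uses the mean-radius approximation
#' `n * (4/3) * pi * r_mean^3` and is tagged
#' `approximation = "mean-radius"`, because replacing individual radii by
#' their mean changes the third-moment sum.
#'
#' @param radii_px Per-berry radii, px (all > 0), or `NULL`.
#' @param n,r_mean_px Visible count and mean radius, used when `radii_px`
#'   is `NULL`.
#' @return Volume in px^3, tagged with `unit = "px3"`.
#' @examples
#' visible_volume_reference(c(20, 25))          # exact per-berry sum
#' visible_volume_reference(n = 30, r_mean_px = 25)  # mean-radius approx.
#' @export
visible_volume_reference <- function(radii_px = NULL, n = NULL,
                                     r_mean_px = NULL) {
  reference_volume(radii_px, n, r_mean_px, "px3",
                   "visible reference volume")
}

#' Reference whole-bunch volume in millimeters
#'
#' Sum of the per-berry sphere volumes over all berries of the bunch, from
#' caliper-measured radii in mm; the mean-radius fallback works as in
#' [visible_volume_reference()].
#'
#' @param radii_mm Per-berry radii, mm (all > 0), or `NULL`.
#' @param n,r_mean_mm Total count and mean radius, used when `radii_mm` is
#'   `NULL`.
#' @return Volume in mm^3, tagged with `unit = "mm3"`.
#' @examples
#' bunch_volume_reference(n = 47, r_mean_mm = 10.1)  # 202765.6 mm^3
#' @export
bunch_volume_reference <- function(radii_mm = NULL, n = NULL,
                                   r_mean_mm = NULL) {
  reference_volume(radii_mm, n, r_mean_mm, "mm3",
                   "whole-bunch reference volume")
}

#' Total/visible volume ratio R
#'
#' A single image shows only the front shell of a bunch; the correction
#' factor `R` maps visible metric volume to whole-bunch volume. It is
#' computed as the mean over images of the per-image ratio
#' `v_total_mm / v_visible_mm` (not the ratio of the means), with its
#' standard uncertainty taken as the sample standard deviation of those
#' per-image ratios.
#'
#' @param v_total_mm Whole-bunch volumes, mm^3, one per image.
#' @param v_visible_mm Matching visible volumes, mm^3 (> 0).
#' @return An object of class `ratio_estimate` with `r_mean`, `r_sigma`
#'   and `n_images`.
#' @examples
#' ratio_R(c(2, 4), c(1, 2))  # R = 2, sigma = 0
#' @export
ratio_R <- function(v_total_mm, v_visible_mm) {
  check_paired(v_total_mm, v_visible_mm)
  if (any(v_visible_mm <= 0)) stop("visible volumes must be > 0")
  ratios <- v_total_mm / v_visible_mm
  structure(list(r_mean = mean(ratios),
                 r_sigma = if (length(ratios) >= 2L) stats::sd(ratios) else 0,
                 n_images = length(ratios)),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("R = %.4g +/- %.4g (from %d images)\n",
              x$r_mean, x$r_sigma, x$n_images))
  invisible(x)
}

#' Estimated whole-bunch volume in metric units
#'
#' The final output of the volume chain: the estimated visible pixel
#' volume is converted to mm^3 through the cubed pixel-to-mm factor and
#' scaled by the occlusion ratio `R`,
#' `v_total_mm = v_visible_px * C^3 * R`.
#'
#' @param v_visible_px Estimated visible volume, px^3 (a `px3`-tagged
#'   volume or plain numeric).
#' @param c_mm_per_px Conversion factor, mm/px: a [quantity()] from
#'   [px_to_mm_factor()] or a plain positive number.
#' @param ratio A [ratio_R()] estimate or a plain positive number.
#' @return Volume in mm^3, tagged with `unit = "mm3"`.
#' @examples
#' total_volume_estimated(1.9635e6, 0.5, 1.8)  # ~441787 mm^3
#' @export
total_volume_estimated <- function(v_visible_px, c_mm_per_px, ratio) {
  check_volume_unit(v_visible_px, "px3", "estimated visible volume")
  if (inherits(c_mm_per_px, "quantity")) {
    if (c_mm_per_px$unit != "mm_per_px")
      stop("conversion factor must be in mm/px, got ", c_mm_per_px$unit)
    c_mm_per_px <- c_mm_per_px$value
  }
  r <- if (inherits(ratio, "ratio_estimate")) ratio$r_mean else ratio
  stopifnot(is.numeric(c_mm_per_px), is.numeric(r))
  if (any(v_visible_px < 0)) stop("visible volume must be >= 0")
  if (c_mm_per_px <= 0) stop("conversion factor must be > 0")
  if (r <= 0) stop("ratio R must be > 0")
  set_volume_unit(as.numeric(v_visible_px) * c_mm_per_px^3 * r, "mm3",
                  approximation = attr(v_visible_px, "approximation"))
}
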