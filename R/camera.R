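#' Pinhole camera model with type-B uncertainties
#'
#' Describes the imaging geometry as a weak-perspective pinhole camera: a
#' focal length `f` in pixels and a single object--camera distance `d` in
#' millimeters shared by all berries of a bunch. Depth variation within a
#' bunch is absorbed into `sigma_d` (half the bunch thickness is a natural
#' choice).
#'
#' @param f Focal length, px; must be > 0. There is no default: the focal
#'   length comes from a camera calibration and must always be supplied.
#' @param d Object--camera distance, mm; must be > 0.
#' @param sigma_f Standard uncertainty of `f`, px (>= 0).
#' @param sigma_d Standard uncertainty of `d`, mm (>= 0).
#' @return An object of class `camera_model`.
#' @examples
#' camera_model(f = 1150, d = 500, sigma_f = 2, sigma_d = 25)
#' @export
camera_model <- function(f, d = 500, sigma_f = 0, sigma_d = 0) {
  stopifnot(is.numeric(f), length(f) == 1L, is.numeric(d), length(d) == 1L)
  if (!is.finite(f) || f <= 0) stop("focal length 'f' must be a positive number")
  if (!is.finite(d) || d <= 0) stop("distance 'd' must be a positive number")
  if (sigma_f < 0 || sigma_d < 0) stop("uncertainties must be >= 0")
  structure(list(f = f, d = d, sigma_f = sigma_f, sigma_d = sigma_d),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera: f = %g +/- %g px, d = %g +/- %g mm\n",
              x$f, x$sigma_f, x$d, x$sigma_d))
  invisible(x)
}

#' Pixel-to-millimeter conversion factor of a pinhole camera
#'
#' Under weak perspective an object of size `s` mm at distance `d` images
#' at `s * f / d` pixels, so one pixel corresponds to `C = d / f`
#' millimeters. The standard uncertainty of `C` is propagated to first
#' order from `sigma_d` and `sigma_f`:
#' `(sigma_C / C)^2 = (sigma_d / d)^2 + (sigma_f / f)^2`.
#'
#' @param camera A [camera_model()].
#' @return A [quantity()] in mm/px.
#' @examples
#' px_to_mm_factor(camera_model(f = 1000, d = 500))  # 0.5 mm/px
#' @export
px_to_mm_factor <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  value <- camera$d / camera$f
  rel <- sqrt((camera$sigma_d / camera$d)^2 + (camera$sigma_f / camera$f)^2)
  quantity(value, value * rel, "mm_per_px")
}

#' Read camera parameters from a structured config file
#'
#' Reads the keys `focal_px`, `focal_sigma_px`, `distance_mm`,
#' `distance_sigma_mm` from a YAML or JSON file (dispatched on the file
#' extension). `focal_px` is mandatory — a focal length is always the
#' product of a calibration and has no sensible default; the distance keys
#' default to the bench geometry d = 500 +/- 25 mm and `focal_sigma_px`
#' to 2 px.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [camera_model()].
#' @export
read_camera_config <- function(path) {
  if (!file.exists(path)) stop("camera config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported camera config format: .", ext, " (use YAML or JSON)"))
  if (is.null(cfg$focal_px))
    stop("camera config must provide 'focal_px'; ",
         "the focal length has no default")
  camera_model(f = as.numeric(cfg$focal_px),
               d = if (is.null(cfg$distance_mm)) 500 else as.numeric(cfg$distance_mm),
               sigma_f = if (is.null(cfg$focal_sigma_px)) 2 else as.numeric(cfg$focal_sigma_px),
               sigma_d = if (is.null(cfg$distance_sigma_mm)) 25 else as.numeric(cfg$distance_sigma_mm))
}
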