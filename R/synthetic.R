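# Synthetic vineyard generator: 3D berry packings, rotated views with
# occlusion, and a detector-error emulator, so the validation chain can be
# exercised end-to-end without any imagery.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Parameters of the synthetic bunch generator
#'
#' Defaults emulate the bunches of the packaged validation study: 36--76
#' berries per bunch (uniform), berry radii from a truncated normal with
#' mean 9.5 mm and sd 0.45 mm (the per-bunch means of the reference table
#' span 9.2--10.1 mm with sds 0.35--0.59 mm), packed without substantial
#' overlap into an upright ellipsoid envelope. The envelope semi-axes
#' (45, 45, 90 mm) give a packing fraction at which rejection packing of
#' the largest bunches still succeeds while lines of sight cross several
#' berries, producing realistic occlusion.
#'
#' @param n_berries_range Integer interval (min, max) for the berry count.
#' @param r_mean_mm,r_sd_mm Mean and sd of the berry radius, mm; the sd
#'   must stay below a third of the mean so the +/- 3 sd truncation keeps
#'   radii positive.
#' @param envelope_mm Ellipsoid semi-axes (x, y, z), mm; z is vertical.
#' @param overlap_tol Allowed fractional overlap of neighbouring berries:
#'   centers may approach to `(1 - overlap_tol)` times the sum of radii
#'   (real berries press against each other).
#' @param max_attempts Placement attempts per berry before the packing is
#'   declared infeasible.
#' @return A list of class `synthetic_bunch_params`.
#' @export
synthetic_bunch_params <- function(n_berries_range = c(36L, 76L),
                                   r_mean_mm = 9.5, r_sd_mm = 0.45,
                                   envelope_mm = c(45, 45, 90),
                                   overlap_tol = 0.15,
                                   max_attempts = 5000L) {
  stopifnot(length(n_berries_range) == 2L, length(envelope_mm) == 3L)
  if (any(n_berries_range < 1) ||
      n_berries_range[1] > n_berries_range[2])
    stop("'n_berries_range' must be a positive interval (min <= max)")
  if (r_mean_mm <= 0 || r_sd_mm < 0) stop("radius parameters must be positive")
  if (r_sd_mm >= r_mean_mm / 3)
    stop("'r_sd_mm' must be < r_mean_mm / 3 to keep truncated radii positive")
  if (any(envelope_mm <= 0)) stop("envelope semi-axes must be > 0")
  if (overlap_tol < 0 || overlap_tol >= 1)
    stop("'overlap_tol' must be in [0, 1)")
  structure(list(n_berries_range = as.integer(n_berries_range),
                 r_mean_mm = r_mean_mm, r_sd_mm = r_sd_mm,
                 envelope_mm = envelope_mm, overlap_tol = overlap_tol,
                 max_attempts = as.integer(max_attempts)),
            class = "synthetic_bunch_params")
}

#' Default camera of the synthetic bench
#'
#' d = 500 +/- 25 mm reproduces the acquisition bench of the validation
#' study; f = 1150 px is chosen so that 9.5 mm berries image at about
#' 22 px, the middle of the annotated 19--25 px range. sigma_f = 2 px is
#' a typical calibration residual.
#'
#' @return A [camera_model()].
#' @export
synthetic_camera <- function() {
  camera_model(f = 1150, d = 500, sigma_f = 2, sigma_d = 25)
}

rtruncnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[abs(x - mean) <= 3 * sd])
  }
  out[seq_len(n)]
}

runif_ellipsoid <- function(semi) {
  # uniform point in an ellipsoid: uniform in unit ball, then scale axes
  repeat {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) <= 1) return(u * semi)
  }
}

#' Generate a synthetic grape bunch
#'
#' Draws a berry count uniformly from the configured range, berry radii
#' from the truncated normal, and packs the berries sequentially at
#' uniform random positions inside the ellipsoid envelope, rejecting
#' placements that overlap an already placed berry by more than the
#' allowed tolerance. The scene is fully reproducible from `seed`.
#'
#' @param params A [synthetic_bunch_params()].
#' @param camera A [camera_model()]; defaults to [synthetic_camera()].
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return A list of class `synthetic_scene`: `centers` (M x 3 matrix,
#'   mm, z vertical), `radii_mm`, `camera`, `params`, `seed`.
#' @examples
#' scene <- generate_bunch(seed = 42)
#' nrow(scene$centers)
#' @export
generate_bunch <- function(params = synthetic_bunch_params(),
                           camera = synthetic_camera(), seed = NULL) {
  stopifnot(inherits(params, "synthetic_bunch_params"),
            inherits(camera, "camera_model"))
  gen <- function() {
    rng <- params$n_berries_range
    m <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    radii <- rtruncnorm3(m, params$r_mean_mm, params$r_sd_mm)
    semi <- params$envelope_mm
    centers <- matrix(NA_real_, m, 3)
    shrink <- 1 - params$overlap_tol
    for (i in seq_len(m)) {
      placed <- FALSE
      for (att in seq_len(params$max_attempts)) {
        p <- runif_ellipsoid(pmax(semi - radii[i], 0))
        if (i == 1L) { ok <- TRUE } else {
          prev <- seq_len(i - 1L)
          d2 <- (centers[prev, 1] - p[1])^2 + (centers[prev, 2] - p[2])^2 +
                (centers[prev, 3] - p[3])^2
          ok <- all(d2 >= (shrink * (radii[prev] + radii[i]))^2)
        }
        if (ok) { centers[i, ] <- p; placed <- TRUE; break }
      }
      if (!placed)
        stop("berry packing failed after ", params$max_attempts,
             " attempts; enlarge 'envelope_mm' or 'overlap_tol'")
    }
    structure(list(centers = centers, radii_mm = radii, camera = camera,
                   params = params, seed = seed),
              class = "synthetic_scene")
  }
  if (is.null(seed)) gen() else local_seed(seed, gen())
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic bunch: %d berries, mean radius %.2f mm\n",
              nrow(x$centers), mean(x$radii_mm)))
  invisible(x)
}

# equal-area polar sampling grid on the unit disc (center + 6 rings x 16)
disc_grid <- local({
  nr <- 6L; na <- 16L
  rr <- sqrt((seq_len(nr) - 0.5) / nr)
  th <- 2 * pi * (seq_len(na) - 1L) / na
  g <- cbind(c(0, rep(rr, each = na) * cos(th)),
             c(0, rep(rr, each = na) * sin(th)))
  g
})

#' Project a synthetic bunch to one annotated view
#'
#' The bunch is rotated by 0, 120 or 240 degrees about its vertical (z)
#' axis and imaged by a weak-perspective camera on the -y axis: berries
#' project to discs at their (x, z) coordinates with pixel radius
#' `r_mm * f / d`; depth (y) only orders the discs for occlusion. A berry
#' is visible when less than `occlusion_threshold` of its projected disc
#' is covered by the union of strictly nearer discs; coverage is estimated
#' on a fixed equal-area polar grid of 97 points, so the projection is
#' deterministic.
#'
#' @param scene A [generate_bunch()] scene.
#' @param view_index 1, 2 or 3 (rotations 0, 120, 240 degrees).
#' @param occlusion_threshold Covered-fraction above which a berry is
#'   counted as hidden; in (0, 1]. Default 0.75.
#' @return A list of class `view_annotation`: `view_index`, `visible`
#'   (berry indices), `n_visible`, `r_mean_px`, `radii_px` and `radii_mm`
#'   of the visible berries, `v_visible_mm` (per-berry visible metric
#'   volume), `v_total_mm`, `true_R` (per-berry total/visible ratio) and
#'   `true_R_mean_radius` (same ratio with the visible volume computed
#'   from the mean radius, the form the estimation pipeline can access).
#' @export
project_view <- function(scene, view_index, occlusion_threshold = 0.75) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!view_index %in% 1:3) stop("'view_index' must be 1, 2 or 3")
  if (occlusion_threshold <= 0 || occlusion_threshold > 1)
    stop("'occlusion_threshold' must be in (0, 1]")
  ang <- (view_index - 1) * 2 * pi / 3
  rot <- matrix(c(cos(ang), -sin(ang), 0,
                  sin(ang),  cos(ang), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  ctr <- scene$centers %*% t(rot)
  r <- scene$radii_mm
  m <- length(r)
  ord <- order(ctr[, 2])                       # camera at -y: nearest first
  covered_frac <- numeric(m)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (pos == 1L) next
    nearer <- ord[seq_len(pos - 1L)]
    px <- ctr[i, 1] + r[i] * disc_grid[, 1]
    pz <- ctr[i, 3] + r[i] * disc_grid[, 2]
    cov <- rep(FALSE, nrow(disc_grid))
    for (j in nearer) {
      cov <- cov | ((px - ctr[j, 1])^2 + (pz - ctr[j, 3])^2 <= r[j]^2)
      if (all(cov)) break
    }
    covered_frac[i] <- mean(cov)
  }
  visible <- which(covered_frac < occlusion_threshold)
  cpx <- scene$camera$f / scene$camera$d
  radii_px <- r[visible] * cpx
  v_total <- sum(sphere_volume(r))
  v_vis <- sum(sphere_volume(r[visible]))
  n_vis <- length(visible)
  r_mean_mm <- if (n_vis) mean(r[visible]) else NA_real_
  structure(list(view_index = as.integer(view_index),
                 visible = visible,
                 n_visible = n_vis,
                 r_mean_px = if (n_vis) mean(radii_px) else NA_real_,
                 radii_px = radii_px,
                 radii_mm = r[visible],
                 v_visible_mm = v_vis,
                 v_total_mm = v_total,
                 true_R = if (n_vis) v_total / v_vis else Inf,
                 true_R_mean_radius = if (n_vis)
                   v_total / (n_vis * sphere_volume(r_mean_mm)) else Inf),
            class = "view_annotation")
}

#' Emulate the detector on one annotated view
#'
#' Perturbs a view annotation with the detector's empirical error laws:
#' the visible count receives a rounded normal error (default
#' N(-1.57, 1.9^2) berries, the single-cluster counting-error model of
#' the validation study, floored at zero) and the mean radius a normal
#' error in pixels (default N(0.15, 1.5^2) px).
#'
#' @param view A [project_view()] annotation (or any list with
#'   `n_visible` and `r_mean_px`).
#' @param count_error An [error_model()]; default `error_model(-1.57, 1.9)`.
#' @param radius_bias_px,radius_sd_px Mean and sd of the radius error, px.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `view_estimate` with `view_index`, `n_est` and
#'   `r_mean_est_px`.
#' @export
emulate_detector <- function(view, count_error = error_model(-1.57, 1.9),
                             radius_bias_px = 0.15, radius_sd_px = 1.5,
                             seed = NULL) {
  stopifnot(inherits(count_error, "error_model"), radius_sd_px >= 0)
  gen <- function() {
    n_est <- max(0L, view$n_visible +
                   as.integer(round(stats::rnorm(1, count_error$me,
                                                 count_error$sigma_e))))
    r_est <- view$r_mean_px + stats::rnorm(1, radius_bias_px, radius_sd_px)
    structure(list(view_index = view$view_index, n_est = n_est,
                   r_mean_est_px = r_est),
              class = "view_estimate")
  }
  if (is.null(seed)) gen() else local_seed(seed, gen())
}

#' End-to-end synthetic volume-recovery experiment
#'
#' Generates `n_bunches` synthetic bunches, splits them into a calibration
#' subset (used only to estimate the occlusion ratio `R` and the
#' visible-volume estimator uncertainty) and a disjoint test subset, runs
#' the full estimation chain on every test view — detector emulation,
#' estimated visible pixel volume, metric conversion, `R` correction —
#' propagates the uncertainty budget, and compares each estimated bunch
#' volume against the scene's true volume with a coverage-factor-`k`
#' compatibility check.
#'
#' `R` is defined against the same mean-radius visible-volume formulation
#' the estimator produces, so with `exact = TRUE` (no detector noise, no
#' distance jitter, each view corrected by its own true ratio) the chain
#' is exactly invertible and recovers every bunch volume to numerical
#' precision.
#'
#' The synthetic bench mirrors the controlled acquisition it emulates:
#' every bunch is imaged at exactly the nominal distance `d`, and the
#' camera's `sigma_d` and `sigma_f` enter the uncertainty budget as
#' type-B allowances for in-field placement and calibration error (so
#' the compatibility check is conservative on the bench, as it is in the
#' field study).
#'
#' @param n_bunches Number of synthetic bunches (>= 2 unless `exact`).
#' @param params A [synthetic_bunch_params()].
#' @param camera A [camera_model()].
#' @param count_error,radius_bias_px,radius_sd_px Detector error model,
#'   as in [emulate_detector()]; ignored when `exact = TRUE`.
#' @param calib_fraction Fraction of bunches reserved for estimating `R`
#'   (default 0.3; at least one bunch).
#' @param occlusion_threshold Passed to [project_view()].
#' @param k Coverage factor of the compatibility check.
#' @param exact Run the noiseless identity configuration.
#' @param seed Integer seed controlling the whole experiment.
#' @return A list of class `recovery_report`: `views` (one row per test
#'   view: ids, estimated and true volumes, error, combined sigma,
#'   compatibility), `coverage` (fraction compatible), `volume_me` with
#'   its Monte Carlo standard error `volume_me_se` (mm^3; bunch-level
#'   clustering plus the shared calibration-ratio error), `volume_mpe`
#'   (percent), `mean_cov` (mean per-bunch coefficient
#'   of variability, percent), `r_hat` (the [ratio_R()] estimate),
#'   `sigma_v_px` (estimator uncertainty), and the configuration.
#' @export
run_recovery_experiment <- function(n_bunches = 200L,
                                    params = synthetic_bunch_params(),
                                    camera = synthetic_camera(),
                                    count_error = error_model(-1.57, 1.9),
                                    radius_bias_px = 0.15,
                                    radius_sd_px = 1.5,
                                    calib_fraction = 0.3,
                                    occlusion_threshold = 0.75,
                                    k = 2, exact = FALSE, seed = 1L) {
  if (n_bunches < 1L) stop("'n_bunches' must be >= 1")
  local_seed(seed, {
    c_nom <- px_to_mm_factor(camera)            # nominal d/f with sigma

    n_cal <- if (exact) 0L
             else max(1L, as.integer(round(calib_fraction * n_bunches)))
    if (!exact && n_cal >= n_bunches)
      stop("calibration subset would leave no test bunches; ",
           "lower 'calib_fraction' or raise 'n_bunches'")

    scenes <- lapply(seq_len(n_bunches), function(i)
      generate_bunch(params, camera, seed = NULL))
    views <- lapply(scenes, function(s)
      lapply(1:3, function(v) project_view(s, v, occlusion_threshold)))

    view_row <- function(b, v) {
      vw <- views[[b]][[v]]
      list(vw = vw, r_mean_px = vw$r_mean_px, radii_px = vw$radii_px)
    }

    if (exact) {
      rows <- do.call(rbind, lapply(seq_len(n_bunches), function(b)
        do.call(rbind, lapply(1:3, function(v) {
          vr <- view_row(b, v)
          vw <- vr$vw
          v_est_px <- visible_volume_estimated(vw$n_visible, vr$r_mean_px)
          r_k <- vw$true_R_mean_radius
          v_est <- total_volume_estimated(v_est_px, c_nom$value, r_k)
          data.frame(bunch = b, view = v,
                     v_est_mm = as.numeric(v_est),
                     v_true_mm = vw$v_total_mm,
                     error_mm = as.numeric(v_est) - vw$v_total_mm,
                     sigma_mm = 0,
                     compatible = abs(as.numeric(v_est) - vw$v_total_mm) <=
                       1e-9 * vw$v_total_mm)
        }))))
      r_hat <- NULL; sigma_v <- quantity(NA_real_, 0, "px3")
    } else {
      cal_idx <- seq_len(n_cal)
      test_idx <- setdiff(seq_len(n_bunches), cal_idx)

      # R from the calibration subset, against the mean-radius visible volume
      cal_pairs <- do.call(rbind, lapply(cal_idx, function(b)
        do.call(rbind, lapply(1:3, function(v) {
          vw <- views[[b]][[v]]
          c(b, vw$v_total_mm,
            vw$n_visible * sphere_volume(mean(vw$radii_mm)))
        }))))
      r_hat <- ratio_R(cal_pairs[, 2], cal_pairs[, 3])
      # standard error of r_hat treating each bunch (3 correlated views)
      # as one cluster
      scene_ratio <- vapply(split(cal_pairs[, 2] / cal_pairs[, 3],
                                  cal_pairs[, 1]), mean, numeric(1))
      r_hat_se <- if (length(scene_ratio) >= 2L)
        stats::sd(scene_ratio) / sqrt(length(scene_ratio)) else 0

      # estimator uncertainty from detector residuals on the calibration set
      cal_est <- t(vapply(cal_idx, function(b) {
        vapply(1:3, function(v) {
          vr <- view_row(b, v)
          est <- emulate_detector(list(view_index = v,
                                       n_visible = vr$vw$n_visible,
                                       r_mean_px = vr$r_mean_px),
                                  count_error, radius_bias_px, radius_sd_px)
          as.numeric(visible_volume_estimated(
            est$n_est, max(est$r_mean_est_px, 1e-6)))
        }, numeric(1))
      }, numeric(3)))
      cal_ref <- t(vapply(cal_idx, function(b) {
        vapply(1:3, function(v)
          as.numeric(visible_volume_reference(view_row(b, v)$radii_px)),
          numeric(1))
      }, numeric(3)))
      sigma_v <- estimator_rmse_sigma(as.numeric(cal_est),
                                      as.numeric(cal_ref), "px3")

      rows <- do.call(rbind, lapply(test_idx, function(b)
        do.call(rbind, lapply(1:3, function(v) {
          vr <- view_row(b, v)
          vw <- vr$vw
          est <- emulate_detector(list(view_index = v,
                                       n_visible = vw$n_visible,
                                       r_mean_px = vr$r_mean_px),
                                  count_error, radius_bias_px, radius_sd_px)
          v_est_px <- visible_volume_estimated(est$n_est,
                                               max(est$r_mean_est_px, 1e-6))
          v_est <- total_volume_estimated(v_est_px, c_nom$value, r_hat)
          budget <- propagate_power_product(volume_uncertainty_sources(
            v_visible_px = max(as.numeric(v_est_px), 1),
            sigma_v = sigma_v$sigma,
            d = camera$d, sigma_d = camera$sigma_d,
            f = camera$f, sigma_f = camera$sigma_f,
            r = r_hat$r_mean, sigma_r = r_hat$r_sigma))
          sig <- budget$combined_sigma
          data.frame(bunch = b, view = v,
                     v_est_mm = as.numeric(v_est),
                     v_true_mm = vw$v_total_mm,
                     error_mm = as.numeric(v_est) - vw$v_total_mm,
                     sigma_mm = sig,
                     compatible = compatibility_check(
                       as.numeric(v_est) - vw$v_total_mm, sig, k))
        }))))
    }

    rownames(rows) <- NULL
    per_bunch_cov <- vapply(split(rows$v_est_mm, rows$bunch),
                            function(x) if (length(x) >= 2L && mean(x) != 0)
                              coefficient_of_variability(x) else NA_real_,
                            numeric(1))
    # Monte Carlo standard error of the mean volume error: bunch-level
    # clustering (the 3 views of a bunch share its geometry) plus the
    # shared error of the calibration ratio r_hat
    bunch_err <- vapply(split(rows$error_mm, rows$bunch), mean, numeric(1))
    me_se <- stats::sd(bunch_err) / sqrt(length(bunch_err))
    if (!exact && r_hat_se > 0)
      me_se <- sqrt(me_se^2 +
                    (mean(rows$v_est_mm) / r_hat$r_mean * r_hat_se)^2)
    structure(list(views = rows,
                   coverage = mean(rows$compatible),
                   volume_me = mean_error(rows$v_est_mm, rows$v_true_mm),
                   volume_me_se = me_se,
                   volume_mpe = mean_percentage_error(rows$v_est_mm,
                                                      rows$v_true_mm),
                   mean_cov = mean(per_bunch_cov, na.rm = TRUE),
                   r_hat = r_hat, sigma_v_px = sigma_v,
                   n_bunches = n_bunches, n_calibration = n_cal,
                   k = k, exact = exact, seed = seed,
                   params = params, camera = camera),
              class = "recovery_report")
  })
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "synthetic recovery: %d bunches (%d calibration), %d test views\n",
    x$n_bunches, x$n_calibration, nrow(x$views)))
  cat(sprintf("  volume ME  = %.4g +/- %.4g mm^3 (SE), MPE = %.3g%%\n",
              x$volume_me, x$volume_me_se, x$volume_mpe))
  cat(sprintf("  coverage (k = %g): %.1f%% compatible, mean CoV %.3g%%\n",
              x$k, 100 * x$coverage, x$mean_cov))
  if (!is.null(x$r_hat))
    cat(sprintf("  R = %.3g +/- %.3g, sigma_V~ = %.4g px^3\n",
                x$r_hat$r_mean, x$r_hat$r_sigma, x$sigma_v_px$sigma))
  invisible(x)
}
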