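# Synthetic scene generator, occlusion projection, detector emulator.

test_that("scenes are reproducible from their seed", {
  s1 <- generate_bunch(seed = 123)
  s2 <- generate_bunch(seed = 123)
  expect_identical(s1$centers, s2$centers)
  expect_identical(s1$radii_mm, s2$radii_mm)
  v1 <- project_view(s1, 2)
  v2 <- project_view(s2, 2)
  expect_identical(v1$visible, v2$visible)
  expect_identical(v1$r_mean_px, v2$r_mean_px)
  # a different seed gives a different scene
  expect_false(identical(generate_bunch(seed = 124)$radii_mm, s1$radii_mm))
})

test_that("a single-berry bunch is fully visible with R = 1 in every view", {
  p <- synthetic_bunch_params(n_berries_range = c(1L, 1L))
  s <- generate_bunch(p, seed = 5)
  expect_identical(nrow(s$centers), 1L)
  for (v in 1:3) {
    vw <- project_view(s, v)
    expect_identical(vw$n_visible, 1L)
    expect_equal(vw$true_R, 1)
    expect_equal(vw$true_R_mean_radius, 1)
    # weak perspective: r_px = r_mm * f / d exactly
    expect_equal(vw$r_mean_px,
                 s$radii_mm[1] * s$camera$f / s$camera$d)
  }
})

test_that("a berry exactly behind a larger one is always occluded", {
  s <- concentric_scene(r_near = 5, r_far = 4)
  for (thr in c(0.25, 0.5, 1)) {
    vw <- project_view(s, 1, occlusion_threshold = thr)
    expect_identical(vw$visible, 1L)
    expect_identical(vw$n_visible, 1L)
  }
  expect_gt(project_view(s, 1)$true_R, 1)
})

test_that("berry packing respects the overlap tolerance and envelope", {
  p <- synthetic_bunch_params()
  for (seed in c(11, 222)) {
    s <- generate_bunch(p, seed = seed)
    r <- s$radii_mm
    d <- as.matrix(stats::dist(s$centers))
    lim <- (1 - p$overlap_tol) * outer(r, r, `+`)
    diag(d) <- Inf
    expect_true(all(d >= lim - 1e-9))
    inside <- rowSums((s$centers / rep(p$envelope_mm,
                                       each = nrow(s$centers)))^2)
    expect_true(all(inside <= 1 + 1e-9))
  }
  expect_error(
    generate_bunch(synthetic_bunch_params(envelope_mm = c(12, 12, 20),
                                          n_berries_range = c(40L, 40L),
                                          max_attempts = 50L), seed = 1),
    "packing failed")
})

test_that("berry counts and radii follow the configured distributions", {
  p <- synthetic_bunch_params()
  scenes <- lapply(1:150, function(i) generate_bunch(p, seed = 4000 + i))
  m <- vapply(scenes, function(s) nrow(s$centers), integer(1))
  # uniform over 36..76: mean 56, sd sqrt((41^2 - 1)/12)
  se_m <- sqrt((41^2 - 1) / 12) / sqrt(length(m))
  expect_lt(abs(mean(m) - 56), 3 * se_m)
  expect_true(all(m >= 36 & m <= 76))

  radii <- unlist(lapply(scenes, `[[`, "radii_mm"))
  mom <- truncnorm3_moments(p$r_mean_mm, p$r_sd_mm)
  expect_lt(abs(mean(radii) - mom$mean), 3 * mom$sd / sqrt(length(radii)))
  expect_lt(abs(stats::sd(radii) - mom$sd),
            3 * mom$sd / sqrt(2 * length(radii)))
  expect_true(all(abs(radii - p$r_mean_mm) <= 3 * p$r_sd_mm))
})

test_that("visibility is monotone in the occlusion threshold", {
  for (seed in c(31, 77)) {
    s <- generate_bunch(seed = seed)
    for (v in 1:3) {
      n_vis <- vapply(c(0.2, 0.5, 0.75, 1),
                      function(t) project_view(s, v, t)$n_visible,
                      integer(1))
      expect_true(all(diff(n_vis) >= 0))
    }
  }
})

test_that("per-view ratios sit in the generator's regression band", {
  stats <- do.call(rbind, lapply(1:40, function(i) {
    s <- generate_bunch(seed = 6000 + i)
    t(vapply(1:3, function(v) {
      vw <- project_view(s, v)
      c(R = vw$true_R, frac = vw$n_visible / nrow(s$centers))
    }, numeric(2)))
  }))
  expect_true(all(stats[, "R"] >= 1))
  expect_gt(mean(stats[, "R"]), 1.3)
  expect_lt(mean(stats[, "R"]), 1.7)
  # spread of the per-view ratio: same order as the field study's 0.32
  expect_gt(stats::sd(stats[, "R"]), 0.1)
  expect_lt(stats::sd(stats[, "R"]), 0.35)
  # visible fraction comparable to the reference tables (~0.5-0.8)
  expect_gt(mean(stats[, "frac"]), 0.5)
  expect_lt(mean(stats[, "frac"]), 0.8)
})

test_that("ratio_R recovers the generator's mean ratio", {
  pairs <- do.call(rbind, lapply(1:40, function(i) {
    s <- generate_bunch(seed = 6000 + i)   # same scenes as the band test
    t(vapply(1:3, function(v) {
      vw <- project_view(s, v)
      c(vw$v_total_mm, vw$v_visible_mm)
    }, numeric(2)))
  }))
  est <- ratio_R(pairs[, 1], pairs[, 2])
  truth <- mean(pairs[, 1] / pairs[, 2])
  expect_equal(est$r_mean, truth)               # same definition
  expect_lt(abs(est$r_mean - truth), 3 * est$r_sigma / sqrt(est$n_images))
})

test_that("the detector emulator reduces to identity without noise", {
  s <- generate_bunch(seed = 9)
  vw <- project_view(s, 1)
  e0 <- emulate_detector(vw, error_model(0, 0), 0, 0)
  expect_identical(e0$n_est, vw$n_visible)
  expect_identical(e0$r_mean_est_px, vw$r_mean_px)

  em2 <- emulate_detector(vw, error_model(-2, 0), 0, 0)
  expect_identical(em2$n_est, vw$n_visible - 2L)

  # reproducible from seed
  ea <- emulate_detector(vw, seed = 42)
  eb <- emulate_detector(vw, seed = 42)
  expect_identical(ea$n_est, eb$n_est)
  expect_identical(ea$r_mean_est_px, eb$r_mean_est_px)
})

test_that("emulated errors follow the configured laws", {
  vw <- list(view_index = 1L, n_visible = 30L, r_mean_px = 22)
  n <- 3000
  draws <- withr::with_seed(8, lapply(seq_len(n), function(i)
    emulate_detector(vw, error_model(-1.57, 1.9), 0.15, 1.5)))
  ce <- vapply(draws, function(d) d$n_est - vw$n_visible, numeric(1))
  re <- vapply(draws, function(d) d$r_mean_est_px - vw$r_mean_px, numeric(1))
  expect_lt(abs(mean(ce) + 1.57), 3 * 1.9 / sqrt(n))
  # rounding to integer counts adds 1/12 to the variance
  expect_lt(abs(stats::sd(ce) - sqrt(1.9^2 + 1 / 12)),
            3 * 1.9 / sqrt(2 * n))
  expect_lt(abs(mean(re) - 0.15), 3 * 1.5 / sqrt(n))
  expect_lt(abs(stats::sd(re) - 1.5), 3 * 1.5 / sqrt(2 * n))
})

test_that("the recovery experiment report is internally consistent", {
  r <- run_recovery_experiment(n_bunches = 30, seed = 17)
  expect_identical(nrow(r$views), 3L * (30L - r$n_calibration))
  expect_equal(r$coverage, mean(r$views$compatible))
  expect_equal(r$volume_me, mean(r$views$error_mm))
  expect_true(all(r$views$sigma_mm > 0))
  expect_gt(r$r_hat$r_mean, 1)
  # reproducibility end-to-end
  r2 <- run_recovery_experiment(n_bunches = 30, seed = 17)
  expect_identical(r$views$v_est_mm, r2$views$v_est_mm)
})
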