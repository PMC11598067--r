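# GUM power-product budgets, sphere-sum sensitivities, and the Monte Carlo
# cross-check.

test_that("single-source budgets are identities", {
  s <- uncertainty_sources("x", 10, 1, 1)
  b <- propagate_power_product(s)
  expect_equal(b$rel_sigma, 0.1)
  expect_equal(unname(b$upc), 100)
  expect_equal(b$value, 10)
})

test_that("the volume-chain budget matches its frozen Monte Carlo values", {
  # frozen against a 1e6-draw Monte Carlo oracle (UPCs agree to < 1 point)
  s <- volume_uncertainty_sources(1e6, 2.8e5, 500, 25, 1000, 2, 1.8, 0.32)
  b <- propagate_power_product(s)
  expect_equal(b$rel_sigma, 0.3640617, tolerance = 1e-6)
  expect_equal(unname(b$upc), c(59.15, 16.98, 0.03, 23.85), tolerance = 2e-3)
  expect_equal(sum(b$upc), 100)

  mc <- monte_carlo_budget(s, n_samples = 2e5, seed = 7)
  expect_equal(unname(mc$upc), unname(b$upc), tolerance = 0.02)
})

test_that("UPC sums to 100 and is invariant to unit rescaling", {
  for (seed in 1:15) {
    cfg <- withr::with_seed(seed, list(
      k = sample(2:6, 1),
      v = stats::runif(6, 0.5, 2000),
      s = stats::runif(6, 0, 0.2),
      p = sample(c(-3L, -1L, 1L, 2L, 3L), 6, replace = TRUE)))
    idx <- seq_len(cfg$k)
    src <- uncertainty_sources(letters[idx], cfg$v[idx],
                               cfg$s[idx] * cfg$v[idx], cfg$p[idx])
    b <- propagate_power_product(src)
    expect_true(all(b$upc >= 0))
    expect_equal(sum(b$upc), 100)

    # rescaling one source's unit (value and sigma together) changes nothing
    scl <- cfg$v[1]
    src2 <- src
    src2$value[1] <- src2$value[1] * scl
    src2$sigma[1] <- src2$sigma[1] * scl
    expect_equal(propagate_power_product(src2)$upc, b$upc)
    expect_equal(propagate_power_product(src2)$rel_sigma, b$rel_sigma)
  }
})

test_that("linear budget matches Monte Carlo within 2% at small sigmas", {
  for (seed in 1:3) {
    cfg <- withr::with_seed(seed, list(
      v = stats::runif(3, 1, 100),
      rel = stats::runif(3, 0.005, 0.05),
      p = sample(c(-3L, 1L, 3L), 3)))
    src <- uncertainty_sources(c("a", "b", "c"), cfg$v, cfg$rel * cfg$v,
                               cfg$p)
    lin <- propagate_power_product(src)
    mc <- monte_carlo_budget(src, n_samples = 1e5, seed = seed + 50)
    expect_equal(mc$rel_sigma, lin$rel_sigma, tolerance = 0.02)
  }
})

test_that("Monte Carlo budget is deterministic in its seed and detects zero spread", {
  src <- uncertainty_sources(c("a", "b"), c(2, 3), c(0.1, 0.2), c(1L, -1L))
  m1 <- monte_carlo_budget(src, 1e4, seed = 5)
  m2 <- monte_carlo_budget(src, 1e4, seed = 5)
  expect_identical(m1$combined_sigma, m2$combined_sigma)

  z <- monte_carlo_budget(uncertainty_sources("a", 2, 0, 1L), 1e4, seed = 1)
  expect_identical(z$combined_sigma, 0)
})

test_that("sphere-sum sensitivity matches the analytic derivative", {
  q <- propagate_sphere_sum(25, 1 / sqrt(3), "px3")
  expect_equal(q$sigma, 4 * pi * 625 / sqrt(3), tolerance = 1e-12)
  expect_equal(q$sigma, 4534.498, tolerance = 1e-6)

  # finite-difference check of the 4*pi*r^2 sensitivity
  h <- 1e-6
  fd <- (sphere_volume(25 + h) - sphere_volume(25 - h)) / (2 * h)
  expect_equal(q$sigma, fd / sqrt(3), tolerance = 1e-6)

  # N identical berries: sigma scales as sqrt(N)
  qn <- propagate_sphere_sum(rep(25, 9), 1 / sqrt(3), "px3")
  expect_equal(qn$sigma, 3 * q$sigma)
  expect_error(propagate_sphere_sum(numeric(0), 0.5), "empty")
})

test_that("reference-volume uncertainty over the packaged views is near the study value", {
  views <- load_table1()$views
  sig <- vapply(seq_len(nrow(views)), function(i)
    propagate_sphere_sum(rep(views$r_mean_px[i], views$n_visible[i]),
                         type_b_uniform_sigma(1, "px")$sigma, "px3")$sigma,
    numeric(1))
  expect_equal(mean(sig), 18921.64, tolerance = 1e-5)  # ~5% above 1.8e4
})

test_that("estimator RMSE and compatibility behave as defined", {
  expect_identical(estimator_rmse_sigma(c(1, 2), c(1, 2))$sigma, 0)
  expect_equal(estimator_rmse_sigma(c(-3, 4), c(0, 0))$sigma, 3.5355,
               tolerance = 1e-4)
  expect_error(estimator_rmse_sigma(1:3, 1:2), "same length")

  expect_true(compatibility_check(0, 1))
  expect_false(compatibility_check(3, 1, k = 2))
  expect_equal(compatibility_check(c(-1.9, 2.1), 1, k = 2), c(TRUE, FALSE))
  expect_error(compatibility_check(1, 0), "> 0")
})
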