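# Independent oracles and small generators used across the test files.

# two-pass coefficient of variability, independent of the package's one-liner
cov_two_pass <- function(x) {
  m <- sum(x) / length(x)
  dev2 <- sum((x - m)^2) / (length(x) - 1)
  100 * sqrt(dev2) / m
}

# Monte Carlo oracle for the extrapolated metrics: empirical ME/MAE/RMSE of
# sums of b iid N(me, sigma^2) draws, with standard errors of each estimate
mc_extrapolated <- function(me, sigma, b, n = 1e5, seed = 1) {
  withr::with_seed(seed, {
    x <- rowSums(matrix(stats::rnorm(n * b, me, sigma), nrow = n))
    list(me = mean(x), me_se = stats::sd(x) / sqrt(n),
         mae = mean(abs(x)), mae_se = stats::sd(abs(x)) / sqrt(n),
         rmse = sqrt(mean(x^2)),
         rmse_se = stats::sd(x^2) / (2 * sqrt(mean(x^2)) * sqrt(n)))
  })
}

# moments of a normal truncated to mean +/- 3 sd (the generator's radius law)
truncnorm3_moments <- function(mean, sd) {
  z <- 3
  sd_t <- sd * sqrt(1 - 2 * z * stats::dnorm(z) / (2 * stats::pnorm(z) - 1))
  list(mean = mean, sd = sd_t)
}

# hand-built two-berry scene: a small berry exactly behind a larger one
concentric_scene <- function(r_near = 5, r_far = 4) {
  structure(list(
    centers = rbind(c(0, 0, 0), c(0, 2 * r_near, 0)),
    radii_mm = c(r_near, r_far),
    camera = synthetic_camera(),
    params = synthetic_bunch_params(n_berries_range = c(2L, 2L)),
    seed = NULL), class = "synthetic_scene")
}

random_paired_series <- function(k, seed) {
  withr::with_seed(seed, {
    ref <- stats::runif(k, 10, 60)
    list(est = ref + stats::rnorm(k, 0, 5), ref = ref)
  })
}
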