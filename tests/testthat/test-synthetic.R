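test_that("generators are pure functions of parameters and seed", {
  expect_identical(gen_lognormal(0.26, 3.3, 100, seed = 5),
                   gen_lognormal(0.26, 3.3, 100, seed = 5))
  expect_false(identical(gen_lognormal(0.26, 3.3, 100, seed = 5),
                         gen_lognormal(0.26, 3.3, 100, seed = 6)))
  expect_identical(gen_powerlaw(0.25, 1.67, 100, seed = 5),
                   gen_powerlaw(0.25, 1.67, 100, seed = 5))
  expect_identical(gen_spliced(0.26, 3.3, 0.25, 1.67, 100, seed = 5)$values,
                   gen_spliced(0.26, 3.3, 0.25, 1.67, 100, seed = 5)$values)
  g1 <- gen_crack_image(c(40, 60), c(64, 64), seed = 5)
  g2 <- gen_crack_image(c(40, 60), c(64, 64), seed = 5)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(gen_force_curve(10, 2, 2, noise_sd = 0.2, seed = 5),
                   gen_force_curve(10, 2, 2, noise_sd = 0.2, seed = 5))
  # the generator leaves the caller's RNG stream untouched
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_lognormal(0.26, 3.3, 10, seed = 1))
  expect_identical(runif(1), before)
})

test_that("gen_lognormal matches its distributional parameters", {
  # degenerate limit sigma_star -> 1+: all values collapse to mu_star
  x <- gen_lognormal(0.26, 1 + 1e-9, 100, seed = 1)
  expect_equal(x, rep(0.26, 100), tolerance = 1e-6)
  # CLT bound on the geometric mean, log scale
  x <- gen_lognormal(0.26, 3.3, 4000, seed = 2)
  expect_lt(abs(mean(log(x)) - log(0.26)), 3 * log(3.3) / sqrt(4000))
  expect_error(gen_lognormal(-1, 3.3, 10, seed = 1), "positive")
  expect_error(gen_lognormal(0.26, 0.9, 10, seed = 1), "exceed 1")
})

test_that("gen_powerlaw draws from the Pareto inverse CDF", {
  x <- gen_powerlaw(0.25, 1.67, 2000, seed = 3)
  expect_true(all(x >= 0.25))
  # alpha = 2, xmin = 1: closed-form median is 2
  y <- gen_powerlaw(1, 2, 10001, seed = 4)
  expect_lt(abs(stats::median(y) - 2), 0.15)   # binomial error at n = 10001
  expect_error(gen_powerlaw(0, 1.67, 10, seed = 1), "positive")
  expect_error(gen_powerlaw(0.25, 1, 10, seed = 1), "exceed 1")
})

test_that("gen_spliced spans the pure-body and pure-tail limits", {
  tail_only <- gen_spliced(0.26, 3.3, 0.25, 1.67, 500, seed = 5,
                           tail_fraction = 1)
  expect_true(all(tail_only$values >= 0.25))
  body_only <- gen_spliced(0.26, 3.3, 0.25, 1.67, 500, seed = 5,
                           tail_fraction = 0)
  expect_true(all(body_only$values < 0.25))
  expect_error(gen_spliced(0.26, 3.3, 0.25, 1.67, 10, seed = 1,
                           tail_fraction = 1.5), "\\[0, 1\\]")
})

test_that("gen_spliced truth moments match numerical integration and the sample", {
  s <- gen_spliced(0.26, 3.3, 0.25, 1.67, n = 4000, seed = 6)
  tr <- s$truth
  # independent check of the closed-form ln X moments by quadrature
  mu <- log(0.26); sg <- log(3.3); a <- log(0.25); q <- tr$tail_fraction
  body_dens <- function(t) dnorm(t, mu, sg) / pnorm((a - mu) / sg)
  tail_dens <- function(t) (1.67 - 1) * exp(-(1.67 - 1) * (t - a))
  m1 <- (1 - q) * stats::integrate(function(t) t * body_dens(t), -Inf, a,
                                   rel.tol = 1e-10)$value +
    q * stats::integrate(function(t) t * tail_dens(t), a, Inf,
                         rel.tol = 1e-10)$value
  m2 <- (1 - q) * stats::integrate(function(t) t^2 * body_dens(t), -Inf, a,
                                   rel.tol = 1e-10)$value +
    q * stats::integrate(function(t) t^2 * tail_dens(t), a, Inf,
                         rel.tol = 1e-10)$value
  expect_equal(tr$log_mean, m1, tolerance = 1e-7)
  expect_equal(tr$log_sd, sqrt(m2 - m1^2), tolerance = 1e-7)
  expect_equal(tr$geo_mean, exp(m1), tolerance = 1e-7)
  # the sample's log-mean concentrates on the population value
  expect_lt(abs(mean(log(s$values)) - tr$log_mean),
            3 * tr$log_sd / sqrt(4000))
})

test_that("spliced truth records round-trip through the tail fit", {
  s <- gen_spliced(0.26, 3.3, 0.25, 1.67, n = 5000, seed = 8)
  f <- fit_powerlaw_tail(s$values)
  expect_lt(abs(f$alpha - 1.67), 3 * (1.67 - 1) / sqrt(f$n_tail))
  ln <- fit_lognormal(s$values)
  expect_lt(abs(log(ln$mu_star) - s$truth$log_mean),
            3 * s$truth$log_sd / sqrt(5000))
})

test_that("gen_crack_image places exact areas with enforced separation", {
  areas <- c(100, 9, 50, 200, 1)
  g <- gen_crack_image(areas, canvas_shape = c(96, 96), seed = 9)
  expect_identical(g$areas_px, as.integer(areas))
  # component areas in the ground-truth mask are exactly as requested
  ps <- label_particles(g$mask, pixel_pitch_um = 63.5)
  expect_equal(sort(ps$particles$area_px), sort(as.integer(areas)))
  # pairwise boundary separation > 2 px (Chebyshev)
  ids <- seq_along(areas)
  for (i in ids) for (j in ids[ids > i]) {
    expect_gt(oracle_min_cheb_dist(g$labels, i, j), 2)
  }
  # empty request yields a blank mask
  blank <- gen_crack_image(integer(0), c(32, 32), seed = 1)
  expect_equal(sum(blank$mask$pixels), 0)
  # infeasible packings are rejected
  expect_error(gen_crack_image(2000, c(32, 32), seed = 1), "infeasible")
  expect_error(gen_crack_image(c(10, 0), c(32, 32), seed = 1), ">= 1 px")
})

test_that("segmentation recovers generated blobs end to end", {
  areas <- c(60, 25, 120, 40, 9, 300)
  g <- gen_crack_image(areas, canvas_shape = c(128, 128), seed = 10)
  ps <- segment_cracks(g$image, min_size_px = 2, image_id = "synthetic")
  expect_equal(nrow(ps$particles), length(areas))
  got <- sort(ps$particles$area_px)
  want <- sort(areas)
  expect_true(all(abs(got - want) / want <= 0.05))
})

test_that("gen_force_curve round-trips exactly without noise", {
  cv <- gen_force_curve(10, 2, 2, noise_sd = 0)
  ft <- extract_features(cv, contact_threshold_N = 0)
  expect_equal(ft$hardness_N, 10)
  expect_equal(ft$crust_thickness_mm, 2)
  # WOD against the closed-form integral of the generator's shape
  wod_exact <- 2 * (20 - 2) + (10 - 2) * 0.5 * (1 - exp(-(20 - 2) / 0.5))
  expect_equal(ft$wod_Nmm, wod_exact, tolerance = 0.005 * wod_exact)
  expect_error(gen_force_curve(10, 25, 2), "thickness < travel")
  expect_error(gen_force_curve(10, 2, 12), "plateau_force < hardness")
})

test_that("noisy force curves recover location and integral features", {
  # 5% additive noise: thickness and WOD mean-recover within 2%; hardness,
  # a sampled maximum, carries an upward extreme-value bias and is only
  # bounded within 10% per seed (see the methods vignette).
  res <- t(vapply(1:50, function(s) {
    cv <- gen_force_curve(10, 2, 2, noise_sd = 0.5, seed = s)
    ft <- extract_features(cv, contact_threshold_N = 0)
    c(h = ft$hardness_N, th = ft$crust_thickness_mm, w = ft$wod_Nmm)
  }, numeric(3)))
  wod_true <- 2 * 18 + 8 * 0.5 * (1 - exp(-36))
  expect_lt(abs(mean(res[, "th"]) - 2) / 2, 0.02)
  expect_lt(abs(mean(res[, "w"]) - wod_true) / wod_true, 0.02)
  expect_true(all(abs(res[, "h"] - 10) / 10 < 0.15))
  expect_gt(mean(res[, "h"]), 10)   # the bias is systematically upward
})
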