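test_that("empirical_ccdf counts exceedance fractions", {
  cc <- empirical_ccdf(c(1, 2, 3))
  expect_equal(cc$xs, c(1, 2, 3))
  expect_equal(cc$gs, c(1, 2 / 3, 1 / 3))
  expect_equal(empirical_ccdf(5)$gs, 1)
  expect_error(empirical_ccdf(c(1, -2)), "positive")
  expect_error(empirical_ccdf(c(1, 0)), "positive")
})

test_that("empirical_ccdf is non-increasing, starts at 1, matches the O(n^2) oracle", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, round(exp(rnorm(60)), 2))
    x <- x[x > 0]
    cc <- empirical_ccdf(x)
    expect_equal(cc$gs[1], 1)
    expect_true(all(diff(cc$gs) <= 0))
    expect_true(all(cc$gs > 0 & cc$gs <= 1))
    orc <- oracle_ccdf(x)
    expect_equal(cc$xs, orc$xs)
    expect_equal(cc$gs, orc$gs)
  }
})

test_that("fit_lognormal computes MLE and back-transformed parameters", {
  f <- fit_lognormal(c(exp(-1), exp(1)))
  expect_equal(f$mu, 0)
  expect_equal(f$sigma, 1)          # divide-by-n MLE
  expect_equal(f$mu_star, 1)
  expect_equal(f$sigma_star, exp(1))
  expect_false(f$degenerate)
  # divide-by-(n-1) option
  fu <- fit_lognormal(c(exp(-1), exp(1)), unbiased_sigma = TRUE)
  expect_equal(fu$sigma, sqrt(2))
  # degenerate sample
  fd <- fit_lognormal(c(1, 1, 1))
  expect_true(fd$degenerate)
  expect_equal(fd$mu_star, 1)
  expect_equal(fd$sigma_star, 1)
  expect_true(is.na(fd$ks_D))
})

test_that("fit_lognormal mu_star is the geometric mean with scale equivariance", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, exp(rnorm(100, 0.5, 1.2)))
    f <- fit_lognormal(x)
    expect_equal(f$mu_star, exp(mean(log(x))))
    expect_true(f$sigma_star >= 1)
    # permutation invariance
    fp <- fit_lognormal(rev(sort(x)))
    expect_equal(fp$mu_star, f$mu_star)
    expect_equal(fp$sigma, f$sigma)
    # scaling by s multiplies mu_star by s, leaves sigma_star unchanged
    fs <- fit_lognormal(3.7 * x)
    expect_equal(fs$mu_star, 3.7 * f$mu_star)
    expect_equal(fs$sigma_star, f$sigma_star)
  }
})

test_that("fit_lognormal recovers generator parameters on large samples", {
  mu_star <- 0.26
  sigma_star <- 3.3
  x <- gen_lognormal(mu_star, sigma_star, n = 1e4, seed = 99)
  f <- fit_lognormal(x)
  se <- log(sigma_star) / sqrt(1e4)
  expect_lt(abs(f$mu - log(mu_star)), 3 * se)
  expect_lt(abs(f$sigma - log(sigma_star)), 3 * se)
  expect_true(f$params_estimated)
  expect_true(f$ks_D < 0.02)        # correct model, large n
})

test_that("ks_statistic equals the two-sided step-function distance", {
  # model equal to the empirical step at its own points: D <= 1/n
  x <- c(1, 2, 3, 4)
  step_cdf <- function(q) vapply(q, function(v) mean(x <= v), numeric(1))
  expect_lte(ks_statistic(x, step_cdf), 1 / length(x))
  # single point with model CDF 0.5 there
  expect_equal(ks_statistic(2, function(q) rep(0.5, length(q))), 0.5)
  # brute-force oracle agreement, with and without a tail threshold
  for (seed in 1:4) {
    y <- withr::with_seed(seed, exp(rnorm(50)))
    cdf <- function(q) plnorm(q, 0.2, 0.9)
    expect_equal(ks_statistic(y, cdf), oracle_ks(y, cdf))
    xmin <- stats::median(y)
    tail_cdf <- function(q) 1 - (q / xmin)^(-1)
    expect_equal(ks_statistic(y, tail_cdf, xmin = xmin),
                 oracle_ks(y, tail_cdf, xmin = xmin))
  }
  expect_error(ks_statistic(c(1, 2), function(q) q, xmin = 10), "empty tail")
})

test_that("fit_powerlaw_tail reproduces the closed-form MLE on a fixed tail", {
  # {2,4,8} with the whole sample as tail: alpha = 1 + 3/(3 ln 2)
  f <- fit_powerlaw_tail(c(2, 4, 8), min_tail_size = 3)
  expect_equal(f$xmin, 2)
  expect_equal(f$alpha, 1 + 1 / log(2), tolerance = 1e-12)
  expect_equal(f$c, (f$alpha - 1) * 2^(f$alpha - 1))
  expect_error(fit_powerlaw_tail(c(2, 4, 8), min_tail_size = 10),
               "at least")
})

test_that("fit_powerlaw_tail recovers exact Pareto draws", {
  # for data that is power-law everywhere the KS distance is nearly flat
  # in xmin, so the threshold estimate is noisy while alpha is sharp:
  # alpha must recover on every seed, xmin lands in the lowest sample
  # decile in a majority of seeds
  hits <- vapply(1:20, function(s) {
    x <- gen_powerlaw(xmin = 0.25, alpha = 1.67, n = 5000, seed = s)
    f <- fit_powerlaw_tail(x)
    expect_gt(f$alpha, 1)
    expect_true(f$D >= 0 && f$D <= 1)
    expect_lt(abs(f$alpha - 1.67), 3 * (1.67 - 1) / sqrt(f$n_tail))
    f$xmin <= stats::quantile(x, 0.1)
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("xmin search agrees with the exhaustive candidate oracle", {
  for (seed in 1:3) {
    x <- round(gen_spliced(0.26, 3.3, 0.25, 1.67, n = 250,
                           seed = seed)$values, 4)
    f <- fit_powerlaw_tail(x)
    orc <- oracle_plfit(x)
    expect_equal(f$xmin, orc$xmin)
    expect_equal(f$alpha, orc$alpha)
    expect_equal(f$D, orc$D)
    expect_equal(f$n_tail, orc$n_tail)
  }
})

test_that("fitted power-law density integrates to one over the tail", {
  for (seed in 4:6) {
    x <- gen_powerlaw(0.25, 1.67, n = 400, seed = seed)
    f <- fit_powerlaw_tail(x)
    mass <- stats::integrate(function(v) f$c * v^(-f$alpha), f$xmin, Inf,
                             rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("critical_D follows the asymptotic table and acceptance rule", {
  expect_equal(critical_D(100), 0.136)
  expect_equal(critical_D(400), 0.068)
  expect_true(0.06 < critical_D(400))          # D = 0.06 passes at n = 400
  expect_equal(critical_D(100, 0.10), 0.122)
  expect_equal(critical_D(100, 0.01), 0.163)
  expect_error(critical_D(100, 0.2), "unsupported")
  # n -> Inf drives the critical value to 0
  expect_lt(critical_D(1e8), 1e-3)
  # exact small-n overrides take precedence
  expect_equal(critical_D(5, table_override = c("5" = 0.563)), 0.563)
})

test_that("geometric k-sigma interval masses follow 2*Phi(k) - 1 for any parameters", {
  expect_equal(lognormal_interval_mass(0.26, 3.3, 1), 2 * pnorm(1) - 1)
  expect_equal(lognormal_interval_mass(0.26, 3.3, 2), 2 * pnorm(2) - 1)
  expect_equal(lognormal_interval_mass(0.26, 3.3, 3), 2 * pnorm(3) - 1)
  expect_equal(lognormal_interval_mass(0.26, 3.3, 0), 0)
  for (ms in c(0.01, 1, 250)) for (ss in c(1.1, 3.3, 8)) {
    expect_equal(lognormal_interval_mass(ms, ss, 1.7),
                 lognormal_interval_mass(0.26, 3.3, 1.7))
  }
  expect_error(lognormal_interval_mass(0.26, 0.9, 1), "exceed 1")
})

test_that("summarize_groups reproduces single reports and averages groups", {
  x1 <- gen_spliced(0.26, 3.3, 0.25, 1.67, n = 200, seed = 1)$values
  r1 <- fit_areas(x1, sample_id = "s1", group = "A")
  s1 <- summarize_groups(r1)
  expect_equal(nrow(s1$by_sample), 1)
  expect_equal(s1$by_group$mu_star, r1$lognormal$mu_star)
  expect_equal(s1$by_group$xmin, r1$powerlaw$xmin)
  expect_equal(s1$by_group$n_samples, 1)
  # two identical reports: mean equals the common value
  s2 <- summarize_groups(list(r1, r1))
  expect_equal(s2$by_group$alpha, r1$powerlaw$alpha)
  expect_equal(s2$by_group$n_samples, 2)
  # schema of the coefficient table
  expect_setequal(names(s2$by_sample),
                  c("sample_id", "group", "xmin", "alpha", "D", "mu_star",
                    "sigma_star", "total_area_mm2"))
  expect_equal(r1$total_area_mm2, sum(x1))
})
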