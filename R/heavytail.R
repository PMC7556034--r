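# Heavy-tailed size-distribution modeling of crack areas: empirical CCDF,
# log-normal fit with back-transformed (geometric) parameters, power-law
# tail fit with KS-minimizing threshold selection, and critical-value
# testing of the KS distance.

check_area_sample <- function(values, n_min = 1L) {
  if (!is.numeric(values) || length(values) < n_min) {
    stop(sprintf("sample must be numeric with at least %d value(s)", n_min),
         call. = FALSE)
  }
  if (anyNA(values) || any(values <= 0)) {
    stop("area sample must be strictly positive with no missing values",
         call. = FALSE)
  }
  invisible(values)
}

#' Empirical complementary cumulative distribution function
#'
#' For each distinct sample value `x`, the CCDF is
#' `G(x) = P(X >= x) = #\{values >= x\} / n`, the curve plotted on log-log
#' axes to reveal heavy tails.
#'
#' @param values Positive numeric sample (e.g. crack areas in mm^2).
#' @return An object of class `empirical_ccdf`: list with sorted distinct
#'   `xs`, the fractions `gs` (non-increasing, `gs[1] == 1`), and `n`.
#' @export
empirical_ccdf <- function(values) {
  check_area_sample(values)
  n <- length(values)
  tab <- table(values)
  xs <- as.numeric(names(tab))
  counts <- as.integer(tab)
  # values >= xs[i] = n minus those strictly below xs[i]
  gs <- (n - cumsum(counts) + counts) / n
  structure(list(xs = xs, gs = gs, n = n), class = "empirical_ccdf")
}

#' @export
print.empirical_ccdf <- function(x, ...) {
  cat(sprintf("<empirical_ccdf> n = %d, %d distinct values in [%g, %g]\n",
              x$n, length(x$xs), min(x$xs), max(x$xs)))
  invisible(x)
}

#' Fit a log-normal distribution with back-transformed parameters
#'
#' Maximum-likelihood fit on the log scale: `mu = mean(ln x)` and, by
#' default, the divide-by-n MLE `sigma = sqrt(mean((ln x - mu)^2))`. The
#' back-transformed parameters are `mu_star = exp(mu)` — the geometric
#' mean and the median of the distribution, in the units of the data — and
#' the dimensionless geometric standard deviation `sigma_star = exp(sigma)`.
#' A one-sample Kolmogorov-Smirnov distance against the fitted CDF is
#' reported together with its asymptotic p-value; because the parameters
#' were estimated from the same sample this p-value is anti-conservative,
#' and the fit carries a `params_estimated` caveat flag.
#'
#' @param values Positive numeric sample, at least 2 values.
#' @param unbiased_sigma Use the divide-by-(n-1) estimator for `sigma`
#'   instead of the MLE (default `FALSE`). Back-transformed comparisons of
#'   `sigma_star` across studies are sensitive to this choice.
#' @return An object of class `lognormal_fit` with elements `mu`, `sigma`,
#'   `mu_star`, `sigma_star`, `n`, `ks_D`, `ks_p`, `params_estimated`,
#'   `degenerate`. A sample of identical values is flagged degenerate
#'   (`sigma = 0`, `sigma_star = 1`, KS undefined).
#' @export
fit_lognormal <- function(values, unbiased_sigma = FALSE) {
  check_area_sample(values, n_min = 2L)
  lx <- log(values)
  n <- length(values)
  mu <- mean(lx)
  if (length(unique(values)) == 1L) {
    return(structure(list(mu = mu, sigma = 0, mu_star = exp(mu),
                          sigma_star = 1, n = n, ks_D = NA_real_,
                          ks_p = NA_real_, params_estimated = TRUE,
                          degenerate = TRUE),
                     class = "lognormal_fit"))
  }
  ss <- sum((lx - mu)^2)
  sigma <- sqrt(ss / if (unbiased_sigma) (n - 1) else n)
  D <- ks_statistic(values, function(x) plnorm(x, meanlog = mu, sdlog = sigma))
  structure(list(mu = mu, sigma = sigma, mu_star = exp(mu),
                 sigma_star = exp(sigma), n = n, ks_D = D,
                 ks_p = ks_p_asymptotic(D, n), params_estimated = TRUE,
                 degenerate = FALSE),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit> n = %d: mu* = %.4g, sigma* = %.4g (mu = %.4g, sigma = %.4g)\n",
    x$n, x$mu_star, x$sigma_star, x$mu, x$sigma))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate sample (all values identical); KS undefined\n")
  } else {
    cat(sprintf("  KS D = %.4f, asymptotic p = %.4g%s\n", x$ks_D, x$ks_p,
                if (isTRUE(x$params_estimated))
                  " (parameters estimated from data)" else ""))
  }
  invisible(x)
}

# Asymptotic one-sample Kolmogorov p-value, Q_KS evaluated at
# (sqrt(n) + 0.12 + 0.11/sqrt(n)) * D (Stephens' small-sample adjustment).
ks_p_asymptotic <- function(D, n) {
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  if (lambda < 1e-8) return(1)
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov distance between a sample and a model CDF
#'
#' `D = max over sample points of |S(x) - F(x)|`, where `S` is the
#' empirical distribution function evaluated at both sides of each step
#' and `F` is the model CDF. With `xmin` supplied, only values
#' `>= xmin` enter and the empirical distribution is that of the tail
#' subsample, so `model_cdf` must be the model's conditional CDF on
#' `[xmin, Inf)` (for a power-law tail, `1 - (x/xmin)^-(alpha-1)`).
#' The maximum absolute distance between distribution functions equals the
#' maximum distance between the corresponding survival functions, so this
#' is also the CCDF-based distance.
#'
#' @param values Positive numeric sample.
#' @param model_cdf Vectorized function returning the model CDF.
#' @param xmin Optional tail threshold.
#' @return The KS distance `D` in \[0, 1\].
#' @export
ks_statistic <- function(values, model_cdf, xmin = NULL) {
  check_area_sample(values)
  if (!is.null(xmin)) {
    values <- values[values >= xmin]
    if (length(values) == 0L) {
      stop("no sample values at or above `xmin`: empty tail", call. = FALSE)
    }
  }
  x <- sort(values)
  n <- length(x)
  Fm <- model_cdf(x)
  if (anyNA(Fm) || any(Fm < -1e-12) || any(Fm > 1 + 1e-12)) {
    stop("`model_cdf` must return probabilities in [0, 1]", call. = FALSE)
  }
  upper <- seq_len(n) / n
  lower <- (seq_len(n) - 1) / n
  max(pmax(abs(upper - Fm), abs(Fm - lower)))
}

#' Fit a power-law tail with KS-minimizing threshold selection
#'
#' For each distinct sample value taken as candidate threshold `xmin`
#' (keeping candidates whose tail holds at least `min_tail_size` values),
#' the tail exponent is the continuous maximum-likelihood estimate
#' `alpha = 1 + n_tail / sum(ln(x_i / xmin))` over the `x_i >= xmin`, and
#' the Kolmogorov-Smirnov distance `D` between the tail subsample and the
#' fitted power-law CDF is computed. The returned fit is the candidate
#' minimizing `D`; ties are broken toward the smaller `xmin` (larger
#' tail). The density normalization is `c = (alpha - 1) * xmin^(alpha-1)`,
#' so that `c * x^-alpha` integrates to 1 on `[xmin, Inf)`.
#'
#' @param values Positive numeric sample.
#' @param min_tail_size Smallest admissible tail (default 10).
#' @param significance Level for the critical-D acceptance test
#'   (see [critical_D()]).
#' @return An object of class `powerlaw_tail_fit` with elements `xmin`,
#'   `alpha`, `c`, `n_tail`, `D`, `D_crit`, `passed`, `significance`, `n`.
#' @export
fit_powerlaw_tail <- function(values, min_tail_size = 10,
                              significance = 0.05) {
  check_area_sample(values)
  n <- length(values)
  if (n < min_tail_size) {
    stop(sprintf("need at least `min_tail_size` = %d values, got %d",
                 min_tail_size, n), call. = FALSE)
  }
  x <- sort(values)
  lx <- log(x)
  # suffix sums of ln x for O(1) tail log-sums per candidate
  slog <- rev(cumsum(rev(lx)))
  first_idx <- which(!duplicated(x))            # first position of each
  cand <- first_idx[n - first_idx + 1L >= min_tail_size]
  best <- NULL
  for (i in cand) {
    xmin <- x[i]
    n_tail <- n - i + 1L
    sum_lr <- slog[i] - n_tail * lx[i]
    if (sum_lr <= 0) next                       # all tail values equal xmin
    alpha <- 1 + n_tail / sum_lr
    tail_x <- x[i:n]
    Fm <- 1 - (tail_x / xmin)^(-(alpha - 1))
    k <- seq_len(n_tail)
    D <- max(pmax(abs(k / n_tail - Fm), abs(Fm - (k - 1) / n_tail)))
    if (is.null(best) || D < best$D) {
      best <- list(xmin = xmin, alpha = alpha, n_tail = n_tail, D = D)
    }
  }
  if (is.null(best)) {
    stop("no admissible tail threshold (all candidate tails degenerate)",
         call. = FALSE)
  }
  D_crit <- critical_D(best$n_tail, significance)
  structure(list(xmin = best$xmin, alpha = best$alpha,
                 c = (best$alpha - 1) * best$xmin^(best$alpha - 1),
                 n_tail = best$n_tail, D = best$D, D_crit = D_crit,
                 passed = best$D < D_crit, significance = significance,
                 n = n),
            class = "powerlaw_tail_fit")
}

#' @export
print.powerlaw_tail_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_tail_fit> xmin = %.4g, alpha = %.4g (tail n = %d of %d)\n",
    x$xmin, x$alpha, x$n_tail, x$n))
  cat(sprintf("  KS D = %.4f vs critical %.4f at %.2g: %s\n", x$D, x$D_crit,
              x$significance,
              if (isTRUE(x$passed)) "not rejected" else "rejected"))
  invisible(x)
}

#' Critical Kolmogorov-Smirnov distance
#'
#' Asymptotic critical value `coef / sqrt(n_tail)` of the one-sample KS
#' statistic, against which a fitted tail's `D` is compared; `D < D_crit`
#' means the power-law tail is not rejected at the given level. Exact
#' small-sample table values can be supplied via `table_override`.
#'
#' @param n_tail Tail sample size (>= 1).
#' @param significance One of 0.10, 0.05 (default), 0.01.
#' @param table_override Optional named numeric vector mapping
#'   `n_tail` values (as names) to exact critical values, taking
#'   precedence over the asymptotic formula.
#' @return The critical distance `D_crit`.
#' @export
critical_D <- function(n_tail, significance = 0.05, table_override = NULL) {
  if (!is.numeric(n_tail) || length(n_tail) != 1L || n_tail < 1) {
    stop("`n_tail` must be a single value >= 1", call. = FALSE)
  }
  if (!is.null(table_override)) {
    hit <- table_override[as.character(n_tail)]
    if (!is.na(hit)) return(unname(hit))
  }
  coefs <- c("0.1" = 1.22, "0.05" = 1.36, "0.01" = 1.63)
  key <- as.character(significance)
  if (!key %in% names(coefs)) {
    stop("unsupported significance level; use 0.10, 0.05 or 0.01",
         call. = FALSE)
  }
  unname(coefs[key]) / sqrt(n_tail)
}

#' Probability mass of a log-normal between geometric k-sigma bounds
#'
#' Mass of the log-normal with geometric mean `mu_star` and geometric
#' standard deviation `sigma_star` contained between `mu_star / sigma_star^k`
#' and `mu_star * sigma_star^k`. By the back-transform this equals
#' `2 * pnorm(k) - 1` for every parameter value: 68.3% for k = 1, 95.5%
#' for k = 2, 99.7% for k = 3 (the geometric analogue of the normal
#' k-sigma rule).
#'
#' @param mu_star Geometric mean (> 0).
#' @param sigma_star Geometric standard deviation (> 1).
#' @param k Number of geometric standard deviations (>= 0).
#' @return Probability in \[0, 1).
#' @export
lognormal_interval_mass <- function(mu_star, sigma_star, k) {
  if (mu_star <= 0) stop("`mu_star` must be positive", call. = FALSE)
  if (sigma_star <= 1) stop("`sigma_star` must exceed 1", call. = FALSE)
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  mu <- log(mu_star)
  sigma <- log(sigma_star)
  plnorm(mu_star * sigma_star^k, mu, sigma) -
    plnorm(mu_star / sigma_star^k, mu, sigma)
}

#' Full distribution fit report for one crack-area sample
#'
#' Bundles the log-normal fit of the whole sample, the power-law tail fit,
#' and the total cracked area into one report row.
#'
#' @param values Positive numeric crack areas (mm^2).
#' @param sample_id Identifier of the sample (e.g. image id).
#' @param group Group label (e.g. variety).
#' @param min_tail_size,significance Passed to [fit_powerlaw_tail()].
#' @param unbiased_sigma Passed to [fit_lognormal()].
#' @return An object of class `fit_report` with elements `sample_id`,
#'   `group`, `lognormal`, `powerlaw`, `total_area_mm2`, `n`.
#' @export
fit_areas <- function(values, sample_id = "", group = "",
                      min_tail_size = 10, significance = 0.05,
                      unbiased_sigma = FALSE) {
  check_area_sample(values, n_min = 2L)
  structure(list(
    sample_id = sample_id, group = group,
    lognormal = fit_lognormal(values, unbiased_sigma = unbiased_sigma),
    powerlaw = fit_powerlaw_tail(values, min_tail_size = min_tail_size,
                                 significance = significance),
    total_area_mm2 = sum(values), n = length(values)
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> sample '%s' (group '%s'): n = %d, total %.4g mm^2\n",
              x$sample_id, x$group, x$n, x$total_area_mm2))
  print(x$lognormal)
  print(x$powerlaw)
  invisible(x)
}

#' Summarize fit reports by group
#'
#' Renders the per-variety coefficient layout: one row per sample with the
#' fitted tail threshold, exponent, KS distance and back-transformed
#' log-normal parameters, plus per-group means with sample counts.
#'
#' @param reports List of [fit_areas()] reports (at least one).
#' @return List with `by_sample` (data frame: `sample_id`, `group`,
#'   `xmin`, `alpha`, `D`, `mu_star`, `sigma_star`, `total_area_mm2`) and
#'   `by_group` (group means of those columns plus `n_samples`).
#' @export
summarize_groups <- function(reports) {
  if (inherits(reports, "fit_report")) reports <- list(reports)
  if (length(reports) < 1L ||
      !all(vapply(reports, inherits, logical(1), "fit_report"))) {
    stop("`reports` must be one or more fit_report objects", call. = FALSE)
  }
  by_sample <- do.call(rbind, lapply(reports, function(r) {
    data.frame(sample_id = r$sample_id, group = r$group,
               xmin = r$powerlaw$xmin, alpha = r$powerlaw$alpha,
               D = r$powerlaw$D, mu_star = r$lognormal$mu_star,
               sigma_star = r$lognormal$sigma_star,
               total_area_mm2 = r$total_area_mm2)
  }))
  num_cols <- c("xmin", "alpha", "D", "mu_star", "sigma_star",
                "total_area_mm2")
  by_group <- aggregate(by_sample[num_cols],
                        by = list(group = by_sample$group), FUN = mean)
  counts <- aggregate(list(n_samples = by_sample$sample_id),
                      by = list(group = by_sample$group), FUN = length)
  by_group <- merge(by_group, counts, by = "group")
  list(by_sample = by_sample, by_group = by_group)
}
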