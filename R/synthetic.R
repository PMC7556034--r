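# Seeded generators for every input the toolkit consumes — area samples
# with known distributional truth, crack images with exact ground-truth
# masks, and force-deformation curves — so segmentation and fitting can be
# validated end to end without study data. All generators are pure
# functions of their parameters and seed.

#' Generate a log-normal area sample
#'
#' Draws `n` values with `ln(x) ~ Normal(ln mu_star, ln sigma_star)`, i.e.
#' a log-normal with geometric mean `mu_star` and geometric standard
#' deviation `sigma_star`.
#'
#' @param mu_star Geometric mean (> 0), in the units of the data (mm^2).
#' @param sigma_star Geometric standard deviation (> 1, dimensionless).
#' @param n Sample size.
#' @param seed RNG seed; the same seed reproduces the same sample.
#' @return Numeric vector of `n` positive values.
#' @export
gen_lognormal <- function(mu_star, sigma_star, n, seed) {
  if (mu_star <= 0) stop("`mu_star` must be positive", call. = FALSE)
  if (sigma_star <= 1) stop("`sigma_star` must exceed 1", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  with_seed(seed, exp(rnorm(n, log(mu_star), log(sigma_star))))
}

#' Generate a power-law (Pareto) area sample
#'
#' Inverse-CDF draws `x = xmin * (1 - u)^(-1/(alpha - 1))` with `u`
#' uniform on \[0, 1), so the density is proportional to `x^-alpha` on
#' `[xmin, Inf)`.
#'
#' @param xmin Lower support bound (> 0).
#' @param alpha Tail exponent (> 1).
#' @param n Sample size.
#' @param seed RNG seed.
#' @return Numeric vector of `n` values, all `>= xmin`.
#' @export
gen_powerlaw <- function(xmin, alpha, n, seed) {
  if (xmin <= 0) stop("`xmin` must be positive", call. = FALSE)
  if (alpha <= 1) stop("`alpha` must exceed 1", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  with_seed(seed, xmin * (1 - runif(n))^(-1 / (alpha - 1)))
}

#' Generate a spliced body-plus-tail area sample with a truth record
#'
#' With probability `tail_fraction` a value is drawn from the power law on
#' `[xmin, Inf)`; otherwise from the log-normal body truncated below
#' `xmin` (rejection sampling). The default `tail_fraction = NULL` uses
#' the log-normal's own survival mass at `xmin`,
#' `P(X >= xmin)` under the body — the choice under which the splice
#' perturbs the body distribution least.
#'
#' The truth record carries the generator parameters and, because a
#' spliced sample is *not* log-normal, the closed-form population moments
#' of `ln X` under the splice (`log_mean`, `log_sd`) and the implied
#' population geometric mean `geo_mean = exp(log_mean)`. Fitting a
#' log-normal to a spliced sample consistently estimates `geo_mean`, not
#' `mu_star`, so recovery checks must compare against `geo_mean`.
#'
#' @param mu_star,sigma_star Body geometric mean (> 0) and geometric SD
#'   (> 1).
#' @param xmin,alpha Tail threshold (> 0) and exponent (> 1).
#' @param n Sample size.
#' @param seed RNG seed.
#' @param tail_fraction Probability of a tail draw, in \[0, 1\] (0 and 1
#'   give the pure truncated body and the pure power law), or `NULL` for
#'   the body's own survival mass at `xmin`.
#' @param max_rejections Rejection-sampling budget for the truncated body
#'   (default 1e6 rejected draws) before aborting.
#' @return List with `values` (length `n`) and `truth` (parameters,
#'   `tail_fraction`, `log_mean`, `log_sd`, `geo_mean`, `seed`).
#' @export
gen_spliced <- function(mu_star, sigma_star, xmin, alpha, n, seed,
                        tail_fraction = NULL, max_rejections = 1e6) {
  if (mu_star <= 0 || sigma_star <= 1 || xmin <= 0 || alpha <= 1 || n < 1) {
    stop("invalid generator parameters", call. = FALSE)
  }
  mu <- log(mu_star)
  sigma <- log(sigma_star)
  a <- log(xmin)
  z <- (a - mu) / sigma
  body_mass <- pnorm(z)                      # P(X < xmin) under the body
  q <- tail_fraction %||% (1 - body_mass)
  if (q < 0 || q > 1) {
    stop("`tail_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (q < 1 && body_mass <= 0) {
    stop("body has no mass below `xmin`: cannot draw the truncated body",
         call. = FALSE)
  }

  # ln X moments: body = Normal(mu, sigma) upper-truncated at a;
  # tail = a + Exponential(rate alpha - 1).
  if (q < 1) {
    h <- dnorm(z) / pnorm(z)
    mean_body <- mu - sigma * h
    var_body <- sigma^2 * (1 - z * h - h^2)
  } else {
    mean_body <- 0
    var_body <- 0
  }
  mean_tail <- a + 1 / (alpha - 1)
  var_tail <- 1 / (alpha - 1)^2
  log_mean <- (1 - q) * mean_body + q * mean_tail
  log_var <- (1 - q) * (var_body + mean_body^2) +
    q * (var_tail + mean_tail^2) - log_mean^2

  values <- with_seed(seed, {
    from_tail <- runif(n) < q
    out <- numeric(n)
    n_tail <- sum(from_tail)
    if (n_tail > 0) {
      out[from_tail] <- xmin * (1 - runif(n_tail))^(-1 / (alpha - 1))
    }
    need <- n - n_tail
    body <- numeric(0)
    rejected <- 0
    while (length(body) < need) {
      draw <- exp(rnorm(max(need, 1000L), mu, sigma))
      keep <- draw[draw < xmin]
      rejected <- rejected + length(draw) - length(keep)
      if (rejected > max_rejections) {
        stop("rejection budget exhausted while sampling the truncated body",
             call. = FALSE)
      }
      body <- c(body, keep)
    }
    out[!from_tail] <- body[seq_len(need)]
    out
  })
  list(values = values,
       truth = list(mu_star = mu_star, sigma_star = sigma_star,
                    xmin = xmin, alpha = alpha, tail_fraction = q,
                    log_mean = log_mean, log_sd = sqrt(log_var),
                    geo_mean = exp(log_mean), n = n, seed = seed))
}

#' Generate a crack image with exact ground truth
#'
#' Places dark blobs of exactly the requested pixel areas (regions grown
#' by random accretion from a seed pixel) on a light textured background,
#' with pairwise blob separation greater than 2 px so that labeling at
#' either connectivity recovers each blob as one component. Returns both
#' the rendered grayscale image and the exact foreground mask.
#'
#' @param area_list_px Integer vector of requested blob areas in pixels
#'   (each >= 1; total at most 30% of the canvas).
#' @param canvas_shape `(rows, cols)` of the canvas (default 256 x 256).
#' @param seed RNG seed.
#' @param bg_mean,bg_sd Background intensity model (default 200 +/- 10).
#' @param fg_mean,fg_sd Blob intensity model (default 40 +/- 10). The
#'   default contrast guarantees Otsu separability.
#' @param pixel_pitch_um Physical calibration attached to the image
#'   (default 63.5, i.e. 400 dpi).
#' @param max_tries Placement attempts per blob before declaring the
#'   packing infeasible.
#' @return List with `image` (an [image_gray()]), `mask` (a
#'   [binary_mask()] with the exact ground truth), `labels` (integer
#'   matrix, one id per blob in placement order) and `areas_px` (the
#'   realized = requested areas).
#' @export
gen_crack_image <- function(area_list_px, canvas_shape = c(256, 256), seed,
                            bg_mean = 200, bg_sd = 10, fg_mean = 40,
                            fg_sd = 10, pixel_pitch_um = 63.5,
                            max_tries = 200) {
  nr <- canvas_shape[1]
  nc <- canvas_shape[2]
  area_list_px <- as.integer(area_list_px)
  if (length(area_list_px) > 0 && any(area_list_px < 1)) {
    stop("all requested areas must be >= 1 px", call. = FALSE)
  }
  if (sum(area_list_px) > 0.3 * nr * nc) {
    stop("requested blob areas exceed 30% of the canvas: infeasible packing",
         call. = FALSE)
  }
  with_seed(seed, {
    labels <- matrix(0L, nr, nc)
    forbidden <- matrix(FALSE, nr, nc)
    for (b in seq_along(area_list_px)) {
      target <- area_list_px[b]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        region <- grow_region(target, forbidden, nr, nc)
        if (!is.null(region)) {
          labels[region] <- b
          blob <- matrix(FALSE, nr, nc)
          blob[region] <- TRUE
          forbidden <- forbidden | dilate_cheb(blob, 2L)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place blob %d (%d px): infeasible packing",
                     b, target), call. = FALSE)
      }
    }
    fg <- labels > 0L
    px <- matrix(rnorm(nr * nc, bg_mean, bg_sd), nr, nc)
    px[fg] <- rnorm(sum(fg), fg_mean, fg_sd)
    px <- round(pmin(pmax(px, 0), 255))
    list(image = image_gray(px, pixel_pitch_um),
         mask = binary_mask(fg, pixel_pitch_um = pixel_pitch_um),
         labels = labels,
         areas_px = as.integer(tabulate(labels[labels > 0L],
                                        nbins = length(area_list_px))))
  })
}

# Grow a connected region of exactly `target` free pixels by random
# accretion; returns linear indices or NULL if growth stalled.
grow_region <- function(target, forbidden, nr, nc) {
  free_idx <- which(!forbidden)
  if (length(free_idx) < target) return(NULL)
  seed_px <- free_idx[sample.int(length(free_idx), 1L)]
  in_region <- matrix(FALSE, nr, nc)
  in_cand <- matrix(FALSE, nr, nc)
  region <- integer(target)
  region[1] <- seed_px
  in_region[seed_px] <- TRUE
  cand <- free_neighbors(seed_px, in_region, in_cand, forbidden, nr, nc)
  in_cand[cand] <- TRUE
  count <- 1L
  while (count < target) {
    if (length(cand) == 0L) return(NULL)
    pick <- sample.int(length(cand), 1L)
    px <- cand[pick]
    cand <- cand[-pick]
    in_cand[px] <- FALSE
    count <- count + 1L
    region[count] <- px
    in_region[px] <- TRUE
    new_cand <- free_neighbors(px, in_region, in_cand, forbidden, nr, nc)
    if (length(new_cand)) {
      in_cand[new_cand] <- TRUE
      cand <- c(cand, new_cand)
    }
  }
  region
}

# Free 4-neighbors of a pixel not yet in the region or candidate set.
free_neighbors <- function(px, in_region, in_cand, forbidden, nr, nc) {
  r <- (px - 1L) %% nr + 1L
  c <- (px - 1L) %/% nr + 1L
  rs <- c(r - 1L, r + 1L, r, r)
  cs <- c(c, c, c - 1L, c + 1L)
  ok <- rs >= 1L & rs <= nr & cs >= 1L & cs <= nc
  idx <- (cs[ok] - 1L) * nr + rs[ok]
  idx[!in_region[idx] & !in_cand[idx] & !forbidden[idx]]
}

# Chebyshev (square) dilation by `radius` pixels.
dilate_cheb <- function(mask, radius) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -radius:radius) {
    rs_src <- max(1L, 1L - dr):min(nr, nr - dr)
    rs_dst <- rs_src + dr
    for (dc in -radius:radius) {
      cs_src <- max(1L, 1L - dc):min(nc, nc - dc)
      cs_dst <- cs_src + dc
      out[rs_dst, cs_dst] <- out[rs_dst, cs_dst] | mask[rs_src, cs_src]
    }
  }
  out
}

#' Generate a synthetic puncture-test force curve
#'
#' Emulates the canonical crust-puncture trace: linear rise from zero
#' force to the crust peak `(thickness, hardness)`, exponential relaxation
#' toward `plateau_force` (the softer interior), then a plateau to full
#' travel, with optional additive Gaussian noise (clipped at zero force).
#'
#' @param hardness Peak force in N (> 0).
#' @param thickness Distance of the peak from the start, mm
#'   (0 < thickness < travel). Exact round-trip recovery requires
#'   `thickness` to be a multiple of `step`.
#' @param plateau_force Interior plateau force in N (0 < plateau_force <
#'   hardness).
#' @param travel Total probe travel in mm (default 20).
#' @param step Sampling step in mm (default 0.01, i.e. 1 mm/s at 100 Hz).
#' @param noise_sd Gaussian noise SD in N (default 0).
#' @param seed RNG seed (only used when `noise_sd > 0`, but the curve is
#'   reproducible for any setting).
#' @param decay_mm Length constant of the post-peak exponential drop
#'   (default 0.5 mm).
#' @return A [force_curve()].
#' @export
gen_force_curve <- function(hardness, thickness, plateau_force, travel = 20,
                            step = 0.01, noise_sd = 0, seed = 1,
                            decay_mm = 0.5) {
  if (hardness <= 0 || plateau_force <= 0 || plateau_force >= hardness) {
    stop("need 0 < plateau_force < hardness", call. = FALSE)
  }
  if (thickness <= 0 || thickness >= travel) {
    stop("need 0 < thickness < travel", call. = FALSE)
  }
  if (step <= 0 || noise_sd < 0 || decay_mm <= 0) {
    stop("invalid curve geometry", call. = FALSE)
  }
  d <- seq(0, travel, by = step)
  f <- ifelse(d <= thickness,
              hardness * d / thickness,
              plateau_force +
                (hardness - plateau_force) * exp(-(d - thickness) / decay_mm))
  if (noise_sd > 0) {
    f <- with_seed(seed, f + rnorm(length(f), 0, noise_sd))
  }
  force_curve(d, pmax(f, 0))
}
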