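# Independent brute-force oracles. These deliberately share no code with
# the package implementation: explicit loops and first-principles formulas.

# Exhaustive Otsu: between-class variance w0*w1*(m0-m1)^2 for every
# candidate level, first maximizer.
oracle_otsu <- function(px) {
  v <- round(as.vector(px))
  best_t <- NA_integer_
  best_var <- -Inf
  for (t in 0:254) {
    g0 <- v[v <= t]
    g1 <- v[v > t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(v)
    bv <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (bv > best_var + 1e-12) {
      best_var <- bv
      best_t <- t
    }
  }
  list(level = best_t, variance = best_var)
}

oracle_otsu_variance_at <- function(px, t) {
  v <- round(as.vector(px))
  g0 <- v[v <= t]
  g1 <- v[v > t]
  if (length(g0) == 0 || length(g1) == 0) return(-Inf)
  w0 <- length(g0) / length(v)
  w0 * (1 - w0) * (mean(g0) - mean(g1))^2
}

# Queue-based flood-fill labeling (independent of the package's C++ code).
oracle_label <- function(px, connectivity = 8) {
  nr <- nrow(px)
  nc <- ncol(px)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  next_lab <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!px[rr, cc] || lab[rr, cc] != 0L) next
    next_lab <- next_lab + 1L
    queue <- list(c(rr, cc))
    lab[rr, cc] <- next_lab
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r2 <- cur[1] + nb[k, 1]
        c2 <- cur[2] + nb[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            px[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- next_lab
          queue <- c(queue, list(c(r2, c2)))
        }
      }
    }
  }
  lab
}

# O(n^2) empirical CCDF by double-loop counting.
oracle_ccdf <- function(values) {
  xs <- sort(unique(values))
  gs <- vapply(xs, function(x) {
    cnt <- 0
    for (v in values) if (v >= x) cnt <- cnt + 1
    cnt / length(values)
  }, numeric(1))
  list(xs = xs, gs = gs)
}

# KS distance by scanning every tail point at both step sides.
oracle_ks <- function(values, cdf, xmin = NULL) {
  if (!is.null(xmin)) values <- values[values >= xmin]
  x <- sort(values)
  n <- length(x)
  D <- 0
  for (i in seq_len(n)) {
    Fm <- cdf(x[i])
    D <- max(D, abs(i / n - Fm), abs(Fm - (i - 1) / n))
  }
  D
}

# Exhaustive power-law tail search: every distinct value as candidate
# xmin, direct MLE and KS formulas, minimum D with ties to smaller xmin.
oracle_plfit <- function(values, min_tail_size = 10) {
  best <- NULL
  for (xmin in sort(unique(values))) {
    tail_x <- sort(values[values >= xmin])
    n_tail <- length(tail_x)
    if (n_tail < min_tail_size) next
    slr <- sum(log(tail_x / xmin))
    if (slr <= 0) next
    alpha <- 1 + n_tail / slr
    D <- oracle_ks(tail_x, function(x) 1 - (x / xmin)^(-(alpha - 1)))
    if (is.null(best) || D < best$D) {
      best <- list(xmin = xmin, alpha = alpha, n_tail = n_tail, D = D)
    }
  }
  best
}

# Minimum Chebyshev distance between pixels of two label ids.
oracle_min_cheb_dist <- function(labels, id1, id2) {
  p1 <- which(labels == id1, arr.ind = TRUE)
  p2 <- which(labels == id2, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(p1))) {
    d <- pmax(abs(p2[, 1] - p1[i, 1]), abs(p2[, 2] - p1[i, 2]))
    best <- min(best, min(d))
  }
  best
}

# Two-Gaussian mixture test image (crust-like light field, dark cracks).
make_bimodal_image <- function(seed, nr = 64, nc = 64, frac_dark = 0.3,
                               mean_dark = 60, mean_light = 180, sd = 10) {
  withr::with_seed(seed, {
    n <- nr * nc
    dark <- runif(n) < frac_dark
    v <- ifelse(dark, rnorm(n, mean_dark, sd), rnorm(n, mean_light, sd))
    matrix(round(pmin(pmax(v, 0), 255)), nr, nc)
  })
}

# Blob-area request for pipeline fixtures: enough particles per image to
# pool a distribution fit.
sample_areas_px <- function(seed, n = 12) {
  withr::with_seed(seed, sample(5:60, n, replace = TRUE))
}

table4_colors <- function() {
  read_lab_csv(system.file("extdata", "amaretti_lab_means.csv",
                           package = "crackfrac"))
}
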