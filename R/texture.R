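# Puncture-test texture features from force-deformation curves: crust
# hardness (peak force), crust thickness (distance from test start to the
# onset of maximum force) and work of deformation (area under the curve
# from the peak to full penetration).

#' Force-deformation curve
#'
#' An ordered puncture-test trace from test start to full probe
#' penetration (typical protocol: cylinder probe lowered 20 mm at 1 mm/s).
#'
#' @param distance_mm Strictly increasing probe travel in millimeters.
#' @param force_N Non-negative force readings in newtons, same length.
#' @return An object of class `force_curve`: a data frame with columns
#'   `distance_mm` and `force_N` (at least 3 points).
#' @export
force_curve <- function(distance_mm, force_N) {
  if (length(distance_mm) != length(force_N) || length(distance_mm) < 3L) {
    stop("need at least 3 (distance, force) points of equal length",
         call. = FALSE)
  }
  if (anyNA(distance_mm) || anyNA(force_N)) {
    stop("curve must not contain missing values", call. = FALSE)
  }
  if (any(diff(distance_mm) <= 0)) {
    stop("`distance_mm` must be strictly increasing", call. = FALSE)
  }
  if (any(force_N < 0)) {
    stop("`force_N` must be non-negative", call. = FALSE)
  }
  structure(data.frame(distance_mm = distance_mm, force_N = force_N),
            class = c("force_curve", "data.frame"))
}

#' Extract puncture-test texture features
#'
#' The test start is the first sample whose force reaches
#' `contact_threshold_N` (the probe-contact trigger; with a threshold of 0
#' the first recorded sample starts the test, and if no sample reaches the
#' threshold the first sample is used). From there:
#' hardness is the global maximum force; crust thickness is the distance
#' from the start to the first occurrence of that maximum; the work of
#' deformation (WOD) is the trapezoidal integral of force over distance
#' from the first maximum point to the last recorded point (full
#' penetration). A curve peaking at its final point therefore has zero
#' WOD. An optional centered moving-average window can be applied before
#' peak detection.
#'
#' @param curve A [force_curve()].
#' @param contact_threshold_N Contact trigger in newtons (default 0.05).
#' @param smooth_window Odd moving-average window width in samples
#'   (default 1 = no smoothing).
#' @return An object of class `texture_features`: list with `hardness_N`,
#'   `crust_thickness_mm`, `wod_Nmm`, plus `start_mm` and `peak_mm` for
#'   audit.
#' @export
extract_features <- function(curve, contact_threshold_N = 0.05,
                             smooth_window = 1L) {
  stopifnot(inherits(curve, "force_curve"))
  if (contact_threshold_N < 0) {
    stop("`contact_threshold_N` must be >= 0", call. = FALSE)
  }
  if (all(curve$force_N == 0)) {
    stop("all forces are zero: probe never contacted the sample",
         call. = FALSE)
  }
  f <- curve$force_N
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) {
      stop("`smooth_window` must be odd", call. = FALSE)
    }
    f <- as.numeric(stats::filter(f, rep(1 / smooth_window, smooth_window),
                                  sides = 2))
    half <- (smooth_window - 1L) %/% 2L
    f[seq_len(half)] <- curve$force_N[seq_len(half)]
    f[(length(f) - half + 1L):length(f)] <-
      curve$force_N[(length(f) - half + 1L):length(f)]
  }
  d <- curve$distance_mm
  start_idx <- which(f >= contact_threshold_N)[1]
  if (is.na(start_idx)) start_idx <- 1L
  hardness <- max(f[start_idx:length(f)])
  peak_idx <- start_idx - 1L + which(f[start_idx:length(f)] == hardness)[1]
  wod <- if (peak_idx == length(d)) {
    0
  } else {
    idx <- peak_idx:length(d)
    sum(diff(d[idx]) * (head(f[idx], -1) + tail(f[idx], -1)) / 2)
  }
  structure(list(hardness_N = hardness,
                 crust_thickness_mm = d[peak_idx] - d[start_idx],
                 wod_Nmm = wod,
                 start_mm = d[start_idx], peak_mm = d[peak_idx]),
            class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf(
    "<texture_features> hardness %.3g N, crust %.3g mm, WOD %.3g N*mm\n",
    x$hardness_N, x$crust_thickness_mm, x$wod_Nmm))
  invisible(x)
}

#' Texture features for a batch of curves with group summaries
#'
#' @param curves List of [force_curve()] objects (at least one).
#' @param groups Group labels, one per curve (default a single group).
#' @param curve_ids Identifiers, one per curve.
#' @param ... Passed to [extract_features()].
#' @return List with `by_curve` (data frame: `curve_id`, `group`,
#'   `hardness_N`, `crust_thickness_mm`, `wod_Nmm`) and `by_group`
#'   (per-group mean and SD of each feature plus `n_curves`).
#' @export
batch_features <- function(curves, groups = NULL, curve_ids = NULL, ...) {
  if (inherits(curves, "force_curve")) curves <- list(curves)
  if (length(curves) < 1L) stop("need at least one curve", call. = FALSE)
  groups <- groups %||% rep("all", length(curves))
  curve_ids <- curve_ids %||% sprintf("curve_%03d", seq_along(curves))
  if (length(groups) != length(curves) ||
      length(curve_ids) != length(curves)) {
    stop("`groups` and `curve_ids` must match the number of curves",
         call. = FALSE)
  }
  by_curve <- do.call(rbind, Map(function(cv, g, id) {
    ft <- extract_features(cv, ...)
    data.frame(curve_id = id, group = g, hardness_N = ft$hardness_N,
               crust_thickness_mm = ft$crust_thickness_mm,
               wod_Nmm = ft$wod_Nmm)
  }, curves, groups, curve_ids))
  num_cols <- c("hardness_N", "crust_thickness_mm", "wod_Nmm")
  mean_tab <- aggregate(by_curve[num_cols],
                        by = list(group = by_curve$group), FUN = mean)
  sd_tab <- aggregate(by_curve[num_cols],
                      by = list(group = by_curve$group),
                      FUN = function(v) if (length(v) > 1) sd(v) else 0)
  names(mean_tab)[-1] <- paste0(num_cols, "_mean")
  names(sd_tab)[-1] <- paste0(num_cols, "_sd")
  counts <- aggregate(list(n_curves = by_curve$curve_id),
                      by = list(group = by_curve$group), FUN = length)
  by_group <- Reduce(function(a, b) merge(a, b, by = "group"),
                     list(mean_tab, sd_tab, counts))
  list(by_curve = by_curve, by_group = by_group)
}
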