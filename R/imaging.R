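# Image segmentation of surface cracks: grayscale conversion, circular
# region of interest, Otsu thresholding, noise reduction and particle
# (crack-area) extraction under a physical pixel calibration.

#' Grayscale image with physical pixel calibration
#'
#' Container for an 8-bit grayscale image together with the physical width
#' of one pixel in micrometers, which converts pixel counts to mm^2.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\] (rows = image
#'   rows, columns = image columns).
#' @param pixel_pitch_um Physical width of one pixel in micrometers
#'   (e.g. 63.5 at 400 dpi). Must be positive.
#' @return An object of class `image_gray`: a list with elements `pixels`
#'   and `pixel_pitch_um`.
#' @seealso [pitch_from_dpi()], [rgb_to_gray()]
#' @export
image_gray <- function(pixels, pixel_pitch_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie in [0, 255] with no missing values",
         call. = FALSE)
  }
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1L ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0) {
    stop("`pixel_pitch_um` must be a single positive number", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_pitch_um = pixel_pitch_um),
            class = "image_gray")
}

#' @export
print.image_gray <- function(x, ...) {
  cat(sprintf("<image_gray> %d x %d px, pitch %.3g um (%.3g x %.3g mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_um,
              nrow(x$pixels) * x$pixel_pitch_um / 1000,
              ncol(x$pixels) * x$pixel_pitch_um / 1000))
  invisible(x)
}

#' Pixel pitch from scan resolution
#'
#' @param dpi Scan resolution in dots per inch.
#' @return Pixel width in micrometers, `25400 / dpi` (63.5 um at 400 dpi).
#' @export
pitch_from_dpi <- function(dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0) {
    stop("`dpi` must be a single positive number", call. = FALSE)
  }
  25400 / dpi
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Luma conversion with ITU-R BT.601 weights (0.299, 0.587, 0.114), the
#' default used by ImageJ; results are rounded to integers and clipped to
#' \[0, 255\].
#'
#' @param rgb Numeric array of dimension `c(nrow, ncol, 3)` with channel
#'   values in \[0, 255\].
#' @param pixel_pitch_um Physical pixel width in micrometers.
#' @param weights Length-3 channel weights; must sum to 1.
#' @return An [image_gray()].
#' @export
rgb_to_gray <- function(rgb, pixel_pitch_um,
                        weights = c(0.299, 0.587, 0.114)) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("`rgb` must be an array with three channels (nrow x ncol x 3)",
         call. = FALSE)
  }
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be three values summing to 1", call. = FALSE)
  }
  gray <- weights[1] * rgb[, , 1] + weights[2] * rgb[, , 2] +
    weights[3] * rgb[, , 3]
  gray <- round(gray)
  gray[gray < 0] <- 0
  gray[gray > 255] <- 255
  image_gray(gray, pixel_pitch_um)
}

#' Circular region of interest
#'
#' A planar circular window (e.g. the flat central portion of a convex
#' cookie surface) specified by a pixel center and a physical diameter.
#'
#' @param center Length-2 numeric `(row, col)` pixel coordinates of the
#'   circle center.
#' @param diameter_mm Circle diameter in millimeters; must be positive.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center, diameter_mm) {
  if (length(center) != 2L || !is.numeric(center) || anyNA(center)) {
    stop("`center` must be numeric (row, col)", call. = FALSE)
  }
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      !is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("`diameter_mm` must be a single positive number", call. = FALSE)
  }
  structure(list(center = as.numeric(center), diameter_mm = diameter_mm),
            class = "circular_roi")
}

#' Mask a grayscale image to a circular region of interest
#'
#' Pixels whose centers fall outside the circle are replaced by
#' `background_value`; pixels inside are left unchanged. A pixel at
#' `(r, c)` is inside when its squared distance from the ROI center is at
#' most the squared pixel radius `diameter_mm * 1000 / (2 * pitch)`.
#'
#' @param gray An [image_gray()].
#' @param roi A [circular_roi()]; if `center` is `NULL` in the helper
#'   callers, use the image center.
#' @param background_value Intensity assigned outside the circle
#'   (default 255, a light crust-like background that Otsu assigns to the
#'   non-crack class).
#' @return An [image_gray()] of the same dimensions.
#' @export
apply_roi <- function(gray, roi, background_value = 255) {
  stopifnot(inherits(gray, "image_gray"), inherits(roi, "circular_roi"))
  if (background_value < 0 || background_value > 255) {
    stop("`background_value` must lie in [0, 255]", call. = FALSE)
  }
  nr <- nrow(gray$pixels)
  nc <- ncol(gray$pixels)
  radius_px <- roi$diameter_mm * 1000 / gray$pixel_pitch_um / 2
  dr <- (seq_len(nr) - roi$center[1])^2
  dc <- (seq_len(nc) - roi$center[2])^2
  inside <- outer(dr, dc, `+`) <= radius_px^2
  if (!any(inside)) {
    stop("ROI circle does not intersect the image", call. = FALSE)
  }
  px <- gray$pixels
  px[!inside] <- background_value
  image_gray(px, gray$pixel_pitch_um)
}

#' Otsu threshold of a grayscale image
#'
#' Selects the intensity level that maximizes the between-class variance of
#' the 256-bin histogram (intensities rounded to integers 0-255). The
#' returned level `t` splits pixels into classes `<= t` and `> t`; when
#' several levels attain the maximum the smallest is returned.
#'
#' @param gray An [image_gray()] or a numeric matrix in \[0, 255\].
#' @return Integer threshold level in `0:254`.
#' @export
otsu_threshold <- function(gray) {
  px <- if (inherits(gray, "image_gray")) gray$pixels else gray
  v <- round(as.vector(px))
  if (length(unique(v)) < 2L) {
    stop("image is constant: Otsu threshold is undefined", call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)                 # class-0 weight for threshold t
  mu <- cumsum(p * levels)           # class-0 first moment
  mu_total <- mu[256]
  t_cand <- 1:255                    # thresholds 0..254 (split must be proper)
  w0 <- omega[t_cand]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_total * w0[valid] - mu[t_cand][valid])^2 /
    (w0[valid] * w1[valid])
  as.integer(which.max(sigma_b) - 1L)
}

#' Binarize a grayscale image at a threshold level
#'
#' With the default `"dark_foreground"` polarity, pixels with intensity
#' `<= level` become foreground (cracks are darker than the crust);
#' `"light_foreground"` inverts the rule to pixels `> level`.
#'
#' @param gray An [image_gray()].
#' @param level Threshold in \[0, 255\].
#' @param polarity `"dark_foreground"` (default) or `"light_foreground"`.
#' @return An object of class `binary_mask`: list with logical matrix
#'   `pixels` (TRUE = foreground), the `threshold` used, the `polarity`,
#'   and the inherited `pixel_pitch_um`.
#' @export
binarize <- function(gray, level,
                     polarity = c("dark_foreground", "light_foreground")) {
  stopifnot(inherits(gray, "image_gray"))
  polarity <- match.arg(polarity)
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level > 255) {
    stop("`level` must be a single value in [0, 255]", call. = FALSE)
  }
  fg <- if (polarity == "dark_foreground") gray$pixels <= level
        else gray$pixels > level
  binary_mask(fg, threshold = level, polarity = polarity,
              pixel_pitch_um = gray$pixel_pitch_um)
}

#' Binary mask constructor
#'
#' @param pixels Logical matrix, `TRUE` marking foreground (crack) pixels.
#' @param threshold Threshold level the mask was produced with (or `NA`).
#' @param polarity Polarity flag used at binarization.
#' @param pixel_pitch_um Physical pixel width in micrometers, carried along
#'   for area calibration (may be `NA` for masks of unknown provenance).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, threshold = NA_real_,
                        polarity = "dark_foreground",
                        pixel_pitch_um = NA_real_) {
  if (!is.matrix(pixels) || !is.logical(pixels) || anyNA(pixels)) {
    stop("`pixels` must be a logical matrix without missing values",
         call. = FALSE)
  }
  structure(list(pixels = pixels, threshold = threshold, polarity = polarity,
                 pixel_pitch_um = pixel_pitch_um),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px (threshold %s)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              format(x$threshold)))
  invisible(x)
}

#' Remove segmentation noise from a binary mask
#'
#' `method = "size"` (default) removes connected components smaller than
#' `min_size_px` pixels, the usual treatment of isolated speckle after
#' thresholding. `method = "median"` applies a 3x3 median (majority)
#' filter instead.
#'
#' @param mask A [binary_mask()].
#' @param min_size_px Minimum component size kept, in pixels (`0` keeps
#'   everything). Default 2 removes single-pixel speckle.
#' @param method `"size"` or `"median"`.
#' @param connectivity Neighborhood used for component size, 4 or 8.
#' @return A [binary_mask()] with the same shape.
#' @export
denoise <- function(mask, min_size_px = 2, method = c("size", "median"),
                    connectivity = 8) {
  stopifnot(inherits(mask, "binary_mask"))
  method <- match.arg(method)
  if (method == "median") {
    px <- median3x3(mask$pixels)
  } else {
    if (min_size_px < 0) stop("`min_size_px` must be >= 0", call. = FALSE)
    px <- mask$pixels
    if (min_size_px > 0 && any(px)) {
      labels <- .label_components(px, as.integer(connectivity))
      sizes <- tabulate(labels[labels > 0L])
      keep <- which(sizes >= min_size_px)
      px <- matrix(labels %in% keep, nrow(px), ncol(px))
    }
  }
  binary_mask(px, threshold = mask$threshold, polarity = mask$polarity,
              pixel_pitch_um = mask$pixel_pitch_um)
}

# 3x3 binary median (= majority of the 9-neighborhood, edges padded with
# the pixel's own row/column replicated).
median3x3 <- function(px) {
  nr <- nrow(px)
  nc <- ncol(px)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  pad[1L, ] <- pad[2L, ]; pad[nr + 2L, ] <- pad[nr + 1L, ]
  pad[, 1L] <- pad[, 2L]; pad[, nc + 2L] <- pad[, nc + 1L]
  acc <- matrix(0L, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + pad[(1:nr) + dr, (1:nc) + dc]
  }
  acc >= 5L
}

#' Extract particles (crack areas) from a binary mask
#'
#' Labels connected foreground components and reports, per particle, its
#' pixel area, physically calibrated area in mm^2, centroid and bounding
#' box — the information ImageJ's particle analysis routine exports.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 4 or 8 (default 8, the ImageJ default).
#' @param pixel_pitch_um Physical pixel width in micrometers; defaults to
#'   the pitch carried by the mask.
#' @param image_id Identifier recorded with the particle set.
#' @return An object of class `particle_set`: list with `particles` (a
#'   data frame with columns `label`, `area_px`, `area_mm2`,
#'   `centroid_row`, `centroid_col`, `bbox_rmin`, `bbox_rmax`,
#'   `bbox_cmin`, `bbox_cmax`), `image_id`, `pixel_pitch_um` and
#'   `total_area_mm2`. An empty mask yields an empty particle set.
#' @export
label_particles <- function(mask, connectivity = 8, pixel_pitch_um = NULL,
                            image_id = "") {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  pitch <- pixel_pitch_um %||% mask$pixel_pitch_um
  if (!is.numeric(pitch) || length(pitch) != 1L || is.na(pitch) ||
      pitch <= 0) {
    stop("a positive `pixel_pitch_um` is required (none carried by mask)",
         call. = FALSE)
  }
  labels <- .label_components(mask$pixels, as.integer(connectivity))
  n_lab <- max(labels)
  if (n_lab == 0L) {
    particles <- data.frame(
      label = integer(), area_px = integer(), area_mm2 = numeric(),
      centroid_row = numeric(), centroid_col = numeric(),
      bbox_rmin = integer(), bbox_rmax = integer(),
      bbox_cmin = integer(), bbox_cmax = integer()
    )
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    rows <- (idx - 1L) %% nrow(labels) + 1L
    cols <- (idx - 1L) %/% nrow(labels) + 1L
    area_px <- tabulate(lab, nbins = n_lab)
    particles <- data.frame(
      label = seq_len(n_lab),
      area_px = area_px,
      area_mm2 = area_px * (pitch / 1000)^2,
      centroid_row = as.numeric(rowsum(rows, lab)) / area_px,
      centroid_col = as.numeric(rowsum(cols, lab)) / area_px,
      bbox_rmin = as.integer(tapply(rows, lab, min)),
      bbox_rmax = as.integer(tapply(rows, lab, max)),
      bbox_cmin = as.integer(tapply(cols, lab, min)),
      bbox_cmax = as.integer(tapply(cols, lab, max))
    )
  }
  structure(list(particles = particles, image_id = image_id,
                 pixel_pitch_um = pitch,
                 total_area_mm2 = sum(particles$area_px) * (pitch / 1000)^2),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> '%s': %d particles, total %.4g mm^2\n",
              x$image_id, nrow(x$particles), x$total_area_mm2))
  invisible(x)
}

#' Total cracked area of a particle set
#'
#' @param ps A [particle_set()][label_particles()].
#' @return Sum of member areas in mm^2 (0 for an empty set). The sum is
#'   taken over integer pixel counts before unit conversion, so it is
#'   exact in pixel units.
#' @export
total_cracked_area <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  sum(ps$particles$area_px) * (ps$pixel_pitch_um / 1000)^2
}

#' Segment a grayscale image into crack particles
#'
#' Convenience wrapper chaining the workflow stages: optional circular ROI,
#' Otsu thresholding, binarization, noise reduction and particle labeling.
#'
#' @param gray An [image_gray()].
#' @param roi Optional [circular_roi()]; `NULL` analyzes the whole frame.
#' @param background_value Fill value outside the ROI (see [apply_roi()]).
#' @param polarity Foreground polarity (see [binarize()]).
#' @param min_size_px Noise-reduction size cutoff (see [denoise()]).
#' @param connectivity 4 or 8.
#' @param image_id Identifier recorded with the result.
#' @return A `particle_set` (see [label_particles()]).
#' @export
segment_cracks <- function(gray, roi = NULL, background_value = 255,
                           polarity = "dark_foreground", min_size_px = 2,
                           connectivity = 8, image_id = "") {
  stopifnot(inherits(gray, "image_gray"))
  if (!is.null(roi)) gray <- apply_roi(gray, roi, background_value)
  level <- otsu_threshold(gray)
  mask <- binarize(gray, level, polarity)
  mask <- denoise(mask, min_size_px = min_size_px,
                  connectivity = connectivity)
  label_particles(mask, connectivity = connectivity, image_id = image_id)
}
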