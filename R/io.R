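# Readers and writers: standard image formats (PNG/TIFF/JPEG), particle
# tables, area samples, Lab coordinate tables, force-curve tables and fit
# reports. CSV is the interchange format throughout; fit reports are JSON.

#' Read an image file as a calibrated grayscale image
#'
#' Reads 8-bit PNG, TIFF or JPEG (RGB, RGBA or grayscale); RGB images are
#' converted with [rgb_to_gray()], an alpha channel is dropped.
#'
#' @param path Image file path; format chosen by extension.
#' @param pixel_pitch_um Physical pixel width in micrometers.
#' @return An [image_gray()].
#' @export
read_image <- function(path, pixel_pitch_um) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  raw <- raw * 255
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 4L) raw <- raw[, , 1:3]          # drop alpha
    if (dim(raw)[3] == 1L) {
      image_gray(round(raw[, , 1]), pixel_pitch_um)
    } else {
      rgb_to_gray(raw, pixel_pitch_um)
    }
  } else {
    image_gray(round(raw), pixel_pitch_um)
  }
}

#' Write a grayscale image to PNG
#'
#' @param img An [image_gray()].
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "image_gray"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Write a particle table to CSV
#'
#' Columns: `image_id`, `label`, `area_px`, `area_mm2`, `centroid_row`,
#' `centroid_col`.
#'
#' @param ps A `particle_set` (see [label_particles()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(ps, path) {
  stopifnot(inherits(ps, "particle_set"))
  p <- ps$particles
  out <- data.frame(image_id = rep(ps$image_id, nrow(p)),
                    label = p$label, area_px = p$area_px,
                    area_mm2 = p$area_mm2,
                    centroid_row = p$centroid_row,
                    centroid_col = p$centroid_col)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read crack areas from a CSV table
#'
#' Accepts either a particle table written by [write_particles_csv()] or
#' any CSV with an `area_mm2` column (and optionally `image_id`).
#'
#' @param path CSV path.
#' @return Data frame with columns `image_id` and `area_mm2`.
#' @export
read_areas_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"area_mm2" %in% names(df)) {
    stop("CSV must contain an `area_mm2` column", call. = FALSE)
  }
  if (!"image_id" %in% names(df)) df$image_id <- ""
  df[c("image_id", "area_mm2")]
}

#' Read named CIELAB coordinates from CSV
#'
#' Expects columns `name`, `L`, `a`, `b`.
#'
#' @param path CSV path.
#' @return Named list of [lab_color()] objects.
#' @export
read_lab_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "L", "a", "b")
  if (!all(need %in% names(df))) {
    stop("CSV must contain columns name, L, a, b", call. = FALSE)
  }
  setNames(lapply(seq_len(nrow(df)),
                  function(i) lab_color(df$L[i], df$a[i], df$b[i])),
           df$name)
}

#' Read force-deformation curves from CSV
#'
#' Expects columns `distance_mm` and `force_N`, plus an optional
#' `curve_id` for long-format files holding several curves.
#'
#' @param path CSV path.
#' @return Named list of [force_curve()] objects.
#' @export
read_force_curves_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("distance_mm", "force_N") %in% names(df))) {
    stop("CSV must contain columns distance_mm and force_N", call. = FALSE)
  }
  if (!"curve_id" %in% names(df)) df$curve_id <- "curve_001"
  lapply(split(df, df$curve_id),
         function(d) force_curve(d$distance_mm, d$force_N))
}

#' Write fit reports to JSON
#'
#' @param reports A list of [fit_areas()] reports (or one report).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_reports_json <- function(reports, path) {
  if (inherits(reports, "fit_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    list(sample_id = r$sample_id, group = r$group, n = r$n,
         total_area_mm2 = r$total_area_mm2,
         lognormal = unclass(r$lognormal),
         powerlaw = unclass(r$powerlaw))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the per-group coefficient table to CSV
#'
#' Writes the group-level coefficient layout (`group`, `xmin`, `alpha`,
#' `D`, `mu_star`, `sigma_star`, `total_area_mm2`, `n_samples`).
#'
#' @param summary Output of [summarize_groups()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_group_table_csv <- function(summary, path) {
  write.csv(summary$by_group, path, row.names = FALSE)
  invisible(path)
}
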