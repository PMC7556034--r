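# Run configuration: flat YAML key-value files with validated defaults.

config_defaults <- function() {
  list(
    dpi = 400,                      # scan resolution; pitch = 25400/dpi um
    pixel_pitch_um = NULL,          # set directly instead of dpi (exclusive)
    roi_diameter_mm = NULL,         # NULL = analyze the whole frame
    background_value = 255,
    min_size_px = 2,
    connectivity = 8,
    polarity = "dark_foreground",
    min_tail_size = 10,
    significance = 0.05,
    k_L = 1, k_C = 1, k_H = 1,
    contact_threshold_N = 0.05,
    seed = 1,
    out_dir = ".",
    log_level = "INFO"
  )
}

#' Load and validate a run configuration
#'
#' Reads a flat YAML key-value file, applies defaults for absent keys,
#' rejects unknown keys, and validates every value. Exactly one of `dpi`
#' and `pixel_pitch_um` may be set; the effective pixel pitch is stored in
#' `pixel_pitch_um` either way (25400/dpi micrometers when derived). An
#' empty or missing-key file yields all defaults (400 dpi, Otsu with
#' dark-foreground polarity, 2 px noise cutoff, 8-connectivity, tail size
#' 10 at significance 0.05, unit parametric color factors, 0.05 N contact
#' trigger).
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path) %||% list()
    if (!is.list(user)) stop("config must be a flat key-value mapping",
                             call. = FALSE)
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(user$dpi) && !is.null(user$pixel_pitch_um)) {
    stop("config error in `dpi`/`pixel_pitch_um`: set exactly one",
         call. = FALSE)
  }
  if (!is.null(user$pixel_pitch_um)) cfg$dpi <- NULL
  cfg[names(user)] <- user
  if (is.null(cfg$pixel_pitch_um)) {
    cfg$pixel_pitch_um <- pitch_from_dpi(cfg$dpi)
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  bad <- function(key, why) {
    stop(sprintf("config error in `%s`: %s", key, why), call. = FALSE)
  }
  pos <- function(key) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
                        v <= 0)) bad(key, "must be a positive number")
  }
  for (key in c("dpi", "pixel_pitch_um", "roi_diameter_mm", "k_L", "k_C",
                "k_H")) pos(key)
  if (cfg$background_value < 0 || cfg$background_value > 255) {
    bad("background_value", "must lie in [0, 255]")
  }
  if (cfg$min_size_px < 0) bad("min_size_px", "must be >= 0")
  if (!cfg$connectivity %in% c(4, 8)) bad("connectivity", "must be 4 or 8")
  if (!cfg$polarity %in% c("dark_foreground", "light_foreground")) {
    bad("polarity", "must be dark_foreground or light_foreground")
  }
  if (cfg$min_tail_size < 2) bad("min_tail_size", "must be >= 2")
  if (!cfg$significance %in% c(0.1, 0.05, 0.01)) {
    bad("significance", "must be one of 0.10, 0.05, 0.01")
  }
  if (cfg$contact_threshold_N < 0) bad("contact_threshold_N", "must be >= 0")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      !is.finite(cfg$seed)) bad("seed", "must be a single finite number")
  if (!is.character(cfg$out_dir)) bad("out_dir", "must be a path")
  if (!cfg$log_level %in% c("DEBUG", "INFO", "WARN", "ERROR")) {
    bad("log_level", "must be DEBUG, INFO, WARN or ERROR")
  }
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (key in names(x)) {
    if (!is.null(x[[key]])) cat(sprintf("  %s: %s\n", key, format(x[[key]])))
  }
  invisible(x)
}
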