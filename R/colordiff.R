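# CIELAB color differences: Euclidean CIE76 distance with perceptibility
# banding, and the full CIEDE2000 formula with all intermediates exposed.

#' CIELAB color
#'
#' @param L_star Lightness in \[0, 100\].
#' @param a_star Red/green opponent axis.
#' @param b_star Blue/yellow opponent axis.
#' @return An object of class `lab_color`.
#' @export
lab_color <- function(L_star, a_star, b_star) {
  vals <- c(L_star, a_star, b_star)
  if (length(vals) != 3L || !is.numeric(vals) || anyNA(vals)) {
    stop("a Lab color needs three numeric coordinates", call. = FALSE)
  }
  if (L_star < 0 || L_star > 100) {
    stop("`L_star` must lie in [0, 100]", call. = FALSE)
  }
  structure(list(L_star = L_star, a_star = a_star, b_star = b_star),
            class = "lab_color")
}

#' @export
print.lab_color <- function(x, ...) {
  cat(sprintf("<lab_color> L* = %.2f, a* = %.2f, b* = %.2f\n",
              x$L_star, x$a_star, x$b_star))
  invisible(x)
}

as_lab <- function(x) {
  if (inherits(x, "lab_color")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(lab_color(x[1], x[2], x[3]))
  stop("expected a lab_color or a numeric (L, a, b) triplet", call. = FALSE)
}

#' CIE76 color difference
#'
#' Euclidean distance in CIELAB space,
#' `sqrt(dL^2 + da^2 + db^2)`.
#'
#' @param c1,c2 [lab_color()] objects (or numeric `(L, a, b)` triplets).
#' @return Non-negative difference value.
#' @export
delta_e76 <- function(c1, c2) {
  c1 <- as_lab(c1)
  c2 <- as_lab(c2)
  sqrt((c1$L_star - c2$L_star)^2 + (c1$a_star - c2$a_star)^2 +
         (c1$b_star - c2$b_star)^2)
}

#' CIEDE2000 color difference
#'
#' The CIE 2001-recommended perceptual color-difference formula:
#' chroma-dependent `G` correction of the a* axis, hue angles from
#' `atan2` in degrees on \[0, 360), lightness/chroma/hue weighting
#' functions `S_L`, `S_C`, `S_H`, the blue-region rotation term `R_T`,
#' and parametric factors `k_L`, `k_C`, `k_H` (all 1 under reference
#' viewing conditions). The hue mean and hue difference use the standard
#' branch rules for angles more than 180 degrees apart; when either
#' corrected chroma is zero the hue difference is zero and the hue mean
#' degenerates to the sum of the angles.
#'
#' @param c1,c2 [lab_color()] objects (or numeric `(L, a, b)` triplets).
#' @param k_L,k_C,k_H Parametric factors (default 1).
#' @return An object of class `color_difference`: list with `dE00`,
#'   `dE76`, the signed differences `dLp` (lightness), `dCp` (corrected
#'   chroma), `dhp` (hue angle, degrees), `dHp` (hue), and an
#'   `intermediates` list (`G`, `a1p`, `a2p`, `C1p`, `C2p`, `h1p`, `h2p`,
#'   `Lbar`, `Cbar`, `hbar`, `T`, `S_L`, `S_C`, `S_H`, `R_T`, `k_L`,
#'   `k_C`, `k_H`). `dE00` is symmetric in the two colors; the signed
#'   differences change sign when the arguments are swapped.
#' @export
delta_e00 <- function(c1, c2, k_L = 1, k_C = 1, k_H = 1) {
  c1 <- as_lab(c1)
  c2 <- as_lab(c2)
  deg <- function(rad) rad * 180 / pi
  rad <- function(deg) deg * pi / 180

  C1 <- sqrt(c1$a_star^2 + c1$b_star^2)
  C2 <- sqrt(c2$a_star^2 + c2$b_star^2)
  Cbar_ab <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar_ab^7 / (Cbar_ab^7 + 25^7)))
  a1p <- (1 + G) * c1$a_star
  a2p <- (1 + G) * c2$a_star
  C1p <- sqrt(a1p^2 + c1$b_star^2)
  C2p <- sqrt(a2p^2 + c2$b_star^2)
  hue <- function(ap, b) {
    if (ap == 0 && b == 0) return(0)
    h <- deg(atan2(b, ap))
    if (h < 0) h + 360 else h
  }
  h1p <- hue(a1p, c1$b_star)
  h2p <- hue(a2p, c2$b_star)

  dLp <- c2$L_star - c1$L_star
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) {
    0
  } else {
    dh <- h2p - h1p
    if (abs(dh) <= 180) dh else if (dh > 180) dh - 360 else dh + 360
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(rad(dhp) / 2)

  Lbar <- (c1$L_star + c2$L_star) / 2
  Cbar <- (C1p + C2p) / 2
  hbar <- if (C1p * C2p == 0) {
    h1p + h2p
  } else if (abs(h1p - h2p) <= 180) {
    (h1p + h2p) / 2
  } else if (h1p + h2p < 360) {
    (h1p + h2p + 360) / 2
  } else {
    (h1p + h2p - 360) / 2
  }

  T <- 1 - 0.17 * cos(rad(hbar - 30)) + 0.24 * cos(rad(2 * hbar)) +
    0.32 * cos(rad(3 * hbar + 6)) - 0.20 * cos(rad(4 * hbar - 63))
  dtheta <- 30 * exp(-((hbar - 275) / 25)^2)
  R_C <- 2 * sqrt(Cbar^7 / (Cbar^7 + 25^7))
  S_L <- 1 + 0.015 * (Lbar - 50)^2 / sqrt(20 + (Lbar - 50)^2)
  S_C <- 1 + 0.045 * Cbar
  S_H <- 1 + 0.015 * Cbar * T
  R_T <- -sin(rad(2 * dtheta)) * R_C

  tL <- dLp / (k_L * S_L)
  tC <- dCp / (k_C * S_C)
  tH <- dHp / (k_H * S_H)
  dE00 <- sqrt(tL^2 + tC^2 + tH^2 + R_T * tC * tH)

  structure(list(
    dE00 = dE00, dE76 = delta_e76(c1, c2),
    dLp = dLp, dCp = dCp, dhp = dhp, dHp = dHp,
    intermediates = list(G = G, a1p = a1p, a2p = a2p, C1p = C1p, C2p = C2p,
                         h1p = h1p, h2p = h2p, Lbar = Lbar, Cbar = Cbar,
                         hbar = hbar, T = T, S_L = S_L, S_C = S_C,
                         S_H = S_H, R_T = R_T, k_L = k_L, k_C = k_C,
                         k_H = k_H)
  ), class = "color_difference")
}

#' @export
print.color_difference <- function(x, ...) {
  cat(sprintf(
    "<color_difference> dE00 = %.4f, dE76 = %.4f (%s)\n",
    x$dE00, x$dE76, classify_de76(x$dE76)$band))
  cat(sprintf("  dL' = %.4f, dC' = %.4f, dh' = %.4f deg, dH' = %.4f\n",
              x$dLp, x$dCp, x$dhp, x$dHp))
  invisible(x)
}

# dE76 perceptibility intervals; boundary values fall to the lower band,
# i.e. bands are (lo, hi], with 0 in the first band.
de76_bands <- data.frame(
  band = c("unnoticeable", "experienced-observer", "unexperienced-observer",
           "clearly-noticeable", "different-colors"),
  lo = c(0, 1, 2, 3.5, 5),
  hi = c(1, 2, 3.5, 5, Inf),
  stringsAsFactors = FALSE
)

#' Perceptibility band of a CIE76 color difference
#'
#' Maps a dE76 value to the conventional five perceptibility bands:
#' up to 1 the difference is unnoticeable; up to 2 it is noticed only by
#' an experienced observer; up to 3.5 it is also noticed by an
#' unexperienced observer; up to 5 it is clearly noticeable; above 5 the
#' colors give the impression of being different colors. Boundary values
#' are assigned to the lower band.
#'
#' @param value Non-negative dE76 value.
#' @return List with `band` (character) and `bounds` (the `(lo, hi]`
#'   interval).
#' @export
classify_de76 <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0) {
    stop("`value` must be a single non-negative number", call. = FALSE)
  }
  i <- if (value <= 1) 1L else max(which(de76_bands$lo < value))
  list(band = de76_bands$band[i],
       bounds = c(lo = de76_bands$lo[i], hi = de76_bands$hi[i]))
}

#' Pairwise color-difference panel
#'
#' For every unordered pair of named colors, the CIEDE2000 and CIE76
#' differences together with the absolute lightness, chroma and hue
#' difference terms — the layout used to compare product groups.
#'
#' @param colors Named list of [lab_color()] objects (or `(L, a, b)`
#'   triplets), at least two, with unique names.
#' @param k_L,k_C,k_H Parametric factors passed to [delta_e00()].
#' @return Data frame with one row per pair: `pair`, `dE00`, `dE76`,
#'   `band`, `dLp`, `dCp`, `dhp`, `dHp` (difference terms as absolute
#'   values, matching tabulated panels).
#' @export
difference_panel <- function(colors, k_L = 1, k_C = 1, k_H = 1) {
  if (length(colors) < 2L) {
    stop("need at least two named colors", call. = FALSE)
  }
  nm <- names(colors)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("`colors` must have unique non-empty names", call. = FALSE)
  }
  colors <- lapply(colors, as_lab)
  pairs <- utils::combn(length(colors), 2)
  rows <- apply(pairs, 2, function(ij) {
    d <- delta_e00(colors[[ij[1]]], colors[[ij[2]]],
                   k_L = k_L, k_C = k_C, k_H = k_H)
    data.frame(pair = paste(nm[ij[1]], nm[ij[2]], sep = "-"),
               dE00 = d$dE00, dE76 = d$dE76,
               band = classify_de76(d$dE76)$band,
               dLp = abs(d$dLp), dCp = abs(d$dCp),
               dhp = abs(d$dhp), dHp = abs(d$dHp))
  })
  do.call(rbind, rows)
}
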