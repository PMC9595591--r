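# Shared helpers: coordinate conventions, seeding, interpolation.
#
# Image channels are numeric matrices indexed [ix, iy] with ix running along
# the image x axis (width) and iy along y (height), matching EBImage. Pixel
# indices are 0-based in physical terms: the centre of pixel (i, j) (0-based)
# sits at ((i + 0.5) * pixel_size_um, (j + 0.5) * pixel_size_um).

#' Convert physical coordinates (micrometers) to 1-based pixel indices
#' @noRd
um_to_px <- function(x_um, pixel_size_um) {
  floor(x_um / pixel_size_um) + 1L
}

#' Physical coordinate (um) of the centre of a 1-based pixel index
#' @noRd
px_to_um <- function(ix, pixel_size_um) {
  (ix - 0.5) * pixel_size_um
}

#' Deterministic sub-seed derivation
#'
#' Derives a reproducible 31-bit seed from a master seed and a character key
#' (well id, group label, stage name). Uses a polynomial rolling hash so the
#' derived seed depends only on (master, key), never on evaluation order —
#' this is what makes shared-control bootstrap runs invariant to group order.
#'
#' @param master integer master seed
#' @param key character scalar
#' @return integer in [0, 2^31 - 2]
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(key) == 1L, is.character(key))
  h <- as.double(master %% 2147483647)
  for (cc in utf8ToInt(key)) {
    h <- (h * 31 + cc) %% 2147483647
  }
  as.integer(h)
}

#' Bilinear interpolation of a channel matrix at physical coordinates
#'
#' Samples the image (treated as pixel-centre point samples) at arbitrary
#' micrometer positions. Positions outside the grid clamp to the border.
#'
#' @param img numeric matrix [ix, iy]
#' @param x_um,y_um numeric vectors of physical coordinates
#' @param pixel_size_um micrometers per pixel
#' @return numeric vector of interpolated intensities
#' @export
interp_bilinear <- function(img, x_um, y_um, pixel_size_um) {
  w <- nrow(img); h <- ncol(img)
  # continuous pixel coordinate of a position, in units where pixel centre k
  # (1-based) is at k
  fx <- x_um / pixel_size_um + 0.5
  fy <- y_um / pixel_size_um + 0.5
  fx <- pmin(pmax(fx, 1), w)
  fy <- pmin(pmax(fy, 1), h)
  x0 <- pmin(floor(fx), w - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(fy), h - 1L); y1 <- y0 + 1
  tx <- fx - x0; ty <- fy - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x1, y0)
  i01 <- cbind(x0, y1); i11 <- cbind(x1, y1)
  img[i00] * (1 - tx) * (1 - ty) + img[i10] * tx * (1 - ty) +
    img[i01] * (1 - tx) * ty + img[i11] * tx * ty
}

#' Arc length of a polyline given as an n x 2 matrix of (x, y) in um
#' @noRd
polyline_length <- function(xy) {
  if (is.null(xy) || nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Resample a polyline at (approximately) fixed arc-length steps
#'
#' Returns positions, cumulative arc length and unit tangents. Used by the
#' varicosity detector to walk skeleton branches at sub-pixel resolution.
#' @noRd
resample_polyline <- function(xy, step_um) {
  seg <- sqrt(rowSums(diff(xy)^2))
  keep <- seg > 0
  if (!any(keep)) {
    return(list(xy = xy[1, , drop = FALSE], s = 0,
                tangent = matrix(c(1, 0), 1)))
  }
  # drop zero-length duplicate vertices
  xy <- xy[c(TRUE, keep), , drop = FALSE]
  seg <- seg[keep]
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  n_out <- max(2L, ceiling(total / step_um) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  x <- stats::approx(cs, xy[, 1], xout = s_out)$y
  y <- stats::approx(cs, xy[, 2], xout = s_out)$y
  dx <- c(x[2] - x[1], diff(x))
  dy <- c(y[2] - y[1], diff(y))
  nrm <- sqrt(dx^2 + dy^2)
  nrm[nrm == 0] <- 1
  list(xy = cbind(x, y), s = s_out, tangent = cbind(dx / nrm, dy / nrm))
}

#' Stop unless a condition holds, with a formatted message
#' @noRd
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}
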