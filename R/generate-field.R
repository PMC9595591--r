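# Synthetic multichannel neuron-field generator.
#
# Renders four channels (neurochemical marker, MAP2, Syt-1, nuclei) on a
# supersampled grid: neurites are splatted as Gaussian-profile curves of
# sub-resolution width, varicosities as oriented Gaussian enlargements added
# at their nominal FWHM (so measured widths match planted widths), somata and
# nuclei as soft-edged disks. The camera model is a constant background with
# additive Gaussian read noise; channels are scanned "sequentially", i.e. no
# bleed-through is simulated.

FINE_FACTOR <- 3L          # supersampling factor for rendering
LINE_FWHM_UM <- 0.25       # rendered neurite width (sub-resolution at 0.3 um/px)
LINE_AMP <- 40             # neurite ridge peak over background
SOMA_AMP <- 200            # soma plateau over background (marker channel)
MAP2_SOMA_AMP <- 120
NUCLEUS_AMP <- 150
VARICOSITY_AMP_FACTOR <- 2.5  # varicosity peak relative to LINE_AMP

#' Generate one synthetic multichannel neuron field with ground truth
#'
#' Produces an `image_field` (marker, MAP2, Syt-1 and nuclei channels) and the
#' matching `ground_truth`: soma centers, neurite centerline polylines with
#' per-chain lengths, varicosity records (position, width, length, Syt-1
#' intensity and class) and per-field totals. Identical seeds give
#' bit-identical output.
#'
#' @param spec a [field_spec()]
#' @return list with elements `field` (class `image_field`) and `truth`
#'   (class `ground_truth`)
#' @examples
#' fg <- generate_field(field_spec(n_neurons = 4, neurite_total_length_um = 600,
#'                                 seed = 42))
#' dim(fg$field$channels$marker)
#' fg$truth$total_neurite_length_um
#' @export
generate_field <- function(spec) {
  validate_field_spec(spec)
  set.seed(spec$seed)
  W <- spec$width_px; H <- spec$height_px; psz <- spec$pixel_size_um
  fx <- FINE_FACTOR
  fW <- W * fx; fH <- H * fx; fpsz <- psz / fx
  w_um <- W * psz; h_um <- H * psz

  somata <- place_somata(spec$n_neurons, w_um, h_um)
  polylines <- grow_neurites(spec, somata, w_um, h_um)
  total_len <- sum(vapply(polylines, polyline_length, numeric(1)))
  varic <- place_varicosities(spec, polylines)

  sigma_l <- LINE_FWHM_UM / (2 * sqrt(2 * log(2)))

  # --- marker channel ---------------------------------------------------
  marker_f <- matrix(0, fW, fH)
  if (length(polylines)) {
    lam <- LINE_AMP * sqrt(2 * pi) * sigma_l      # linear density for peak A
    pts <- polyline_samples(polylines, ds = 0.05)
    marker_f <- splat_nearest(marker_f, pts[, 1], pts[, 2], fpsz,
                              rep(lam * 0.05, nrow(pts)))
    marker_f <- as.matrix(EBImage::gblur(marker_f, sigma = sigma_l / fpsz))
  }
  if (nrow(varic)) {
    marker_f <- add_oriented_blobs(marker_f, varic$x_um, varic$y_um,
                                   varic$length_um, varic$width_um,
                                   varic$theta,
                                   amp = LINE_AMP * VARICOSITY_AMP_FACTOR *
                                     varic$brightness, fpsz)
  }
  # --- Syt-1 channel: signal only at varicosity sites -------------------
  syt1_f <- matrix(0, fW, fH)
  if (nrow(varic)) {
    syt1_f <- add_oriented_blobs(syt1_f, varic$x_um, varic$y_um,
                                 varic$length_um, varic$width_um,
                                 varic$theta, amp = varic$syt1_intensity, fpsz)
  }

  # disk-scale structures (>= 2.5 um radius) are rendered directly on the
  # coarse grid; only sub-resolution structure needs the supersampled grid
  marker <- bin_fine(marker_f, fx, W, H)
  if (nrow(somata)) {
    marker <- add_disks(marker, somata$x_um, somata$y_um,
                        somata$radius_um, SOMA_AMP, psz)
  }
  map2 <- matrix(0, W, H)
  if (nrow(somata)) {
    map2 <- add_disks(map2, somata$x_um, somata$y_um,
                      somata$radius_um * 1.1, MAP2_SOMA_AMP, psz)
  }
  nuc_x <- c(somata$x_um, stats::runif(spec$n_nuclei, 0, w_um))
  nuc_y <- c(somata$y_um, stats::runif(spec$n_nuclei, 0, h_um))
  nuclei <- matrix(0, W, H)
  if (length(nuc_x)) {
    nuclei <- add_disks(nuclei, nuc_x, nuc_y,
                        stats::runif(length(nuc_x), 2.5, 4.5),
                        NUCLEUS_AMP, psz)
  }

  camera <- function(coarse) {
    coarse + spec$background_level +
      matrix(stats::rnorm(W * H, 0, spec$noise_sd), W, H)
  }
  field <- structure(list(
    channels = list(marker = camera(marker), map2 = camera(map2),
                    syt1 = camera(bin_fine(syt1_f, fx, W, H)),
                    nuclei = camera(nuclei)),
    pixel_size_um = psz, width_px = W, height_px = H),
    class = "image_field")

  truth <- structure(list(
    soma_centers = somata,
    skeleton_polylines = polylines,
    polyline_lengths_um = vapply(polylines, polyline_length, numeric(1)),
    varicosities = varic,
    n_neurons = nrow(somata),
    total_neurite_length_um = total_len,
    n_varicosities = nrow(varic)),
    class = "ground_truth")
  list(field = field, truth = truth)
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("image_field: %d x %d px @ %.3g um/px, channels: %s\n",
              x$width_px, x$height_px, x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("ground_truth: %d somata, %.0f um neurite ",
                     "(%d polylines), %d varicosities\n"),
              x$n_neurons, x$total_neurite_length_um,
              length(x$skeleton_polylines), x$n_varicosities))
  invisible(x)
}

# Rejection-sample soma centers with pairwise clearance; the clearance is
# relaxed geometrically if the field is too crowded, so placement always
# terminates (possibly with touching somata, which the census contract allows).
place_somata <- function(n, w_um, h_um) {
  if (n == 0) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0)))
  }
  radius <- stats::runif(n, 4, 7.5)
  clearance <- 5
  repeat {
    x <- numeric(n); y <- numeric(n); ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      m <- radius[i] + 1.5
      for (try in seq_len(200)) {
        xi <- stats::runif(1, m, w_um - m)
        yi <- stats::runif(1, m, h_um - m)
        if (i == 1 || all(sqrt((x[seq_len(i - 1)] - xi)^2 +
                               (y[seq_len(i - 1)] - yi)^2) >
                          radius[seq_len(i - 1)] + radius[i] + clearance)) {
          x[i] <- xi; y[i] <- yi; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
    clearance <- clearance * 0.5
    if (clearance < 0.1) {  # give up on separation, place uniformly
      x <- stats::runif(n, 8, w_um - 8); y <- stats::runif(n, 8, h_um - 8)
      break
    }
  }
  data.frame(x_um = x, y_um = y, radius_um = radius)
}

# Grow branched neurites as smoothed random walks from each soma edge.
# Curvature is bounded; branch events follow a Poisson process per unit
# length; walks steer back when near the field border and away from somata
# (axons skirt cell bodies rather than crossing them). Each neuron consumes
# an equal share of the total length budget, so the summed polyline length
# tracks the target to within one step per neuron.
grow_neurites <- function(spec, somata, w_um, h_um) {
  n <- nrow(somata)
  if (n == 0 || spec$neurite_total_length_um <= 0) return(list())
  ds <- 1.0                      # um per step
  curv_sd <- 0.22                # rad per step, clamped below
  margin <- 2
  polylines <- list()
  budget_each <- spec$neurite_total_length_um / n
  for (i in seq_len(n)) {
    budget <- budget_each
    a0 <- stats::runif(1, 0, 2 * pi)
    tips <- list(list(
      x = somata$x_um[i] + somata$radius_um[i] * cos(a0),
      y = somata$y_um[i] + somata$radius_um[i] * sin(a0),
      heading = a0))
    while (budget > 0 && length(tips)) {
      tip <- tips[[1]]; tips <- tips[-1]
      px <- tip$x; py <- tip$y; heading <- tip$heading
      verts_x <- px; verts_y <- py
      while (budget > 0) {
        heading <- heading + max(-0.5, min(0.5, stats::rnorm(1, 0, curv_sd)))
        # steer back toward the field centre near borders
        nx <- px + ds * cos(heading); ny <- py + ds * sin(heading)
        if (nx < margin || nx > w_um - margin ||
            ny < margin || ny > h_um - margin) {
          heading <- atan2(h_um / 2 - py, w_um / 2 - px) +
            stats::rnorm(1, 0, 0.3)
          nx <- px + ds * cos(heading); ny <- py + ds * sin(heading)
        }
        # steer away from any soma the step would enter
        d2 <- (somata$x_um - nx)^2 + (somata$y_um - ny)^2
        hit <- which(d2 < (somata$radius_um + 2.5)^2)
        if (length(hit)) {
          j <- hit[which.min(d2[hit])]
          heading <- atan2(py - somata$y_um[j], px - somata$x_um[j]) +
            stats::rnorm(1, 0, 0.3)
          nx <- px + ds * cos(heading); ny <- py + ds * sin(heading)
        }
        px <- nx; py <- ny
        verts_x <- c(verts_x, px); verts_y <- c(verts_y, py)
        budget <- budget - ds
        if (stats::runif(1) < spec$branch_prob_per_um * ds) {
          turn <- sample(c(-1, 1), 1) * stats::runif(1, 0.4, 1.1)
          tips <- c(tips, list(list(x = px, y = py,
                                    heading = heading + turn)))
        }
      }
      if (length(verts_x) >= 2) {
        polylines[[length(polylines) + 1L]] <- cbind(x = verts_x, y = verts_y)
      }
    }
  }
  polylines
}

# Plant varicosities along each polyline: gamma-distributed arc-length gaps
# around the requested mean spacing, geometry drawn uniformly from the spec
# ranges, Syt-1 intensity from the positive/negative mixture.
place_varicosities <- function(spec, polylines) {
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      theta = numeric(0), width_um = numeric(0),
                      length_um = numeric(0), syt1_intensity = numeric(0),
                      is_syt1_positive = logical(0), oversize = logical(0),
                      polyline_id = integer(0),
                      arc_pos_um = numeric(0), brightness = numeric(0))
  if (!length(polylines)) return(empty)
  out <- list()
  shape <- 9  # gap CV = 1/3: spacing jitter without frequent near-collisions
  for (pid in seq_along(polylines)) {
    xy <- polylines[[pid]]
    L <- polyline_length(xy)
    if (L < 2) next
    gaps <- c()
    s <- stats::rgamma(1, shape, scale = spec$varicosity_spacing_um / shape) / 2
    while (s < L - 1) {
      gaps <- c(gaps, s)
      s <- s + stats::rgamma(1, shape, scale = spec$varicosity_spacing_um / shape)
    }
    if (!length(gaps)) next
    rp <- resample_polyline(xy, 0.25)
    k <- length(gaps)
    idx <- vapply(gaps, function(si) which.min(abs(rp$s - si)), integer(1))
    # oversize swellings sit outside the morphological gate and never carry
    # Syt-1 above the negative (nonspecific) component
    oversize <- stats::runif(k) < spec$oversize_fraction
    pos <- stats::rbinom(k, 1, spec$syt1_pos_fraction) == 1 & !oversize
    mu <- ifelse(pos, spec$syt1_pos_mean, spec$syt1_neg_mean)
    width <- ifelse(oversize, stats::runif(k, 1.5, 2.0),
                    stats::runif(k, spec$varicosity_width_range_um[1],
                                 spec$varicosity_width_range_um[2]))
    out[[length(out) + 1L]] <- data.frame(
      x_um = rp$xy[idx, 1], y_um = rp$xy[idx, 2],
      theta = atan2(rp$tangent[idx, 2], rp$tangent[idx, 1]),
      width_um = width,
      length_um = stats::runif(k, spec$varicosity_length_range_um[1],
                               spec$varicosity_length_range_um[2]),
      syt1_intensity = pmax(0, stats::rnorm(k, mu, spec$syt1_sd)),
      is_syt1_positive = pos, oversize = oversize,
      polyline_id = pid, arc_pos_um = gaps,
      brightness = stats::runif(k, 0.9, 1.3))
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Concatenate fixed-step resamplings of all polylines (for line splatting)
polyline_samples <- function(polylines, ds) {
  do.call(rbind, lapply(polylines, function(xy) resample_polyline(xy, ds)$xy))
}

# Deposit point masses at nearest fine-grid pixels (value = mass / px area),
# aggregated with rowsum so arbitrarily many samples stay fast.
splat_nearest <- function(acc, x_um, y_um, fpsz, mass) {
  fW <- nrow(acc); fH <- ncol(acc)
  ix <- pmin(pmax(floor(x_um / fpsz) + 1L, 1L), fW)
  iy <- pmin(pmax(floor(y_um / fpsz) + 1L, 1L), fH)
  idx <- (iy - 1L) * fW + ix
  r <- rowsum(mass / fpsz^2, idx)
  acc[as.integer(rownames(r))] <- acc[as.integer(rownames(r))] + r[, 1]
  acc
}

# Add oriented Gaussian blobs: FWHM `len_um` along the local tangent,
# `width_um` across it, peak amplitude `amp` (vectorized over blobs).
add_oriented_blobs <- function(acc, x_um, y_um, len_um, width_um, theta,
                               amp, fpsz) {
  fW <- nrow(acc); fH <- ncol(acc)
  k <- 2 * sqrt(2 * log(2))
  amp <- rep_len(amp, length(x_um))
  for (i in seq_along(x_um)) {
    sl <- len_um[i] / k; sw <- width_um[i] / k
    ext <- 3.5 * max(sl, sw)
    ix0 <- max(1L, floor((x_um[i] - ext) / fpsz) + 1L)
    ix1 <- min(fW, floor((x_um[i] + ext) / fpsz) + 1L)
    iy0 <- max(1L, floor((y_um[i] - ext) / fpsz) + 1L)
    iy1 <- min(fH, floor((y_um[i] + ext) / fpsz) + 1L)
    if (ix1 < ix0 || iy1 < iy0) next
    xs <- px_to_um(ix0:ix1, fpsz) - x_um[i]
    ys <- px_to_um(iy0:iy1, fpsz) - y_um[i]
    ct <- cos(theta[i]); st <- sin(theta[i])
    u <- outer(xs * ct, ys * st, "+")
    v <- outer(-xs * st, ys * ct, "+")
    acc[ix0:ix1, iy0:iy1] <- acc[ix0:ix1, iy0:iy1] +
      amp[i] * exp(-(u^2 / (2 * sl^2) + v^2 / (2 * sw^2)))
  }
  acc
}

# Add soft-edged disks (logistic edge profile, 0.15 um edge width)
add_disks <- function(acc, x_um, y_um, radius_um, amp, fpsz) {
  fW <- nrow(acc); fH <- ncol(acc)
  amp <- rep_len(amp, length(x_um))
  for (i in seq_along(x_um)) {
    r <- radius_um[i]; ext <- r + 1.5
    ix0 <- max(1L, floor((x_um[i] - ext) / fpsz) + 1L)
    ix1 <- min(fW, floor((x_um[i] + ext) / fpsz) + 1L)
    iy0 <- max(1L, floor((y_um[i] - ext) / fpsz) + 1L)
    iy1 <- min(fH, floor((y_um[i] + ext) / fpsz) + 1L)
    if (ix1 < ix0 || iy1 < iy0) next
    xs <- px_to_um(ix0:ix1, fpsz) - x_um[i]
    ys <- px_to_um(iy0:iy1, fpsz) - y_um[i]
    d <- sqrt(outer(xs^2, ys^2, "+"))
    acc[ix0:ix1, iy0:iy1] <- acc[ix0:ix1, iy0:iy1] +
      amp[i] / (1 + exp((d - r) / 0.15))
  }
  acc
}

#' Generate a single straight neurite with explicitly planted enlargements
#'
#' A controlled scenario for detector validation: one horizontal neurite
#' across the field midline with varicosities at stated arc positions,
#' widths, lengths and Syt-1 intensities (no somata, no branching). Useful
#' when the planted geometry itself is the quantity under test.
#'
#' @param positions_um arc positions of the enlargements from the left edge
#' @param widths_um,lengths_um per-enlargement geometry (recycled)
#' @param syt1_intensities per-enlargement Syt-1 amplitude (recycled)
#' @param width_px,height_px,pixel_size_um raster geometry
#' @param background_level,noise_sd camera model
#' @param seed RNG seed (noise only; geometry is deterministic)
#' @return list with `field` (image_field) and `truth` (ground_truth)
#' @export
generate_neurite_strip <- function(positions_um, widths_um = 0.6,
                                   lengths_um = 1.2, syt1_intensities = 120,
                                   width_px = 384L, height_px = 128L,
                                   pixel_size_um = 0.3,
                                   background_level = 100, noise_sd = 5,
                                   seed = 1L) {
  set.seed(seed)
  W <- as.integer(width_px); H <- as.integer(height_px)
  psz <- pixel_size_um; fx <- FINE_FACTOR; fpsz <- psz / fx
  w_um <- W * psz; h_um <- H * psz
  y0 <- h_um / 2
  k <- length(positions_um)
  varic <- if (k == 0) {
    data.frame(x_um = numeric(0), y_um = numeric(0), theta = numeric(0),
               width_um = numeric(0), length_um = numeric(0),
               syt1_intensity = numeric(0), is_syt1_positive = logical(0),
               oversize = logical(0), polyline_id = integer(0),
               arc_pos_um = numeric(0), brightness = numeric(0))
  } else {
    data.frame(
      x_um = positions_um, y_um = rep(y0, k), theta = rep(0, k),
      width_um = rep_len(widths_um, k), length_um = rep_len(lengths_um, k),
      syt1_intensity = rep_len(syt1_intensities, k),
      is_syt1_positive = rep_len(syt1_intensities, k) > 0,
      oversize = rep_len(widths_um, k) > WIDTH_GATE_UM[2],
      polyline_id = 1L, arc_pos_um = positions_um,
      brightness = rep(1, k))
  }
  polyline <- cbind(x = c(0.5, w_um - 0.5), y = c(y0, y0))
  sigma_l <- LINE_FWHM_UM / (2 * sqrt(2 * log(2)))
  marker_f <- matrix(0, W * fx, H * fx)
  pts <- resample_polyline(polyline, 0.05)$xy
  lam <- LINE_AMP * sqrt(2 * pi) * sigma_l
  marker_f <- splat_nearest(marker_f, pts[, 1], pts[, 2], fpsz,
                            rep(lam * 0.05, nrow(pts)))
  marker_f <- as.matrix(EBImage::gblur(marker_f, sigma = sigma_l / fpsz))
  if (k) {
    marker_f <- add_oriented_blobs(marker_f, varic$x_um, varic$y_um,
                                   varic$length_um, varic$width_um,
                                   varic$theta, amp = LINE_AMP *
                                     VARICOSITY_AMP_FACTOR, fpsz)
  }
  syt1_f <- matrix(0, W * fx, H * fx)
  if (k) {
    syt1_f <- add_oriented_blobs(syt1_f, varic$x_um, varic$y_um,
                                 varic$length_um, varic$width_um,
                                 varic$theta, amp = varic$syt1_intensity,
                                 fpsz)
  }
  camera <- function(coarse) {
    coarse + background_level + matrix(stats::rnorm(W * H, 0, noise_sd), W, H)
  }
  field <- structure(list(
    channels = list(marker = camera(bin_fine(marker_f, fx, W, H)),
                    map2 = camera(matrix(0, W, H)),
                    syt1 = camera(bin_fine(syt1_f, fx, W, H)),
                    nuclei = camera(matrix(0, W, H))),
    pixel_size_um = psz, width_px = W, height_px = H),
    class = "image_field")
  truth <- structure(list(
    soma_centers = data.frame(x_um = numeric(0), y_um = numeric(0),
                              radius_um = numeric(0)),
    skeleton_polylines = list(polyline),
    polyline_lengths_um = polyline_length(polyline),
    varicosities = varic, n_neurons = 0L,
    total_neurite_length_um = polyline_length(polyline),
    n_varicosities = k),
    class = "ground_truth")
  list(field = field, truth = truth)
}

# Average supersampled fine grid down to the coarse raster
bin_fine <- function(fine, fx, W, H) {
  fH <- H * fx
  s1 <- colSums(array(fine, c(fx, W * fH)))       # sum over x sub-pixels
  m2 <- matrix(s1, W, fH)
  s2 <- colSums(array(t(m2), c(fx, H, W)))        # sum over y sub-pixels
  t(s2) / fx^2
}
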