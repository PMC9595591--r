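# Varicosity (axonal bouton) detection, size gating, Syt-1 positivity
# classification, and spacing/density metrics.
#
# A varicosity is an enlargement along a thin neurite. Candidates are local
# intensity maxima along skeleton branches; geometry is measured from the
# intensity profile itself: transverse width as the full width at half
# maximum (FWHM) of the perpendicular profile above background, length as the
# half-maximum extent along the branch above the local neurite baseline. The
# morphological gate keeps widths in [0.2, 1] um; the length gate defaults to
# [0.3, 5] um, with the strict literal range [0.3, 0.5] um available via
# `strict_length_gate` (every output records which gate was applied).

WIDTH_GATE_UM <- c(0.2, 1.0)
LENGTH_GATE_UM <- c(0.3, 5.0)
LENGTH_GATE_STRICT_UM <- c(0.3, 0.5)

#' Morphological size gate for varicosity candidates
#'
#' Pure function of (width, length): width within \[0.2, 1\] um (inclusive)
#' and length within the selected length gate.
#'
#' @param width_um,length_um numeric vectors
#' @param strict_length_gate use the literal \[0.3, 0.5\] um length range
#'   instead of the default \[0.3, 5\] um
#' @return logical vector
#' @export
varicosity_gate <- function(width_um, length_um, strict_length_gate = FALSE) {
  lg <- if (strict_length_gate) LENGTH_GATE_STRICT_UM else LENGTH_GATE_UM
  width_um >= WIDTH_GATE_UM[1] & width_um <= WIDTH_GATE_UM[2] &
    length_um >= lg[1] & length_um <= lg[2]
}

#' Detect varicosities along a neurite skeleton
#'
#' Walks every skeleton segment at sub-pixel steps, finds local maxima of the
#' marker intensity profile that rise above the local neurite baseline by
#' `prominence_factor`, measures each candidate's transverse FWHM and
#' along-branch half-maximum extent, samples the mean Syt-1 intensity over
#' the candidate's footprint, and evaluates the size gate. All candidates are
#' returned, gated or not (the failed ones feed [syt1_cutoff()]).
#'
#' @param field an `image_field`
#' @param skeleton a `skeleton_graph`
#' @param prominence_factor candidate peaks must exceed `prominence_factor *`
#'   the branch's baseline signal over background, and additionally clear the
#'   baseline by 5 image MADs, so line ripple and camera noise do not
#'   masquerade as enlargements (default 2)
#' @param min_separation_um merge maxima closer than this along the branch
#'   (default 1.2 um)
#' @param junction_flag_um candidates within this arc distance of a junction
#'   node are flagged `near_junction`: they count for detection and density,
#'   but their geometry and intensity profiles are corrupted by the crossing
#'   branch, so [classify_syt1()] and [syt1_cutoff()] leave them aside
#'   (default 1)
#' @param strict_length_gate see [varicosity_gate()]
#' @return data.frame of candidates: `x_um`, `y_um`, `width_um`, `length_um`,
#'   `mean_syt1_intensity`, `peak_intensity`, `near_junction`, `passes_gate`,
#'   `gate`
#' @export
detect_varicosities <- function(field, skeleton, prominence_factor = 2,
                                min_separation_um = 1.2,
                                junction_flag_um = 1,
                                strict_length_gate = FALSE) {
  stopifnot(inherits(field, "image_field"), inherits(skeleton, "skeleton_graph"))
  img <- field$channels$marker
  syt1 <- field$channels$syt1
  psz <- field$pixel_size_um
  gate_name <- if (strict_length_gate) "width[0.2,1]_length[0.3,0.5]"
               else "width[0.2,1]_length[0.3,5]"
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      width_um = numeric(0), length_um = numeric(0),
                      mean_syt1_intensity = numeric(0),
                      peak_intensity = numeric(0), near_junction = logical(0),
                      passes_gate = logical(0), gate = character(0))
  if (!length(skeleton$segments)) return(empty)
  bg <- stats::median(img)
  noise <- stats::mad(as.numeric(img))
  out <- list()
  step <- 0.15
  deg <- skeleton$degree
  for (seg in skeleton$segments) {
    if (seg$length_um < 1) next
    rp <- resample_polyline(seg$polyline_um, step)
    junction_start <- deg[seg$path[1]] > 2
    junction_end <- deg[seg$path[length(seg$path)]] > 2
    prof <- interp_bilinear(img, rp$xy[, 1], rp$xy[, 2], psz) - bg
    n <- length(prof)
    if (n < 5) next
    # the inter-varicosity line level: a low quantile, so the estimate stays
    # on the bare neurite even when enlargements cover half the branch
    base <- unname(stats::quantile(prof, 0.25, type = 7))
    if (base <= 0) base <- max(prof) / 10
    thr <- max(prominence_factor * base, base + 5 * noise)
    halfw <- max(3L, round(min_separation_um / step / 2))
    is_peak <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - halfw); hi <- min(n, i + halfw)
      prof[i] >= thr && prof[i] == max(prof[lo:hi])
    }, logical(1))
    idx <- which(is_peak)
    if (!length(idx)) next
    # collapse plateaus / near-duplicate maxima
    if (length(idx) > 1) {
      keep <- c(TRUE, diff(rp$s[idx]) > min_separation_um)
      idx <- idx[keep]
    }
    s_end <- rp$s[length(rp$s)]
    for (i in idx) {
      near_j <- (junction_start && rp$s[i] < junction_flag_um) ||
        (junction_end && s_end - rp$s[i] < junction_flag_um)
      width <- transverse_fwhm(img, rp$xy[i, ], rp$tangent[i, ], psz, bg)
      # extent at half maximum over *background*: the local ridge baseline is
      # too noisy a reference at crossings and would shrink lengths spuriously
      len <- along_extent(prof, rp$s, i, 0)
      if (!is.finite(width) || !is.finite(len)) next
      syt1_mean <- footprint_mean(syt1, rp$xy[i, ], max(width, 0.3) / 2, psz)
      out[[length(out) + 1L]] <- data.frame(
        x_um = rp$xy[i, 1], y_um = rp$xy[i, 2],
        width_um = width, length_um = len,
        mean_syt1_intensity = syt1_mean,
        peak_intensity = prof[i] + bg, near_junction = near_j,
        passes_gate = varicosity_gate(width, len, strict_length_gate),
        gate = gate_name)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # deduplicate detections from segments sharing a junction
  if (nrow(res) > 1) {
    o <- order(-res$peak_intensity)
    res <- res[o, ]
    keep <- rep(TRUE, nrow(res))
    for (i in seq_len(nrow(res) - 1)) {
      if (!keep[i]) next
      j <- (i + 1):nrow(res)
      d <- sqrt((res$x_um[j] - res$x_um[i])^2 + (res$y_um[j] - res$y_um[i])^2)
      keep[j][d < min_separation_um / 2] <- FALSE
    }
    res <- res[keep, ]
    res <- res[order(res$x_um, res$y_um), ]
  }
  rownames(res) <- NULL
  res
}

# FWHM of the background-subtracted transverse intensity profile, by linear
# interpolation of the half-maximum crossings on either side of the peak.
transverse_fwhm <- function(img, center, tangent, psz, bg,
                            half_range_um = 2.5, step_um = 0.05) {
  normal <- c(-tangent[2], tangent[1])
  t_off <- seq(-half_range_um, half_range_um, by = step_um)
  xs <- center[1] + normal[1] * t_off
  ys <- center[2] + normal[2] * t_off
  prof <- interp_bilinear(img, xs, ys, psz) - bg
  c0 <- which.min(abs(t_off))
  # re-centre on the local maximum near the nominal centre
  win <- max(1, c0 - 10):min(length(prof), c0 + 10)
  pk <- win[which.max(prof[win])]
  half <- prof[pk] / 2
  if (prof[pk] <= 0) return(NA_real_)
  left <- NA_real_
  if (pk >= 2) for (i in seq(pk, 2)) {
    if (prof[i - 1] < half) {
      f <- (prof[i] - half) / (prof[i] - prof[i - 1])
      left <- t_off[i] - f * step_um
      break
    }
  }
  right <- NA_real_
  if (pk <= length(prof) - 1) for (i in seq(pk, length(prof) - 1)) {
    if (prof[i + 1] < half) {
      f <- (prof[i] - half) / (prof[i] - prof[i + 1])
      right <- t_off[i] + f * step_um
      break
    }
  }
  # 2 x min half-width: robust to a crossing neurite merging into one flank
  if (is.na(left) && is.na(right)) return(NA_real_)
  hw_l <- t_off[pk] - left
  hw_r <- right - t_off[pk]
  2 * min(hw_l, hw_r, na.rm = TRUE)
}

# Along-branch extent at half maximum above the neurite baseline
along_extent <- function(prof, s, pk, base) {
  half <- base + (prof[pk] - base) / 2
  left <- s[pk]; right <- s[pk]
  found_l <- FALSE
  if (pk >= 2) for (i in seq(pk, 2)) {
    if (prof[i - 1] < half) {
      f <- (prof[i] - half) / (prof[i] - prof[i - 1])
      left <- s[i] - f * (s[i] - s[i - 1]); found_l <- TRUE
      break
    }
  }
  found_r <- FALSE
  if (pk <= length(prof) - 1) for (i in seq(pk, length(prof) - 1)) {
    if (prof[i + 1] < half) {
      f <- (prof[i] - half) / (prof[i] - prof[i + 1])
      right <- s[i] + f * (s[i + 1] - s[i]); found_r <- TRUE
      break
    }
  }
  if (!found_l && !found_r) return(NA_real_)
  # peak at a segment end: mirror the measured half
  if (!found_l) left <- s[pk] - (right - s[pk])
  if (!found_r) right <- s[pk] + (s[pk] - left)
  right - left
}

# Mean raw intensity over a disk footprint
footprint_mean <- function(img, center, radius_um, psz) {
  r <- max(radius_um, psz)
  t_off <- seq(-r, r, by = psz / 2)
  grid <- expand.grid(dx = t_off, dy = t_off)
  grid <- grid[grid$dx^2 + grid$dy^2 <= r^2, ]
  mean(interp_bilinear(img, center[1] + grid$dx, center[2] + grid$dy, psz))
}

#' Syt-1 positivity cutoff from gate-failing candidates
#'
#' The intensity threshold for Syt-1 positivity is estimated from the
#' candidates *excluded* by the size gate, whose Syt-1 signal represents
#' background-like (nonspecific) staining. The default statistic is a robust
#' upper envelope, median + 3 MAD, which tolerates the minority of excluded
#' candidates that are genuine varicosities mis-measured across a gate
#' boundary; order statistics of the raw pool (`"p95"`) and `"mean_2sd"` are
#' available but both chase that contamination when the excluded pool is
#' small. With fewer than `min_excluded` excluded candidates the fall-back is
#' the supplied background mean + 2 SD, flagged in the result.
#'
#' @param excluded data.frame of gate-failing candidates (needs column
#'   `mean_syt1_intensity`)
#' @param method `"robust_envelope"` (default; median + 3 MAD), `"p95"` or
#'   `"mean_2sd"`
#' @param min_excluded minimum excluded candidates before falling back
#' @param background optional `c(mean, sd)` of Syt-1 background for the
#'   fall-back
#' @return list with `cutoff`, `method`, `n_excluded`, `fallback`
#' @export
syt1_cutoff <- function(excluded, method = c("robust_envelope", "p95",
                                             "mean_2sd"),
                        min_excluded = 5L, background = NULL) {
  method <- match.arg(method)
  if (!is.null(excluded$near_junction)) {
    excluded <- excluded[!excluded$near_junction, , drop = FALSE]
  }
  vals <- excluded$mean_syt1_intensity
  if (length(vals) < min_excluded) {
    if (is.null(background)) {
      stop("too few excluded candidates and no background estimate; ",
           "Syt-1 positivity undetermined", call. = FALSE)
    }
    return(list(cutoff = background[1] + 2 * background[2],
                method = "background_mean_2sd",
                n_excluded = length(vals), fallback = TRUE))
  }
  cutoff <- switch(method,
                   robust_envelope = stats::median(vals) +
                     3 * stats::mad(vals),
                   p95 = unname(stats::quantile(vals, 0.95, type = 7)),
                   mean_2sd = mean(vals) + 2 * stats::sd(vals))
  list(cutoff = cutoff, method = method, n_excluded = length(vals),
       fallback = FALSE)
}

#' Classify Syt-1 positivity of gate-passing varicosities
#'
#' Candidates flagged `near_junction` are left unclassified (their intensity
#' footprint is corrupted by the crossing branch); the reported fraction is
#' computed over cleanly measured gate-passing varicosities, an unbiased
#' subsample since varicosity placement is independent of branch points.
#'
#' @param varicosities candidate data.frame from [detect_varicosities()]
#' @param cutoff intensity threshold (number, or result of [syt1_cutoff()])
#' @return list with `varicosities` (column `is_syt1_positive` added; defined
#'   only for cleanly measured gate-passing rows), `syt1_positive_fraction`
#'   (NA when nothing is classifiable), `n_passing` (all gate-passing rows),
#'   `n_classified`, `n_positive`
#' @export
classify_syt1 <- function(varicosities, cutoff) {
  if (is.list(cutoff)) cutoff <- cutoff$cutoff
  v <- varicosities
  clean <- if (is.null(v$near_junction)) rep(TRUE, nrow(v)) else
    !v$near_junction
  v$is_syt1_positive <- ifelse(v$passes_gate & clean,
                               v$mean_syt1_intensity > cutoff, NA)
  n_pass <- sum(v$passes_gate)
  n_cls <- sum(v$passes_gate & clean)
  n_pos <- sum(v$is_syt1_positive, na.rm = TRUE)
  list(varicosities = v,
       syt1_positive_fraction = if (n_cls > 0) n_pos / n_cls else NA_real_,
       n_passing = n_pass, n_classified = n_cls, n_positive = n_pos)
}

#' Nearest-neighbor distances between gate-passing varicosities
#'
#' For each passing varicosity, the Euclidean centroid-to-centroid distance
#' to its nearest passing neighbor. Fewer than 2 passing points give an
#' empty vector.
#'
#' @param varicosities candidate data.frame (columns `x_um`, `y_um`,
#'   `passes_gate`), or a plain matrix of coordinates
#' @return numeric vector of distances in um, one per passing varicosity
#' @examples
#' nn_distances(cbind(c(0, 3, 7), 0))
#' @export
nn_distances <- function(varicosities) {
  if (is.data.frame(varicosities)) {
    pts <- as.matrix(varicosities[varicosities$passes_gate,
                                  c("x_um", "y_um")])
  } else {
    pts <- as.matrix(varicosities)
  }
  n <- nrow(pts)
  if (n < 2) return(numeric(0))
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' Varicosity density per millimeter of axon
#'
#' @param varicosities candidate data.frame (or an integer count of passing
#'   varicosities)
#' @param total_axon_length_um summed skeleton length of the same field
#' @return passing varicosities per mm; `NA` (flagged by warning) when the
#'   length is zero
#' @export
density_per_length <- function(varicosities, total_axon_length_um) {
  n_pass <- if (is.data.frame(varicosities)) sum(varicosities$passes_gate)
            else as.integer(varicosities)
  if (total_axon_length_um <= 0) {
    warning("zero axon length: density undefined")
    return(NA_real_)
  }
  n_pass / (total_axon_length_um / 1000)
}

#' Per-field varicosity metrics
#'
#' Convenience wrapper combining gating, Syt-1 classification, spacing and
#' density into the per-field summary used by the pipeline.
#'
#' @param varicosities candidate data.frame from [detect_varicosities()]
#' @param cutoff Syt-1 cutoff (number or [syt1_cutoff()] result)
#' @param total_axon_length_um summed skeleton length
#' @param field_id identifier
#' @return list with `summary` (one-row data.frame) and `nn_distances_um`
#' @export
varicosity_metrics <- function(varicosities, cutoff, total_axon_length_um,
                               field_id = NA_character_) {
  cls <- classify_syt1(varicosities, cutoff)
  nnd <- nn_distances(varicosities)
  data_density <- if (total_axon_length_um > 0) {
    density_per_length(varicosities, total_axon_length_um)
  } else NA_real_
  list(summary = data.frame(
    field = field_id,
    n_detected = nrow(varicosities),
    n_passing = cls$n_passing,
    syt1_positive_fraction = cls$syt1_positive_fraction,
    mean_nn_distance_um = if (length(nnd)) mean(nnd) else NA_real_,
    density_per_mm = data_density,
    gate = if (nrow(varicosities)) varicosities$gate[1] else NA_character_),
    nn_distances_um = nnd,
    varicosities = cls$varicosities)
}
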