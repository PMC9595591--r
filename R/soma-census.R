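# Soma census: segment and count marker-positive cell bodies, evaluate
# against ground truth, and normalize dose-series counts into survival.

#' Segment marker-positive somata
#'
#' Median-filters the requested channel, thresholds it with Otsu's method,
#' removes thin (neurite) structure by a morphological opening of radius
#' about 1.5 um, fills holes, labels connected components and drops regions
#' below `min_soma_area`. An empty or constant image yields an empty mask.
#'
#' @param field an `image_field`
#' @param channel channel role to segment (default `"marker"`)
#' @param min_soma_area minimum region area in um^2 (default 30, well below a
#'   soma of >= 8 um diameter but above varicosities and debris)
#' @param intensity_quantile lower bound on the Otsu threshold expressed as an
#'   image quantile, guarding against thresholds collapsing into background
#'   on near-empty fields (default 0.5)
#' @return a `soma_mask`: list with `labels` (integer matrix, 0 background),
#'   `centroids_um` (data.frame x_um, y_um), `areas_um2`, `n`,
#'   `pixel_size_um`
#' @export
segment_somata <- function(field, channel = "marker", min_soma_area = 30,
                           intensity_quantile = 0.5) {
  stopifnot(inherits(field, "image_field"))
  check_that(channel %in% names(field$channels), "channel '%s' missing", channel)
  img <- field$channels[[channel]]
  psz <- field$pixel_size_um
  empty <- structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          centroids_um = data.frame(x_um = numeric(0),
                                                    y_um = numeric(0)),
                          areas_um2 = numeric(0), n = 0L,
                          pixel_size_um = psz),
                     class = "soma_mask")
  if (diff(range(img)) < .Machine$double.eps^0.5) return(empty)

  sm <- EBImage::medianFilter(img / max(img), size = 2L)
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  thr <- max(thr, stats::quantile(sm, intensity_quantile))
  bw <- sm > thr
  brush <- EBImage::makeBrush(2L * max(1L, round(1.5 / psz)) + 1L,
                              shape = "disc")
  bw <- EBImage::opening(bw, brush)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) return(empty)
  areas_px <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas_px * psz^2 >= min_soma_area)
  if (!length(keep)) return(empty)
  # relabel contiguously 1..K
  remap <- integer(max(lab)); remap[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  lab2[nz] <- remap[lab[nz]]
  k <- length(keep)
  ix <- row(lab2)[lab2 > 0]; iy <- col(lab2)[lab2 > 0]; lv <- lab2[lab2 > 0]
  cx <- vapply(split(ix, lv), mean, numeric(1))
  cy <- vapply(split(iy, lv), mean, numeric(1))
  structure(list(labels = lab2,
                 centroids_um = data.frame(x_um = px_to_um(cx, psz),
                                           y_um = px_to_um(cy, psz)),
                 areas_um2 = areas_px[keep] * psz^2,
                 n = k, pixel_size_um = psz),
            class = "soma_mask")
}

#' @export
print.soma_mask <- function(x, ...) {
  cat(sprintf("soma_mask: %d somata, mean area %.1f um^2\n", x$n,
              if (x$n) mean(x$areas_um2) else NA_real_))
  invisible(x)
}

#' Count segmented neurons
#' @param mask a `soma_mask`
#' @return integer number of labeled somata
#' @export
count_neurons <- function(mask) {
  stopifnot(inherits(mask, "soma_mask"))
  mask$n
}

#' Evaluate a census against generator ground truth
#'
#' Greedy one-to-one matching: predicted centroids and true centers are
#' paired closest-first while the pair distance is below `match_radius_um`.
#' Accuracy is `matches / max(n_true, n_predicted)`, penalizing misses and
#' false positives symmetrically; 1 when both sets are empty.
#'
#' @param mask a `soma_mask`
#' @param truth a `ground_truth`
#' @param match_radius_um maximum center-to-centroid pairing distance
#'   (default 5 um)
#' @return list with `accuracy`, `n_matched`, `n_true`, `n_predicted`
#' @export
evaluate_census <- function(mask, truth, match_radius_um = 5) {
  check_that(match_radius_um > 0, "match_radius_um must be > 0")
  pred <- as.matrix(mask$centroids_um)
  tru <- cbind(truth$soma_centers$x_um, truth$soma_centers$y_um)
  n_p <- nrow(pred); n_t <- nrow(tru)
  if (n_p == 0 && n_t == 0) {
    return(list(accuracy = 1, n_matched = 0L, n_true = 0L, n_predicted = 0L))
  }
  n_match <- 0L
  if (n_p > 0 && n_t > 0) {
    d <- sqrt(outer(pred[, 1], tru[, 1], "-")^2 +
              outer(pred[, 2], tru[, 2], "-")^2)
    while (TRUE) {
      m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
      if (d[m] > match_radius_um) break
      n_match <- n_match + 1L
      d[m[1], ] <- Inf; d[, m[2]] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  list(accuracy = n_match / max(n_t, n_p), n_matched = n_match,
       n_true = n_t, n_predicted = n_p)
}

#' Normalize dose-series neuron counts into survival fractions
#'
#' Each well's raw count is divided by the mean raw count of its population's
#' dose-0 wells (same plate/run; no cross-plate pooling). Populations whose
#' dose-0 mean is zero are flagged as undefined rather than dropped.
#'
#' @param counts data.frame with columns `population`, `dose`, `well`,
#'   `count`
#' @return the input with columns `normalized` and `normalization_defined`
#'   appended (a dose-response table); for every population with a defined
#'   baseline, the mean normalized count at dose 0 is 1
#' @examples
#' normalize_survival(data.frame(
#'   population = "SNc", dose = c(0, 0, 150), well = c("A1", "A2", "A3"),
#'   count = c(50, 50, 40)))
#' @export
normalize_survival <- function(counts) {
  need <- c("population", "dose", "well", "count")
  check_that(all(need %in% names(counts)),
             "counts needs columns %s", paste(need, collapse = ", "))
  for (p in unique(counts$population)) {
    check_that(any(counts$population == p & counts$dose == 0),
               "population '%s' has no dose-0 well", p)
  }
  base <- tapply(counts$count[counts$dose == 0],
                 counts$population[counts$dose == 0], mean)
  denom <- as.numeric(base[as.character(counts$population)])
  counts$normalization_defined <- denom > 0
  counts$normalized <- ifelse(denom > 0, counts$count / denom, NA_real_)
  counts
}
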