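# Neurite segmentation (ridge enhancement) and per-well morphometry.

#' Segment thin neurites from the marker channel
#'
#' Enhances tubular structure with a single-scale Hessian ridge filter
#' (negative second derivative across the ridge after Gaussian smoothing),
#' thresholds the response with Otsu guarded by a noise floor, removes the
#' dilated soma mask, and discards isolated components shorter than
#' `min_component_um`.
#'
#' @param field an `image_field`
#' @param soma_mask optional `soma_mask` whose (dilated) somata are excluded
#' @param ridge_sigma_px smoothing scale of the ridge filter in pixels
#'   (default 1, matched to 1--3 px neurite profiles)
#' @param soma_dilate_um dilation of the soma exclusion zone (default 1.5 um)
#' @param min_component_um minimum component extent kept (default 2 um)
#' @return logical matrix \[ix, iy\] of neurite pixels
#' @export
segment_neurites <- function(field, soma_mask = NULL, ridge_sigma_px = 1,
                             soma_dilate_um = 1.5, min_component_um = 2) {
  stopifnot(inherits(field, "image_field"))
  img <- field$channels$marker
  psz <- field$pixel_size_um
  if (diff(range(img)) < .Machine$double.eps^0.5) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  resp <- ridge_response(img, ridge_sigma_px)
  if (max(resp) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  # the response is ~0 on flat background, so its MAD tracks the noise level;
  # isolated supra-threshold noise specks fall to the component-length filter
  thr <- 4 * stats::mad(as.numeric(resp))
  bw <- resp > thr
  if (!is.null(soma_mask) && soma_mask$n > 0) {
    sm <- soma_mask$labels > 0
    brush <- EBImage::makeBrush(2L * max(1L, round(soma_dilate_um / psz)) + 1L,
                                shape = "disc")
    sm <- EBImage::dilate(sm, brush) > 0
    bw <- bw & !sm
  }
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  if (max(lab) > 0) {
    npx <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(npx < min_component_um / psz)
    if (length(small)) bw[lab %in% small] <- FALSE
  }
  bw
}

# -lambda2 of the Hessian of the Gaussian-smoothed image, clipped at 0
# (bright ridges give strongly negative curvature across the ridge)
ridge_response <- function(img, sigma_px) {
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma_px))
  w <- nrow(sm); h <- ncol(sm)
  # replicate-padded finite differences
  xm <- sm[c(1, 1:(w - 1)), ]; xp <- sm[c(2:w, w), ]
  ym <- sm[, c(1, 1:(h - 1))]; yp <- sm[, c(2:h, h)]
  ixx <- xp - 2 * sm + xm
  iyy <- yp - 2 * sm + ym
  xpyp <- sm[c(2:w, w), c(2:h, h)]; xmym <- sm[c(1, 1:(w - 1)), c(1, 1:(h - 1))]
  xpym <- sm[c(2:w, w), c(1, 1:(h - 1))]; xmyp <- sm[c(1, 1:(w - 1)), c(2:h, h)]
  ixy <- (xpyp + xmym - xpym - xmyp) / 4
  lam2 <- (ixx + iyy - sqrt((ixx - iyy)^2 + 4 * ixy^2)) / 2
  pmax(-lam2, 0)
}

#' Per-well morphometry from a skeleton graph
#'
#' @param graph a `skeleton_graph`
#' @param n_neurons neuron count of the same well (>= 1; a zero count flags
#'   the well as excluded rather than dividing by zero)
#' @param well_id identifier copied into the result
#' @return a one-row data.frame: `well`, `total_neurite_length_um`,
#'   `n_segments`, `n_neurons`, `mean_length_per_neuron_um`,
#'   `segments_per_neuron`, `mean_segment_length_um`, `defined`
#' @examples
#' sk <- skeletonize(matrix(rep(c(TRUE, FALSE), c(101, 101 * 19)), 101, 20),
#'                   pixel_size_um = 0.3)
#' morphometry(sk, n_neurons = 1, well_id = "demo")
#' @export
morphometry <- function(graph, n_neurons, well_id = NA_character_) {
  stopifnot(inherits(graph, "skeleton_graph"))
  total <- graph$total_length_um
  nseg <- graph$n_segments
  if (n_neurons < 1) {
    return(data.frame(well = well_id, total_neurite_length_um = total,
                      n_segments = nseg, n_neurons = n_neurons,
                      mean_length_per_neuron_um = NA_real_,
                      segments_per_neuron = NA_real_,
                      mean_segment_length_um = NA_real_, defined = FALSE))
  }
  data.frame(well = well_id, total_neurite_length_um = total,
             n_segments = nseg, n_neurons = n_neurons,
             mean_length_per_neuron_um = total / n_neurons,
             segments_per_neuron = nseg / n_neurons,
             mean_segment_length_um = if (nseg > 0) total / nseg else 0,
             defined = TRUE)
}
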