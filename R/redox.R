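# roGFP redox-trace analysis: stack registration, trace extraction, QC
# (baseline drift and non-responder exclusion) and relative oxidation.
#
# The calibration protocol saturates the sensor in both directions: DTT
# (dithiothreitol) fully reduces the mitochondria, giving the fluorescence
# maximum FDTT; ALD (aldrithiol) fully oxidizes them, giving the minimum
# FALD. Relative oxidation of the baseline F is 1 - (F - FALD)/(FDTT - FALD).

#' Translation-only registration of an image stack
#'
#' Estimates, for every frame, the integer (dx, dy) pixel offset that
#' maximizes the cross-correlation with frame 1 (FFT-based). The returned
#' offsets are corrections: translating frame k by its offset aligns it to
#' frame 1. Rotation is not modelled (drift in fixed-stage recordings is
#' translational).
#'
#' @param stack list of numeric matrices \[ix, iy\], all the same size
#' @return integer matrix n x 2 (columns dx, dy); first row is (0, 0)
#' @export
register_stack <- function(stack) {
  check_that(length(stack) >= 2, "need at least 2 frames")
  ref <- stack[[1]] - mean(stack[[1]])
  w <- nrow(ref); h <- ncol(ref)
  fref <- stats::fft(ref)
  out <- matrix(0L, length(stack), 2,
                dimnames = list(NULL, c("dx", "dy")))
  for (k in seq_along(stack)[-1]) {
    fr <- stack[[k]] - mean(stack[[k]])
    cc <- Re(stats::fft(fref * Conj(stats::fft(fr)), inverse = TRUE))
    pk <- which.max(cc)
    sx <- (pk - 1) %% w
    sy <- (pk - 1) %/% w
    if (sx > w / 2) sx <- sx - w
    if (sy > h / 2) sy <- sy - h
    out[k, ] <- c(sx, sy)
  }
  out
}

#' Apply integer translations to a stack (zero-padded borders)
#' @param stack list of matrices
#' @param offsets matrix from [register_stack()]
#' @return list of translated matrices
#' @export
apply_offsets <- function(stack, offsets) {
  lapply(seq_along(stack), function(k) {
    translate_int(stack[[k]], offsets[k, 1], offsets[k, 2])
  })
}

translate_int <- function(img, dx, dy) {
  w <- nrow(img); h <- ncol(img)
  out <- matrix(0, w, h)
  xs <- max(1, 1 + dx):min(w, w + dx)
  ys <- max(1, 1 + dy):min(h, h + dy)
  if (length(xs) && length(ys)) {
    out[xs, ys] <- img[xs - dx, ys - dy]
  }
  out
}

#' Extract per-ROI fluorescence traces from a registered stack
#'
#' @param stack list of matrices (already registered)
#' @param roi_labels integer matrix of the same size; 0 = background, k > 0 =
#'   ROI k
#' @param epoch factor/character vector of length `length(stack)` with values
#'   baseline/DTT/ALD
#' @param compartment trace compartment label
#' @return list of `fluor_trace`, one per ROI label
#' @export
extract_traces <- function(stack, roi_labels, epoch,
                           compartment = "axonal") {
  check_that(length(epoch) == length(stack),
             "epoch vector must label every frame")
  labs <- sort(unique(roi_labels[roi_labels > 0]))
  epoch <- factor(as.character(epoch), levels = c("baseline", "DTT", "ALD"))
  lapply(labs, function(l) {
    sel <- roi_labels == l
    intensity <- vapply(stack, function(fr) mean(fr[sel]), numeric(1))
    structure(list(roi_id = paste0("roi", l), intensity = intensity,
                   epoch = epoch, compartment = compartment, spec = NULL),
              class = "fluor_trace")
  })
}

#' Summarize the calibration levels of a trace
#'
#' F, FDTT and FALD are the medians of the last half of each epoch (the
#' plateau, once the calibrant has equilibrated).
#'
#' @param trace a `fluor_trace`
#' @return named numeric vector `c(F, FDTT, FALD)`
#' @export
epoch_levels <- function(trace) {
  lvl <- function(ep) {
    v <- trace$intensity[trace$epoch == ep]
    check_that(length(v) >= 1, "epoch '%s' missing from trace", ep)
    stats::median(v[ceiling(length(v) / 2):length(v)])
  }
  c(F = lvl("baseline"), FDTT = lvl("DTT"), FALD = lvl("ALD"))
}

#' Quality control of a roGFP trace
#'
#' Two exclusion rules: (1) drift — the absolute fractional change of the
#' baseline across the baseline epoch, from a least-squares linear fit
#' (|slope x duration| / fitted level at the first frame), must not exceed
#' `drift_limit` (default 0.10, the >10% rule); (2) responsiveness — DTT must
#' *raise* fluorescence above baseline and ALD must *lower* it below, each by
#' at least `response_k` baseline SDs (SD of the detrended baseline).
#'
#' @param trace a `fluor_trace` with all three epochs
#' @param drift_limit maximum tolerated |baseline drift| fraction
#' @param response_k required response in units of baseline SD
#' @return list with `included`, `excluded_drift`, `excluded_nonresponder`,
#'   `drift_fraction`, and the epoch levels `F`, `FDTT`, `FALD`
#' @export
qc_trace <- function(trace, drift_limit = 0.10, response_k = 3) {
  check_that(all(c("baseline", "DTT", "ALD") %in% trace$epoch),
             "trace must contain baseline, DTT and ALD epochs")
  base <- trace$intensity[trace$epoch == "baseline"]
  t_ <- seq_along(base)
  fit <- stats::lm.fit(cbind(1, t_), base)
  slope <- fit$coefficients[2]
  start_level <- fit$coefficients[1] + slope * 1
  drift <- abs(slope * (length(base) - 1)) / abs(start_level)
  base_sd <- stats::sd(fit$residuals)
  lv <- epoch_levels(trace)
  responds <- (lv["FDTT"] - lv["F"]) >= response_k * base_sd &&
              (lv["F"] - lv["FALD"]) >= response_k * base_sd
  excluded_drift <- drift > drift_limit
  excluded_nonresponder <- !responds
  list(included = !excluded_drift && !excluded_nonresponder,
       excluded_drift = excluded_drift,
       excluded_nonresponder = excluded_nonresponder,
       drift_fraction = unname(drift),
       F = unname(lv["F"]), FDTT = unname(lv["FDTT"]),
       FALD = unname(lv["FALD"]))
}

#' Relative oxidation from calibrated fluorescence levels
#'
#' `1 - (F - FALD) / (FDTT - FALD)`: 0 when the baseline sits at the fully
#' reduced maximum (F = FDTT), 1 at the fully oxidized minimum (F = FALD).
#' Values outside \[0, 1\] (noise pushing F past a calibration plateau) are
#' clipped and flagged.
#'
#' @param F,FDTT,FALD baseline, DTT-plateau and ALD-plateau levels
#' @return list with `value` (clipped), `raw`, `clipped`
#' @examples
#' relative_oxidation(600, 1000, 200)$value  # 0.5
#' @export
relative_oxidation <- function(F, FDTT, FALD) {
  check_that(FDTT > FALD, "calibration error: FDTT must exceed FALD")
  raw <- 1 - (F - FALD) / (FDTT - FALD)
  value <- min(max(raw, 0), 1)
  list(value = value, raw = raw, clipped = !identical(raw, value))
}

#' Full per-trace oxidation analysis (QC + formula)
#'
#' @param trace a `fluor_trace`
#' @param drift_limit,response_k passed to [qc_trace()]
#' @return one-row data.frame with roi_id, compartment, F, FDTT, FALD,
#'   relative_oxidation (NA when excluded), drift_fraction and QC flags
#' @export
oxidation_result <- function(trace, drift_limit = 0.10, response_k = 3) {
  qc <- qc_trace(trace, drift_limit, response_k)
  ox <- if (qc$included) relative_oxidation(qc$F, qc$FDTT, qc$FALD)$value
        else NA_real_
  data.frame(roi_id = trace$roi_id, compartment = trace$compartment,
             F = qc$F, FDTT = qc$FDTT, FALD = qc$FALD,
             relative_oxidation = ox, drift_fraction = qc$drift_fraction,
             included = qc$included, excluded_drift = qc$excluded_drift,
             excluded_nonresponder = qc$excluded_nonresponder)
}

#' Consecutive inter-mitochondrial distances along an axon
#'
#' Orders puncta centers by arc position and returns the consecutive
#' center-to-center gaps. Somatodendritic puncta are not measured (density
#' too high to resolve individual mitochondria); the function is agnostic to
#' compartment and simply operates on the positions it is given.
#'
#' @param centers_um numeric vector of 1-D positions along the axon
#' @return numeric vector of gaps (length `length(centers_um) - 1`); empty
#'   for fewer than 2 centers
#' @examples
#' intermito_distances(c(0, 10, 25))
#' @export
intermito_distances <- function(centers_um) {
  if (length(centers_um) < 2) return(numeric(0))
  diff(sort(centers_um))
}
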