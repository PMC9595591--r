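# Synthetic roGFP trace and mitochondrial spacing generators.

#' Generate a synthetic roGFP fluorescence trace
#'
#' Concatenates the three calibration epochs (baseline, DTT plateau at the
#' fluorescence maximum, ALD plateau at the minimum) at the spec's mean
#' levels with additive Gaussian noise. The baseline epoch is multiplied by a
#' linear ramp from 1 to `1 + drift_fraction` (frame 1 is at 1, the last
#' baseline frame exactly at `1 + drift_fraction`); non-responders hold
#' `f_baseline` through all three epochs.
#'
#' @param spec a [trace_spec()]
#' @param roi_id identifier carried into the trace
#' @param compartment `"axonal"` or `"somatodendritic"`
#' @return a `fluor_trace`: list with `roi_id`, `intensity`, `epoch`
#'   (factor with levels baseline/DTT/ALD), `compartment`, and the echoed
#'   `spec`
#' @export
generate_trace <- function(spec, roi_id = "roi1", compartment = "axonal") {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  nb <- spec$n_baseline; nd <- spec$n_dtt; na <- spec$n_ald
  if (spec$responder) {
    levels_ <- c(rep(spec$f_baseline, nb), rep(spec$f_dtt, nd),
                 rep(spec$f_ald, na))
  } else {
    levels_ <- rep(spec$f_baseline, nb + nd + na)
  }
  ramp <- seq(1, 1 + spec$drift_fraction, length.out = nb)
  levels_[seq_len(nb)] <- levels_[seq_len(nb)] * ramp
  intensity <- levels_ + stats::rnorm(nb + nd + na, 0, spec$noise_sd)
  epoch <- factor(rep(c("baseline", "DTT", "ALD"), c(nb, nd, na)),
                  levels = c("baseline", "DTT", "ALD"))
  structure(list(roi_id = roi_id, intensity = intensity, epoch = epoch,
                 compartment = match.arg(compartment,
                                         c("axonal", "somatodendritic")),
                 spec = spec),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("fluor_trace %s (%s): %d frames (%s)\n", x$roi_id,
              x$compartment, length(x$intensity),
              paste(table(x$epoch), collapse = "/")))
  invisible(x)
}

#' Generate 1-D mitochondrial puncta positions along a simulated axon
#'
#' Consecutive gaps are gamma-distributed with the requested mean and SD
#' (`spacing_sd_um = 0` degenerates to perfectly regular spacing); positions
#' are the cumulative sums starting at 0.
#'
#' @param spec a [mito_spacing_spec()]
#' @return numeric vector of `n_puncta` center positions in micrometers
#' @examples
#' pos <- generate_mito_positions(mito_spacing_spec(n_puncta = 50, seed = 3))
#' mean(diff(pos))
#' @export
generate_mito_positions <- function(spec) {
  stopifnot(inherits(spec, "mito_spacing_spec"))
  set.seed(spec$seed)
  n_gaps <- spec$n_puncta - 1L
  if (spec$spacing_sd_um == 0) {
    gaps <- rep(spec$spacing_mean_um, n_gaps)
  } else {
    shape <- (spec$spacing_mean_um / spec$spacing_sd_um)^2
    scale <- spec$spacing_sd_um^2 / spec$spacing_mean_um
    gaps <- stats::rgamma(n_gaps, shape = shape, scale = scale)
  }
  c(0, cumsum(gaps))
}
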