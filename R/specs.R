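# Specification objects for the synthetic generators. The defaults define the
# study conditions every downstream test runs under; they are documented in
# the methods vignette and are not tuned per test.

#' Field specification for the synthetic multichannel neuron-field generator
#'
#' Describes one simulated well image: geometry of the raster, number of
#' marker-positive somata and background nuclei, target summed neurite
#' centerline length, branching intensity, varicosity geometry and the
#' two-component synaptotagmin-1 (Syt-1) intensity mixture, plus a simple
#' camera model (constant background with additive Gaussian noise).
#'
#' @param width_px,height_px raster extent in pixels
#' @param pixel_size_um micrometers per pixel (default 0.3, a 60x scale at
#'   which varicosity widths of 0.2--1 um span roughly 1--3 px)
#' @param n_neurons number of marker-positive somata
#' @param n_nuclei number of additional background (marker-negative) nuclei
#' @param neurite_total_length_um target summed centerline length of all
#'   neurites in the field
#' @param branch_prob_per_um probability per micrometer of a branch event
#'   along a growing neurite
#' @param varicosity_spacing_um mean along-skeleton spacing between planted
#'   varicosities
#' @param varicosity_width_range_um,varicosity_length_range_um length-2
#'   numeric ranges from which each varicosity's transverse width (FWHM) and
#'   along-axis length are drawn uniformly
#' @param oversize_fraction fraction of planted enlargements drawn oversize
#'   (width 1.5--2 um, well outside the morphological gate); these emulate
#'   nonfunctional swellings, always carry negative-component Syt-1, and are
#'   what the Syt-1 cutoff estimation feeds on
#' @param syt1_pos_fraction fraction of gate-sized varicosities drawn from
#'   the Syt-1 positive intensity component
#' @param syt1_pos_mean,syt1_neg_mean,syt1_sd means and common SD of the
#'   positive/negative Syt-1 intensity components (arbitrary units)
#' @param background_level,noise_sd camera model: constant offset and SD of
#'   additive Gaussian noise (arbitrary units)
#' @param seed integer RNG seed; identical seeds give bit-identical fields
#' @return an object of class `field_spec`
#' @export
field_spec <- function(width_px = 448L, height_px = 448L,
                       pixel_size_um = 0.3,
                       n_neurons = 10L, n_nuclei = 30L,
                       neurite_total_length_um = 1200,
                       branch_prob_per_um = 0.02,
                       varicosity_spacing_um = 6,
                       varicosity_width_range_um = c(0.35, 0.8),
                       varicosity_length_range_um = c(0.5, 1.2),
                       oversize_fraction = 0.15,
                       syt1_pos_fraction = 0.6,
                       syt1_pos_mean = 200, syt1_neg_mean = 30, syt1_sd = 12,
                       background_level = 100, noise_sd = 5,
                       seed = 1L) {
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               pixel_size_um = pixel_size_um,
               n_neurons = as.integer(n_neurons), n_nuclei = as.integer(n_nuclei),
               neurite_total_length_um = neurite_total_length_um,
               branch_prob_per_um = branch_prob_per_um,
               varicosity_spacing_um = varicosity_spacing_um,
               varicosity_width_range_um = varicosity_width_range_um,
               oversize_fraction = oversize_fraction,
               varicosity_length_range_um = varicosity_length_range_um,
               syt1_pos_fraction = syt1_pos_fraction,
               syt1_pos_mean = syt1_pos_mean, syt1_neg_mean = syt1_neg_mean,
               syt1_sd = syt1_sd,
               background_level = background_level, noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "field_spec"
  validate_field_spec(spec)
  spec
}

#' @noRd
validate_field_spec <- function(spec) {
  check_that(spec$width_px > 0 && spec$height_px > 0 && spec$pixel_size_um > 0,
             "field extents and pixel size must be positive")
  check_that(spec$n_neurons >= 0 && spec$n_nuclei >= 0,
             "counts must be non-negative")
  check_that(spec$neurite_total_length_um >= 0, "neurite length must be >= 0")
  check_that(spec$syt1_pos_fraction >= 0 && spec$syt1_pos_fraction <= 1,
             "syt1_pos_fraction must lie in [0, 1]")
  check_that(spec$oversize_fraction >= 0 && spec$oversize_fraction <= 1,
             "oversize_fraction must lie in [0, 1]")
  check_that(spec$syt1_pos_mean > spec$syt1_neg_mean,
             "syt1_pos_mean must exceed syt1_neg_mean")
  check_that(all(spec$varicosity_width_range_um > 0) &&
               all(spec$varicosity_length_range_um > 0),
             "varicosity geometry ranges must be positive")
  # a neurite occupies >= 1 px of footprint per pixel_size of length; refuse
  # fields the requested length cannot physically fit
  max_px <- 0.5 * spec$width_px * spec$height_px
  check_that(spec$neurite_total_length_um / spec$pixel_size_um <= max_px,
             "requested neurite length would cover > 50%% of the field")
  invisible(spec)
}

#' Trace specification for the synthetic roGFP fluorescence generator
#'
#' Describes a single region-of-interest fluorescence time course with three
#' epochs: baseline, a dithiothreitol (DTT) plateau at the fluorescence
#' maximum, and an aldrithiol (ALD) plateau at the minimum. A signed
#' `drift_fraction` multiplies the baseline epoch by a linear ramp from 1 to
#' `1 + drift_fraction`; non-responders hold the baseline level through all
#' epochs.
#'
#' @param n_baseline,n_dtt,n_ald frames per epoch
#' @param f_baseline,f_dtt,f_ald mean fluorescence levels (arbitrary units);
#'   requires `f_dtt > f_ald > 0` and, for responders,
#'   `f_ald <= f_baseline <= f_dtt`
#' @param drift_fraction signed fractional change of the baseline across the
#'   baseline epoch (0 = flat)
#' @param responder logical; `FALSE` simulates an ROI that ignores both
#'   calibrants
#' @param noise_sd SD of additive Gaussian noise
#' @param seed integer RNG seed
#' @return an object of class `trace_spec`
#' @export
trace_spec <- function(n_baseline = 30L, n_dtt = 20L, n_ald = 20L,
                       f_baseline = 600, f_dtt = 1000, f_ald = 200,
                       drift_fraction = 0, responder = TRUE,
                       noise_sd = 10, seed = 1L) {
  spec <- list(n_baseline = as.integer(n_baseline), n_dtt = as.integer(n_dtt),
               n_ald = as.integer(n_ald),
               f_baseline = f_baseline, f_dtt = f_dtt, f_ald = f_ald,
               drift_fraction = drift_fraction, responder = isTRUE(responder),
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "trace_spec"
  check_that(spec$n_baseline >= 2 && spec$n_dtt >= 1 && spec$n_ald >= 1,
             "each epoch needs frames (baseline >= 2)")
  check_that(spec$f_dtt > spec$f_ald && spec$f_ald > 0,
             "must have f_dtt > f_ald > 0")
  if (spec$responder) {
    check_that(spec$f_ald <= spec$f_baseline && spec$f_baseline <= spec$f_dtt,
               "responder requires f_ald <= f_baseline <= f_dtt")
  }
  check_that(spec$noise_sd >= 0, "noise_sd must be >= 0")
  spec
}

#' Spacing specification for simulated mitochondrial puncta along an axon
#'
#' Consecutive center-to-center gaps are drawn from a gamma distribution with
#' the requested mean and SD; puncta positions are the cumulative sums. The
#' defaults reproduce the reported axonal inter-mitochondrial spacing of
#' about 13 um with SD 5.4 um.
#'
#' @param n_puncta number of puncta (>= 2)
#' @param spacing_mean_um,spacing_sd_um gamma moments of the gaps;
#'   `spacing_sd_um = 0` gives perfectly regular spacing
#' @param seed integer RNG seed
#' @return an object of class `mito_spacing_spec`
#' @export
mito_spacing_spec <- function(n_puncta = 100L, spacing_mean_um = 13,
                              spacing_sd_um = 5.4, seed = 1L) {
  spec <- list(n_puncta = as.integer(n_puncta),
               spacing_mean_um = spacing_mean_um,
               spacing_sd_um = spacing_sd_um, seed = as.integer(seed))
  class(spec) <- "mito_spacing_spec"
  check_that(spec$n_puncta >= 2, "need at least 2 puncta")
  check_that(spec$spacing_mean_um > 0, "spacing_mean_um must be > 0")
  check_that(spec$spacing_sd_um >= 0, "spacing_sd_um must be >= 0")
  spec
}
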