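# Disk formats: multi-page TIFF (one page per channel, 16-bit), a JSON
# ground-truth sidecar, a CSV well manifest and CSV trace fixtures.

CHANNEL_ROLES <- c("marker", "map2", "syt1", "nuclei")
TIFF_SCALE <- 65535

#' Write an image field as a multi-page 16-bit TIFF
#'
#' One page per channel in the fixed role order marker, MAP2, Syt-1, nuclei.
#' Intensities are rounded to integers and clipped to \[0, 65535\]; pixel size
#' is stored in the sidecar written by [write_ground_truth()] or in the well
#' manifest.
#'
#' @param field an `image_field`
#' @param path output `.tif` path
#' @export
write_field_tiff <- function(field, path) {
  pages <- lapply(field$channels[CHANNEL_ROLES], function(ch) {
    # tiff expects [row, col] = [y, x] and values in [0, 1]
    t(pmin(pmax(round(ch), 0), TIFF_SCALE) / TIFF_SCALE)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read an image field from a multi-page TIFF written by [write_field_tiff()]
#'
#' @param path `.tif` path
#' @param pixel_size_um micrometers per pixel (from the manifest or sidecar)
#' @return an `image_field`
#' @export
read_field_tiff <- function(path, pixel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE)
  check_that(length(pages) == length(CHANNEL_ROLES),
             "expected %d channel pages in %s, found %d",
             length(CHANNEL_ROLES), path, length(pages))
  channels <- lapply(pages, function(p) t(p) * TIFF_SCALE)
  names(channels) <- CHANNEL_ROLES
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 width_px = nrow(channels[[1]]),
                 height_px = ncol(channels[[1]])),
            class = "image_field")
}

#' Write generator ground truth as a JSON sidecar
#' @param truth a `ground_truth`
#' @param path output `.json` path
#' @export
write_ground_truth <- function(truth, path) {
  x <- list(
    soma_centers = truth$soma_centers,
    skeleton_polylines = lapply(truth$skeleton_polylines, function(m)
      list(x_um = m[, 1], y_um = m[, 2])),
    polyline_lengths_um = truth$polyline_lengths_um,
    varicosities = truth$varicosities,
    n_neurons = truth$n_neurons,
    total_neurite_length_um = truth$total_neurite_length_um,
    n_varicosities = truth$n_varicosities)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path `.json` path
#' @return a `ground_truth`
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  polylines <- lapply(x$skeleton_polylines, function(p)
    cbind(x = p$x_um, y = p$y_um))
  structure(list(
    soma_centers = as.data.frame(x$soma_centers),
    skeleton_polylines = polylines,
    polyline_lengths_um = as.numeric(x$polyline_lengths_um),
    varicosities = as.data.frame(x$varicosities),
    n_neurons = x$n_neurons,
    total_neurite_length_um = x$total_neurite_length_um,
    n_varicosities = x$n_varicosities),
    class = "ground_truth")
}

#' Write a fluorescence trace table as CSV (frame, epoch, intensity per ROI)
#' @param traces list of `fluor_trace`
#' @param path output `.csv` path
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(roi_id = tr$roi_id, frame = seq_along(tr$intensity),
               epoch = as.character(tr$epoch), intensity = tr$intensity,
               compartment = tr$compartment)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV back into a list of `fluor_trace`
#' @param path `.csv` path written by [write_traces_csv()]
#' @return list of `fluor_trace`
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$roi_id), function(d) {
    d <- d[order(d$frame), ]
    structure(list(roi_id = d$roi_id[1], intensity = d$intensity,
                   epoch = factor(d$epoch,
                                  levels = c("baseline", "DTT", "ALD")),
                   compartment = d$compartment[1], spec = NULL),
              class = "fluor_trace")
  })
}
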