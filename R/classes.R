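#' AFM height map
#'
#' Container for a raster of physical surface heights, the substrate of all
#' AFM operations. Heights are in nm; `rx` and `ry` give the physical size of
#' one pixel (nm/pixel) along the x (column) and y (row) axes. Row 1 is the
#' top of the image and indices are handled 0-based internally with a
#' centre-of-pixel convention: pixel `(i, j)` (0-based row, column) sits at
#' physical position `((j + 0.5) * rx, (i + 0.5) * ry)`.
#'
#' @param heights numeric matrix of heights (nm), rows = y, columns = x.
#' @param rx,ry pixel size in nm/pixel along x and y. Must be > 0.
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, rx = 1, ry = 1) {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    abort_rmquant("`heights` must be a numeric matrix", "rmquant_parameter_error")
  }
  if (any(!is.finite(heights))) {
    abort_rmquant("`heights` must contain finite values only",
                  "rmquant_parameter_error")
  }
  check_positive(rx, "rx")
  check_positive(ry, "ry")
  structure(list(heights = heights, rx = rx, ry = ry), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "<height_map> %d x %d pixels (%.3g x %.3g nm), rx = %g, ry = %g nm/px\n",
    nrow(x$heights), ncol(x$heights),
    ncol(x$heights) * x$rx, nrow(x$heights) * x$ry, x$rx, x$ry
  ))
  cat(sprintf("  height range: [%.3g, %.3g] nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' @export
dim.height_map <- function(x) dim(x$heights)

#' Multi-channel intensity image
#'
#' Container for a fluorescence image with one or more channels sharing the
#' same geometry (e.g. protein and DNA channels of a confocal scan).
#'
#' @param data numeric matrix (single channel) or 3D array
#'   (rows x columns x channels) of intensities (photon-count units).
#' @param pixel_size physical pixel size in nm/pixel.
#' @param channels character vector of channel names, one per channel.
#' @return An object of class `rm_image`.
#' @export
rm_image <- function(data, pixel_size, channels = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  if (!is.array(data) || length(dim(data)) != 3) {
    abort_rmquant("`data` must be a matrix or 3D array",
                  "rmquant_parameter_error")
  }
  check_positive(pixel_size, "pixel_size")
  n_ch <- dim(data)[3]
  channels <- channels %||% paste0("ch", seq_len(n_ch))
  if (length(channels) != n_ch) {
    abort_rmquant("`channels` must name every channel",
                  "rmquant_parameter_error")
  }
  structure(list(data = data, pixel_size = pixel_size, channels = channels),
            class = "rm_image")
}

#' @export
print.rm_image <- function(x, ...) {
  cat(sprintf("<rm_image> %d x %d px at %g nm/px, channels: %s\n",
              dim(x$data)[1], dim(x$data)[2], x$pixel_size,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of an image as a matrix
#'
#' @param img an [rm_image].
#' @param channel channel name or index.
#' @return numeric matrix of intensities.
#' @export
image_channel <- function(img, channel = 1) {
  stopifnot(inherits(img, "rm_image"))
  if (is.character(channel)) {
    idx <- match(channel, img$channels)
    if (is.na(idx)) {
      abort_rmquant(sprintf("unknown channel '%s'", channel),
                    "rmquant_parameter_error")
    }
    channel <- idx
  }
  img$data[, , channel]
}

#' Confocal scan series
#'
#' An ordered stack of photon-count frames with a fixed frame interval, as
#' recorded in the optical-trap scan movies.
#'
#' @param frames 3D array (rows x columns x frames) of photon counts, or a
#'   list of equally sized matrices.
#' @param frame_interval time between frames in seconds.
#' @param pixel_size physical pixel size in nm/pixel.
#' @param channel optional channel label.
#' @return An object of class `scan_series` with a `t` vector of frame times
#'   (s), starting at 0.
#' @export
scan_series <- function(frames, frame_interval, pixel_size = 100,
                        channel = "protein") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) {
      abort_rmquant("all frames must have the same shape",
                    "rmquant_parameter_error")
    }
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    abort_rmquant("`frames` must be a 3D array or list of matrices",
                  "rmquant_parameter_error")
  }
  check_positive(frame_interval, "frame_interval")
  check_positive(pixel_size, "pixel_size")
  n <- dim(frames)[3]
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size, channel = channel,
         t = (seq_len(n) - 1) * frame_interval),
    class = "scan_series"
  )
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf(
    "<scan_series> %d frames of %d x %d px, dt = %g s (%s channel)\n",
    dim(x$frames)[3], dim(x$frames)[1], dim(x$frames)[2],
    x$frame_interval, x$channel
  ))
  invisible(x)
}
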