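# TIFF + YAML-sidecar I/O. Physical values (nm for height maps, counts for
# images) are stored as 32-bit float TIFF in [0, 1] with an affine
# scale/offset recorded in the sidecar, because baseline TIFF readers do not
# agree on out-of-range float samples. A sidecar read in is kept on the
# object so that write -> read -> write reuses the original affine encoding:
# the sidecar is reproduced exactly and pixel values to within one float32
# ulp (bit-exact identity is not guaranteed because decoding to double and
# re-encoding rounds once more).

sidecar_path <- function(path) paste0(path, ".yaml")

encode_frames <- function(frames, scale_offset = NULL) {
  vals <- unlist(frames)
  if (is.null(scale_offset)) {
    offset <- min(vals)
    scale <- max(max(vals) - offset, 1e-300)
    scale_offset <- c(scale = scale, offset = offset)
  }
  enc <- lapply(frames, function(f) {
    pmin(pmax((f - scale_offset[["offset"]]) / scale_offset[["scale"]], 0), 1)
  })
  list(frames = enc, scale = scale_offset[["scale"]],
       offset = scale_offset[["offset"]])
}

#' Write an image object with its sidecar
#'
#' Writes a [height_map], [rm_image] or [scan_series] as a (multi-frame)
#' 32-bit float TIFF plus a YAML sidecar holding the object kind, physical
#' pixel sizes, frame interval, channels, and the affine value encoding.
#'
#' @param x a `height_map`, `rm_image` or `scan_series`.
#' @param path output TIFF path; the sidecar is written to
#'   `paste0(path, ".yaml")`.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  so <- attr(x, "io_scale_offset")
  if (inherits(x, "height_map")) {
    enc <- encode_frames(list(x$heights), so)
    meta <- list(kind = "height_map", rx = x$rx, ry = x$ry,
                 units = "nm", scale = enc$scale, offset = enc$offset)
  } else if (inherits(x, "rm_image")) {
    frames <- lapply(seq_along(x$channels), function(i) x$data[, , i])
    enc <- encode_frames(frames, so)
    meta <- list(kind = "image", pixel_size = x$pixel_size,
                 channels = as.list(x$channels), units = "counts",
                 scale = enc$scale, offset = enc$offset)
  } else if (inherits(x, "scan_series")) {
    frames <- lapply(seq_len(dim(x$frames)[3]), function(i) x$frames[, , i])
    enc <- encode_frames(frames, so)
    meta <- list(kind = "scan_series", pixel_size = x$pixel_size,
                 frame_interval = x$frame_interval, channel = x$channel,
                 units = "counts", scale = enc$scale, offset = enc$offset)
  } else {
    abort_rmquant("unsupported object for write_image", "rmquant_io_error")
  }
  suppressWarnings(tiff::writeTIFF(enc$frames, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read an image object and its sidecar
#'
#' Reads a TIFF written by [write_image()] (or any single-value-per-pixel
#' TIFF with a hand-written sidecar) and returns the typed object the
#' sidecar declares: a [height_map], an [rm_image], or a [scan_series].
#' The physical pixel size must come from the sidecar or the arguments —
#' there is no silent default.
#'
#' @param path TIFF path.
#' @param sidecar sidecar path (default `paste0(path, ".yaml")`).
#' @param pixel_size,rx,ry,frame_interval overrides used when the sidecar is
#'   absent.
#' @param kind object kind when the sidecar is absent:
#'   `"height_map"`, `"image"`, or `"scan_series"`.
#' @return the typed object.
#' @export
read_image <- function(path, sidecar = sidecar_path(path),
                       pixel_size = NULL, rx = NULL, ry = NULL,
                       frame_interval = NULL, kind = NULL) {
  if (!file.exists(path)) {
    abort_rmquant(sprintf("no such file: %s", path), "rmquant_io_error")
  }
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  kind <- meta$kind %||% kind
  if (is.null(kind)) {
    abort_rmquant("no sidecar found and `kind` not given", "rmquant_io_error")
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  scale <- meta$scale %||% 1
  offset <- meta$offset %||% 0
  frames <- lapply(frames, function(f) f * scale + offset)
  so <- c(scale = scale, offset = offset)
  if (kind == "height_map") {
    rx <- meta$rx %||% rx
    ry <- meta$ry %||% ry
    if (is.null(rx) || is.null(ry)) {
      abort_rmquant("pixel size (rx, ry) missing: supply a sidecar or arguments",
                    "rmquant_io_error")
    }
    out <- height_map(frames[[1]], rx = rx, ry = ry)
  } else if (kind == "image") {
    ps <- meta$pixel_size %||% pixel_size
    if (is.null(ps)) {
      abort_rmquant("pixel_size missing: supply a sidecar or argument",
                    "rmquant_io_error")
    }
    arr <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
    out <- rm_image(arr, pixel_size = ps,
                    channels = unlist(meta$channels) %||% NULL)
  } else if (kind == "scan_series") {
    ps <- meta$pixel_size %||% pixel_size
    fi <- meta$frame_interval %||% frame_interval
    if (is.null(ps) || is.null(fi)) {
      abort_rmquant("pixel_size or frame_interval missing: supply a sidecar or arguments",
                    "rmquant_io_error")
    }
    arr <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
    out <- scan_series(arr, frame_interval = fi, pixel_size = ps,
                       channel = meta$channel %||% "protein")
  } else {
    abort_rmquant(sprintf("unknown image kind '%s'", kind), "rmquant_io_error")
  }
  attr(out, "io_scale_offset") <- so
  out
}

#' Write a results table as CSV with a units header
#'
#' Writes a `# units:` comment line, plus optional provenance comments
#' (seed, config hash, package version), followed by the CSV body.
#'
#' @param df data frame.
#' @param path output path.
#' @param units named character vector or single string describing units.
#' @param seed,config_hash optional provenance recorded as comments.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(df, path, units = "", seed = NULL,
                              config_hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(units, collapse = "; ")), con)
  ver <- as.character(utils::packageVersion("rmquant"))
  prov <- sprintf("# rmquant %s", ver)
  if (!is.null(seed)) prov <- paste0(prov, sprintf("; seed %s", seed))
  if (!is.null(config_hash)) prov <- paste0(prov, sprintf("; config %s", config_hash))
  writeLines(prov, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results_csv()]
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_results_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
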