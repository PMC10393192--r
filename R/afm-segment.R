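#' Estimate the background of a height map
#'
#' Finds the flat mica background by iterative (isodata-style) thresholding:
#' the threshold is updated to the midpoint of the means below and above it
#' until convergence. If the two classes are not separated (mean difference
#' below twice the sum of their spreads) the histogram is effectively
#' unimodal and the background statistics fall back to the median and
#' scaled MAD of the whole map: robust estimates that a sparse foreground
#' cannot contaminate (the mean would be pulled up by exactly the
#' foreground volume divided by the scan area).
#'
#' @param hm a [height_map].
#' @return A list of class `background_model` with `h_b` (mean background
#'   height, nm), `sigma_b` (sd, nm), and `background_fraction`.
#' @export
estimate_background <- function(hm) {
  stopifnot(inherits(hm, "height_map"))
  h <- as.vector(hm$heights)
  if (length(h) == 0) {
    abort_rmquant("empty height map", "rmquant_background_error")
  }
  if (stats::sd(h) == 0) {
    return(structure(list(h_b = h[1], sigma_b = 0, background_fraction = 1),
                     class = "background_model"))
  }
  t <- mean(h)
  for (i in seq_len(100)) {
    lo <- h[h < t]; hi <- h[h >= t]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-12) break
    t <- t_new
  }
  lo <- h[h < t]; hi <- h[h >= t]
  if (length(lo) == 0) {
    abort_rmquant("no background pixels found (all-foreground map)",
                  "rmquant_background_error")
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  separated <- length(hi) > 0 &&
    (mean(hi) - mean(lo)) > 2 * (sd0(lo) + sd0(hi))
  if (!separated) {
    return(structure(
      list(h_b = stats::median(h), sigma_b = stats::mad(h),
           background_fraction = 1),
      class = "background_model"
    ))
  }
  structure(
    list(h_b = mean(lo), sigma_b = sd0(lo),
         background_fraction = length(lo) / length(h)),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> h_b = %.4g nm, sigma_b = %.4g nm (%.0f%% of pixels)\n",
              x$h_b, x$sigma_b, 100 * x$background_fraction))
  invisible(x)
}

#' Segment molecules from a height map
#'
#' Thresholds the map at `h_b + k_sigma * sigma_b` and labels 8-connected
#' components. The threshold statistics come from the raw map, but the
#' comparison is made on a lightly smoothed copy (Gaussian
#' `presmooth_sigma`, mask generation only — heights used for volumetry are
#' never smoothed), which suppresses single-pixel noise excursions that
#' would otherwise serrate molecule boundaries. Components smaller than
#' `min_area` pixels are dropped; components touching the image border are
#' flagged and excluded from downstream statistics (their contour lengths
#' would be truncated).
#'
#' @param hm a [height_map].
#' @param bg a `background_model` from [estimate_background()].
#' @param k_sigma threshold in background-sd units above `h_b` (default 2).
#' @param min_area minimum component area in pixels.
#' @param presmooth_sigma Gaussian sigma (pixels) of the mask-generation
#'   smoothing; 0 disables it.
#' @return A tibble with one row per detected component: `id`, `area_px`,
#'   `touches_border`, `kept`, and a list-column `region` of
#'   `molecule_region` objects (bounding box + local mask).
#' @export
segment_molecules <- function(hm, bg, k_sigma = 2, min_area = 20,
                              presmooth_sigma = 1) {
  stopifnot(inherits(hm, "height_map"), inherits(bg, "background_model"))
  check_positive(k_sigma, "k_sigma")
  h <- hm$heights
  if (presmooth_sigma > 0) h <- gauss_blur(h, presmooth_sigma, presmooth_sigma)
  mask <- h > bg$h_b + k_sigma * bg$sigma_b
  lab <- bwlabel8(mask)
  n <- max(lab)
  if (n == 0) {
    return(tibble::tibble(id = integer(), area_px = integer(),
                          touches_border = logical(), kept = logical(),
                          region = list()))
  }
  ny <- nrow(mask); nx <- ncol(mask)
  rows <- purrr::map(seq_len(n), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    area <- nrow(idx)
    border <- any(idx[, 1] %in% c(1, ny)) || any(idx[, 2] %in% c(1, nx))
    bbox <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
    local <- matrix(FALSE, bbox[2] - bbox[1] + 1, bbox[4] - bbox[3] + 1)
    local[cbind(idx[, 1] - bbox[1] + 1, idx[, 2] - bbox[3] + 1)] <- TRUE
    region <- structure(list(label = i, bbox = bbox, mask = local,
                             area_px = area, rx = hm$rx, ry = hm$ry),
                        class = "molecule_region")
    tibble::tibble(id = i, area_px = area, touches_border = border,
                   kept = area >= min_area && !border, region = list(region))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.molecule_region <- function(x, ...) {
  cat(sprintf("<molecule_region> label %d, %d px, bbox rows %d-%d cols %d-%d\n",
              x$label, x$area_px, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  invisible(x)
}

# full-image logical mask for a molecule_region
region_full_mask <- function(region, dim_full) {
  m <- matrix(FALSE, dim_full[1], dim_full[2])
  b <- region$bbox
  m[b[1]:b[2], b[3]:b[4]] <- region$mask
  m
}
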