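#' Segment a condensate into core and whole masks
#'
#' Thresholds a single-channel view of a condensate image twice: a low
#' threshold (default: Otsu on log intensity) delimits the whole condensate
#' (core + halo), and a high threshold (default: mean + 2 sd of the
#' provisional halo pixels) delimits the dense core. The largest connected
#' component is taken for each mask and the core is forced inside the whole
#' mask; additional components are counted and flagged.
#'
#' @param img an [rm_image] (or a numeric matrix, with `pixel_size`).
#' @param channel channel name or index (default `"protein"`, matching the
#'   channel reported for core radii).
#' @param whole_threshold,core_threshold optional explicit intensity
#'   thresholds overriding the defaults.
#' @param pixel_size required when `img` is a bare matrix.
#' @return A list of class `condensate_masks`: `core`, `whole` (logical
#'   matrices), `center` (x, y in nm), `pixel_size`, `channel`,
#'   `n_extra_components`.
#' @export
segment_condensate <- function(img, channel = "protein",
                               whole_threshold = NULL, core_threshold = NULL,
                               pixel_size = NULL) {
  if (inherits(img, "rm_image")) {
    m <- image_channel(img, channel)
    pixel_size <- img$pixel_size
  } else {
    m <- img
    if (is.null(pixel_size)) {
      abort_rmquant("supply `pixel_size` with a bare matrix",
                    "rmquant_parameter_error")
    }
  }
  if (is.null(whole_threshold)) {
    lm <- log(m - min(m) + 1)
    rng <- range(lm)
    if (diff(rng) == 0) {
      abort_rmquant("flat image: no condensate found", "rmquant_empty_field_error")
    }
    lm01 <- (lm - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(lm01), range = c(0, 1))
    whole_threshold <- min(m) - 1 + exp(thr01 * diff(rng) + rng[1])
  }
  whole_all <- m > whole_threshold
  if (!any(whole_all)) {
    abort_rmquant("no pixels above the whole-condensate threshold",
                  "rmquant_empty_field_error")
  }
  wlab <- bwlabel8(whole_all)
  sizes <- tabulate(wlab[wlab > 0])
  main <- which.max(sizes)
  whole <- wlab == main
  n_extra <- sum(sizes > 0) - 1
  if (is.null(core_threshold)) {
    vals <- m[whole]
    if (diff(range(vals)) == 0) {
      core_threshold <- whole_threshold  # core-only condensate: core = whole
    } else {
      v01 <- (vals - min(vals)) / diff(range(vals))
      split01 <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1)),
                               range = c(0, 1))
      split <- min(vals) + split01 * diff(range(vals))
      halo_vals <- vals[vals <= split]
      core_threshold <- mean(halo_vals) +
        2 * (if (length(halo_vals) > 1) stats::sd(halo_vals) else 0)
    }
  }
  core_all <- whole & m > core_threshold
  if (!any(core_all)) {
    abort_rmquant("no pixels above the core threshold",
                  "rmquant_empty_field_error")
  }
  clab <- bwlabel8(core_all)
  csizes <- tabulate(clab[clab > 0])
  core <- clab == which.max(csizes)
  idx <- which(core, arr.ind = TRUE)
  center <- c((mean(idx[, 2]) - 0.5) * pixel_size,
              (mean(idx[, 1]) - 0.5) * pixel_size)
  structure(
    list(core = core, whole = whole, center = center,
         pixel_size = pixel_size,
         channel = if (is.numeric(channel)) as.character(channel) else channel,
         n_extra_components = n_extra,
         whole_threshold = whole_threshold, core_threshold = core_threshold),
    class = "condensate_masks"
  )
}

#' Core radius from mask area
#'
#' Equivalent-disc radius \code{r = sqrt(A / pi)} from the core mask area.
#'
#' @param core_mask logical matrix (or `condensate_masks`).
#' @param pixel_size nm/pixel (taken from the masks object when given).
#' @return radius in nm.
#' @export
core_radius <- function(core_mask, pixel_size = NULL) {
  if (inherits(core_mask, "condensate_masks")) {
    pixel_size <- core_mask$pixel_size
    core_mask <- core_mask$core
  }
  check_positive(pixel_size, "pixel_size")
  area_px <- sum(core_mask)
  if (area_px == 0) {
    abort_rmquant("empty core mask", "rmquant_empty_field_error")
  }
  sqrt(area_px * pixel_size^2 / pi)
}

# bilinear interpolation of a numeric matrix at continuous pixel coords
# (u = row, v = col, centre-of-pixel convention: pixel (i, j) at (i, j))
bilinear_at <- function(m, u, v) {
  ny <- nrow(m); nx <- ncol(m)
  u <- pmin(pmax(u, 1), ny); v <- pmin(pmax(v, 1), nx)
  i0 <- pmin(pmax(floor(u), 1), ny - 1); j0 <- pmin(pmax(floor(v), 1), nx - 1)
  du <- u - i0; dv <- v - j0
  m[cbind(i0, j0)] * (1 - du) * (1 - dv) +
    m[cbind(i0 + 1, j0)] * du * (1 - dv) +
    m[cbind(i0, j0 + 1)] * (1 - du) * dv +
    m[cbind(i0 + 1, j0 + 1)] * du * dv
}

# first radius (nm) at which the interpolated mask drops below 0.5 along a
# ray from center at angle `ang`; NA when the ray leaves the image first
ray_crossing <- function(mask_num, center, ang, pixel_size, step_frac = 0.1) {
  ny <- nrow(mask_num); nx <- ncol(mask_num)
  t_max <- sqrt((nx * pixel_size)^2 + (ny * pixel_size)^2)
  tt <- seq(0, t_max, by = step_frac * pixel_size)
  x <- center[1] + tt * cos(ang)
  y <- center[2] + tt * sin(ang)
  inside <- x >= 0.5 * pixel_size & x <= (nx - 0.5) * pixel_size &
    y >= 0.5 * pixel_size & y <= (ny - 0.5) * pixel_size
  n_in <- if (all(inside)) length(tt) else which(!inside)[1] - 1
  if (n_in < 2) return(NA_real_)
  u <- y[1:n_in] / pixel_size + 0.5
  v <- x[1:n_in] / pixel_size + 0.5
  vals <- bilinear_at(mask_num, u, v)
  below <- which(vals < 0.5)
  below <- below[below > 1]
  if (length(below) == 0) return(NA_real_)  # still inside at image edge
  i <- below[1]
  f <- (vals[i - 1] - 0.5) / (vals[i - 1] - vals[i])
  tt[i - 1] + f * (tt[i] - tt[i - 1])
}

#' Halo thickness by radial rays
#'
#' Measures the halo width along rays cast from the core centre at fixed
#' angular increments (default 10 degrees, 36 rays): along each ray the
#' thickness is the distance between the core-boundary crossing and the
#' whole-condensate boundary crossing, both located at subpixel precision by
#' linear interpolation; the per-condensate value is the mean over rays.
#' Rays that leave the image while still inside the condensate are excluded;
#' more than 50% excluded is an error.
#'
#' @param masks a `condensate_masks` object (or supply `core`, `whole`,
#'   `center`, `pixel_size` individually).
#' @param ray_count number of rays (36 gives the 10-degree increments).
#' @param step_frac radial sampling step as a fraction of a pixel.
#' @return A list of class `condensate_morphology`: `core_radius_nm`,
#'   `halo_mean_nm`, `rays` tibble (`angle_deg`, `t_core_nm`, `t_whole_nm`,
#'   `thickness_nm`, `excluded`), `center`, `channel`.
#' @export
halo_thickness <- function(masks, ray_count = 36, step_frac = 0.1) {
  stopifnot(inherits(masks, "condensate_masks"))
  core_num <- masks$core * 1
  whole_num <- masks$whole * 1
  ps <- masks$pixel_size
  angles <- seq(0, 2 * pi, length.out = ray_count + 1)[seq_len(ray_count)]
  rays <- purrr::map_dfr(angles, function(a) {
    t_core <- ray_crossing(core_num, masks$center, a, ps, step_frac)
    t_whole <- ray_crossing(whole_num, masks$center, a, ps, step_frac)
    excluded <- is.na(t_core) || is.na(t_whole)
    tibble::tibble(angle_deg = a * 180 / pi,
                   t_core_nm = t_core, t_whole_nm = t_whole,
                   thickness_nm = if (excluded) NA_real_ else
                     max(t_whole - t_core, 0),
                   excluded = excluded)
  })
  if (mean(rays$excluded) > 0.5) {
    abort_rmquant("more than half of the rays leave the image inside the condensate",
                  "rmquant_morphometry_error")
  }
  structure(
    list(core_radius_nm = core_radius(masks),
         halo_mean_nm = mean(rays$thickness_nm[!rays$excluded]),
         rays = rays, center = masks$center, channel = masks$channel,
         pixel_size = ps),
    class = "condensate_morphology"
  )
}

#' @export
print.condensate_morphology <- function(x, ...) {
  cat(sprintf(
    "<condensate_morphology> (%s channel) core radius %.0f nm, halo %.0f nm (mean of %d rays)\n",
    x$channel, x$core_radius_nm, x$halo_mean_nm, sum(!x$rays$excluded)
  ))
  invisible(x)
}

#' Full condensate morphometry for one channel
#'
#' @param img an [rm_image].
#' @param channel channel to analyse (default `"protein"`).
#' @param ray_count rays for the halo measurement.
#' @param ... passed to [segment_condensate()].
#' @return A `condensate_morphology` object.
#' @export
condensate_morphology <- function(img, channel = "protein", ray_count = 36,
                                  ...) {
  halo_thickness(segment_condensate(img, channel = channel, ...),
                 ray_count = ray_count)
}

#' Detect condensation foci by background thresholding
#'
#' Thresholds an image at the background mean plus two background standard
#' deviations, labels connected components above the threshold, counts those
#' of at least `min_focus_area` pixels, and integrates the
#' background-subtracted intensity inside each focus mask.
#'
#' @param img an [rm_image] or numeric matrix.
#' @param channel channel when `img` is multi-channel.
#' @param background `"auto"` (robust estimate: median and scaled MAD of all
#'   pixels, insensitive to the bright foci), a logical background mask, or
#'   `c(mean, sd)` given directly.
#' @param k sd multiplier for the threshold (default 2).
#' @param min_focus_area minimum focus area in pixels.
#' @return A list of class `foci_quant`: `threshold`, `mu_bg`, `sigma_bg`,
#'   `n_foci`, `foci` tibble (`focus`, `area_px`, `integrated_intensity`,
#'   `centroid_row`, `centroid_col`), `mask`.
#' @export
detect_foci <- function(img, channel = 1, background = "auto", k = 2,
                        min_focus_area = 4) {
  m <- if (inherits(img, "rm_image")) image_channel(img, channel) else img
  if (identical(background, "auto")) {
    mu <- stats::median(m)
    sigma <- stats::mad(m)
  } else if (is.logical(background)) {
    mu <- mean(m[background])
    sigma <- stats::sd(m[background])
  } else {
    mu <- background[1]
    sigma <- background[2]
  }
  if (sigma == 0 && all(m == mu)) {
    abort_rmquant("degenerate threshold: image has no intensity variation",
                  "rmquant_threshold_error")
  }
  threshold <- mu + k * sigma
  lab <- bwlabel8(m > threshold)
  foci <- list()
  mask <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(max(lab))) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_focus_area) next
    mask[idx] <- TRUE
    foci[[length(foci) + 1]] <- tibble::tibble(
      focus = length(foci) + 1L, area_px = nrow(idx),
      integrated_intensity = sum(m[idx] - mu),
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2])
    )
  }
  foci <- if (length(foci) > 0) dplyr::bind_rows(foci) else
    tibble::tibble(focus = integer(), area_px = integer(),
                   integrated_intensity = numeric(),
                   centroid_row = numeric(), centroid_col = numeric())
  structure(list(threshold = threshold, mu_bg = mu, sigma_bg = sigma,
                 n_foci = nrow(foci), foci = foci, mask = mask),
            class = "foci_quant")
}

#' @export
print.foci_quant <- function(x, ...) {
  cat(sprintf("<foci_quant> %d foci above threshold %.3g (bg %.3g +/- %.3g)\n",
              x$n_foci, x$threshold, x$mu_bg, x$sigma_bg))
  invisible(x)
}

#' Summarise foci across replicate images
#'
#' Averages of focus count and integrated intensity across the images of a
#' sample (the assays average 10 images per condition).
#'
#' @param quants list of `foci_quant` objects.
#' @return A one-row tibble: `n_images`, `mean_n_foci`,
#'   `mean_total_intensity` (sum over foci, averaged over images),
#'   `mean_focus_intensity` (per-focus average).
#' @export
summarize_foci <- function(quants) {
  if (length(quants) == 0) {
    abort_rmquant("no images supplied", "rmquant_parameter_error")
  }
  per_img <- purrr::map_dfr(quants, function(q) {
    tibble::tibble(n_foci = q$n_foci,
                   total_intensity = sum(q$foci$integrated_intensity))
  })
  all_foci <- purrr::map_dfr(quants, "foci")
  tibble::tibble(
    n_images = length(quants),
    mean_n_foci = mean(per_img$n_foci),
    mean_total_intensity = mean(per_img$total_intensity),
    mean_focus_intensity = if (nrow(all_foci) > 0) {
      mean(all_foci$integrated_intensity)
    } else NA_real_
  )
}
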