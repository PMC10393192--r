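#' Condensate scene parameters
#'
#' Describes a synthetic two-channel confocal scene of one nucleoprotein
#' condensate: a dense circular core surrounded by a dimmer annular halo on
#' a low background. Defaults reproduce the median geometry of the
#' RM-TDB/1000-bp DNA condensates (core radius 940 nm, halo thickness
#' 657 nm) at the 100 nm/pixel confocal scan resolution.
#'
#' @param core_radius core radius in nm (> 0).
#' @param halo_thickness halo annulus width in nm (>= 0).
#' @param core_intensity,halo_intensity,background_intensity mean intensity
#'   per region, photon-count units; must satisfy core > halo > background.
#' @param pixel_size nm/pixel (default 100).
#' @param noise_sd additive Gaussian noise sd per channel, counts.
#' @param image_size pixels, `c(ny, nx)` or single integer; default sized to
#'   hold the condensate with a 25% margin.
#' @param seed integer seed for the noise.
#' @return A list of class `condensate_scene_params`.
#' @export
condensate_scene_params <- function(core_radius = 940, halo_thickness = 657,
                                    core_intensity = 150, halo_intensity = 50,
                                    background_intensity = 10,
                                    pixel_size = 100, noise_sd = 2,
                                    image_size = NULL, seed = NULL) {
  check_positive(core_radius, "core_radius")
  check_positive(halo_thickness, "halo_thickness", strict = FALSE)
  check_positive(pixel_size, "pixel_size")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (!(core_intensity > halo_intensity && halo_intensity > background_intensity)) {
    abort_rmquant("need core_intensity > halo_intensity > background_intensity",
                  "rmquant_parameter_error")
  }
  if (is.null(image_size)) {
    image_size <- ceiling(2.5 * (core_radius + halo_thickness) / pixel_size)
  }
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  structure(
    list(core_radius = core_radius, halo_thickness = halo_thickness,
         core_intensity = core_intensity, halo_intensity = halo_intensity,
         background_intensity = background_intensity,
         pixel_size = pixel_size, noise_sd = noise_sd,
         image_size = as.integer(image_size), seed = seed),
    class = "condensate_scene_params"
  )
}

#' Render a synthetic two-channel condensate image
#'
#' Renders a concentric disc (core) plus annulus (halo) with identical
#' geometry in the protein and DNA channels and independent additive noise
#' per channel. Pixel membership is decided at pixel centres.
#'
#' @param cp a [condensate_scene_params] object.
#' @return An [rm_image] with channels `protein` and `dna`. Attribute
#'   `center` records the true centre (x, y in nm).
#' @export
render_condensate_scene <- function(cp) {
  stopifnot(inherits(cp, "condensate_scene_params"))
  ny <- cp$image_size[1]; nx <- cp$image_size[2]
  r_out <- cp$core_radius + cp$halo_thickness
  if (2 * r_out > min(nx, ny) * cp$pixel_size) {
    abort_rmquant("halo annulus exceeds the image bounds",
                  "rmquant_render_error")
  }
  cx <- nx * cp$pixel_size / 2
  cy <- ny * cp$pixel_size / 2
  xc <- (seq_len(nx) - 0.5) * cp$pixel_size
  yc <- (seq_len(ny) - 0.5) * cp$pixel_size
  d <- sqrt(outer((yc - cy)^2, (xc - cx)^2, "+"))
  base <- matrix(cp$background_intensity, ny, nx)
  base[d <= r_out] <- cp$halo_intensity
  base[d <= cp$core_radius] <- cp$core_intensity
  data <- with_seed(cp$seed, {
    arr <- array(0, dim = c(ny, nx, 2))
    for (ch in 1:2) {
      noise <- if (cp$noise_sd > 0) {
        matrix(stats::rnorm(ny * nx, 0, cp$noise_sd), ny, nx)
      } else 0
      arr[, , ch] <- base + noise
    }
    arr
  })
  img <- rm_image(data, pixel_size = cp$pixel_size,
                  channels = c("protein", "dna"))
  attr(img, "center") <- c(cx, cy)
  img
}

#' Render a multi-focus condensation-assay image
#'
#' Produces a single-channel epifluorescence-like field with `k` disc foci
#' of given radii and intensities on a noisy background, emulating the
#' DNA-driven condensation assay images quantified by thresholded focus
#' counting.
#'
#' @param centers matrix (k x 2) of focus centres, nm.
#' @param radii vector of focus radii, nm.
#' @param intensities vector of focus intensities above background, counts.
#' @param image_size pixels, `c(ny, nx)` or single integer.
#' @param pixel_size nm/pixel.
#' @param background_mean,background_sd background level and noise, counts.
#' @param seed integer seed.
#' @return An [rm_image] with one channel `dna`.
#' @export
render_foci_scene <- function(centers, radii, intensities,
                              image_size = c(256, 256), pixel_size = 100,
                              background_mean = 10, background_sd = 2,
                              seed = NULL) {
  centers <- matrix(centers, ncol = 2)
  k <- nrow(centers)
  stopifnot(length(radii) == k, length(intensities) == k)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  ny <- image_size[1]; nx <- image_size[2]
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  base <- matrix(background_mean, ny, nx)
  for (i in seq_len(k)) {
    d <- sqrt(outer((yc - centers[i, 2])^2, (xc - centers[i, 1])^2, "+"))
    base[d <= radii[i]] <- base[d <= radii[i]] + intensities[i]
  }
  noise <- with_seed(seed, {
    if (background_sd > 0) {
      matrix(stats::rnorm(ny * nx, 0, background_sd), ny, nx)
    } else 0
  })
  rm_image(base + noise, pixel_size = pixel_size, channels = "dna")
}
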