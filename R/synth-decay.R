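#' Dissociation-decay simulation parameters
#'
#' Parameters for simulating ROI photon-count series after transfer of a
#' protein-coated DNA bundle to protein-free buffer: expected counts decay
#' as `background + i0 * exp(-k_true * t)`. Defaults use the measured
#' RM-TDB dissociation rate of 0.034 s^-1.
#'
#' @param k_true dissociation rate in s^-1 (>= 0).
#' @param i0 initial signal above background, counts/pixel.
#' @param background baseline counts/pixel.
#' @param frame_interval seconds between frames (> 0).
#' @param n_frames number of frames (>= 3).
#' @param noise_model `"poisson"`, `"none"`, or `list(gaussian = sd)`.
#' @param seed integer seed.
#' @return A list of class `decay_sim_params`.
#' @export
decay_sim_params <- function(k_true = 0.034, i0 = 50, background = 2,
                             frame_interval = 2, n_frames = 60,
                             noise_model = "poisson", seed = NULL) {
  check_positive(k_true, "k_true", strict = FALSE)
  check_positive(i0, "i0", strict = FALSE)
  check_positive(background, "background", strict = FALSE)
  check_positive(frame_interval, "frame_interval")
  if (n_frames < 3) {
    abort_rmquant("`n_frames` must be >= 3", "rmquant_parameter_error")
  }
  ok <- identical(noise_model, "poisson") || identical(noise_model, "none") ||
    (is.list(noise_model) && !is.null(noise_model$gaussian))
  if (!ok) {
    abort_rmquant("`noise_model` must be \"poisson\", \"none\", or list(gaussian = sd)",
                  "rmquant_parameter_error")
  }
  structure(
    list(k_true = k_true, i0 = i0, background = background,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         noise_model = noise_model, seed = seed),
    class = "decay_sim_params"
  )
}

#' Simulate a photon-count decay series
#'
#' @param dp a [decay_sim_params] object.
#' @return A tibble (`decay_series`) with columns `frame` (0-based), `t`
#'   (s), `counts` (counts/pixel); attribute `params` stores `dp`.
#' @export
simulate_decay <- function(dp) {
  stopifnot(inherits(dp, "decay_sim_params"))
  t <- (seq_len(dp$n_frames) - 1) * dp$frame_interval
  mu <- dp$background + dp$i0 * exp(-dp$k_true * t)
  counts <- with_seed(dp$seed, apply_count_noise(mu, dp$noise_model))
  out <- tibble::tibble(frame = seq_along(t) - 1L, t = t, counts = counts)
  attr(out, "params") <- dp
  class(out) <- c("decay_series", class(out))
  out
}

apply_count_noise <- function(mu, noise_model) {
  if (identical(noise_model, "poisson")) {
    stats::rpois(length(mu), mu)
  } else if (identical(noise_model, "none")) {
    mu
  } else {
    mu + stats::rnorm(length(mu), 0, noise_model$gaussian)
  }
}

#' Simulate a decaying confocal scan movie
#'
#' Renders full frames whose per-pixel counts follow the expected decay, so
#' the ROI-extraction and fitting pipeline can be exercised end to end on
#' image data rather than pre-extracted traces.
#'
#' @param dp a [decay_sim_params] object (`i0`/`background` are per-pixel
#'   means; Poisson noise is drawn per pixel).
#' @param frame_size frame dimensions in pixels, `c(ny, nx)` or single
#'   integer.
#' @param pixel_size nm/pixel.
#' @return A [scan_series].
#' @export
simulate_decay_movie <- function(dp, frame_size = c(32, 32), pixel_size = 100) {
  stopifnot(inherits(dp, "decay_sim_params"))
  if (length(frame_size) == 1) frame_size <- c(frame_size, frame_size)
  ny <- frame_size[1]; nx <- frame_size[2]
  t <- (seq_len(dp$n_frames) - 1) * dp$frame_interval
  mu <- dp$background + dp$i0 * exp(-dp$k_true * t)
  frames <- with_seed(dp$seed, {
    arr <- array(0, dim = c(ny, nx, dp$n_frames))
    for (i in seq_len(dp$n_frames)) {
      arr[, , i] <- matrix(apply_count_noise(rep(mu[i], ny * nx),
                                             dp$noise_model), ny, nx)
    }
    arr
  })
  scan_series(frames, frame_interval = dp$frame_interval,
              pixel_size = pixel_size, channel = "protein")
}
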