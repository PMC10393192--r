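#' AFM rendering parameters
#'
#' Controls rasterisation of simulated AFM scenes. Defaults emulate the
#' imaging conditions of the tapping-mode scans: ~1 nm/pixel resolution, a
#' DNA ridge whose post-broadening apparent height is ~0.5 nm, a tip
#' point-spread of ~2 nm, and a flat mica background with mild instrument
#' noise.
#'
#' @param rx,ry pixel size, nm/pixel (default 1 each).
#' @param image_size image dimensions in pixels, `c(ny, nx)` or a single
#'   integer for a square image.
#' @param dna_height amplitude of the stamped (pre-broadening) DNA ridge in
#'   nm. With the default `psf_sigma` the rendered apparent ridge height is
#'   ~0.2 * `dna_height`.
#' @param psf_sigma isotropic Gaussian tip-broadening sigma in nm (>= 0).
#' @param h_b_true true mean background height in nm.
#' @param background_sd Gaussian background noise sd in nm.
#' @param seed integer seed for the background noise.
#' @return A list of class `afm_render_params`.
#' @export
afm_render_params <- function(rx = 1, ry = 1, image_size = c(512, 512),
                              dna_height = 2.5, psf_sigma = 2,
                              h_b_true = 0, background_sd = 0.05,
                              seed = NULL) {
  check_positive(rx, "rx"); check_positive(ry, "ry")
  check_positive(psf_sigma, "psf_sigma", strict = FALSE)
  check_positive(background_sd, "background_sd", strict = FALSE)
  check_positive(dna_height, "dna_height")
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  image_size <- as.integer(image_size)
  if (any(image_size < 8)) {
    abort_rmquant("`image_size` too small", "rmquant_parameter_error")
  }
  structure(
    list(rx = rx, ry = ry, image_size = image_size, dna_height = dna_height,
         psf_sigma = psf_sigma, h_b_true = h_b_true,
         background_sd = background_sd, seed = seed),
    class = "afm_render_params"
  )
}

#' Protein particle specification
#'
#' Describes one bound (or free) protein particle to render as a 2D Gaussian
#' bump whose integrated volume above background equals `volume` exactly
#' (closed form `V = 2 pi sigma^2 h0`), so the height-map integrator can be
#' checked against an analytic oracle.
#'
#' @param position either a length-2 numeric `c(x, y)` in nm, or a single
#'   number in `[0, 1]`: the arclength fraction along the chain given by
#'   `chain`.
#' @param volume particle volume in nm^3 (> 0).
#' @param footprint_sigma Gaussian footprint sigma in nm (> 0), the
#'   as-imaged (post tip-broadening) footprint.
#' @param chain index of the chain the arclength fraction refers to.
#' @return A list of class `particle_spec`.
#' @export
particle_spec <- function(position, volume, footprint_sigma = 4, chain = 1L) {
  check_positive(volume, "volume")
  check_positive(footprint_sigma, "footprint_sigma")
  if (!length(position) %in% c(1, 2)) {
    abort_rmquant("`position` must be c(x, y) nm or an arclength fraction",
                  "rmquant_parameter_error")
  }
  if (length(position) == 1 && (position < 0 || position > 1)) {
    abort_rmquant("arclength fraction must lie in [0, 1]",
                  "rmquant_parameter_error")
  }
  structure(list(position = position, volume = volume,
                 footprint_sigma = footprint_sigma, chain = as.integer(chain)),
            class = "particle_spec")
}

# point at arclength fraction f along a polyline (nm coordinates)
point_at_fraction <- function(chain, f) {
  seg <- sqrt(diff(chain$x)^2 + diff(chain$y)^2)
  s <- c(0, cumsum(seg))
  target <- f * s[length(s)]
  i <- findInterval(target, s, rightmost.closed = TRUE)
  i <- max(1, min(i, length(seg)))
  w <- if (seg[i] > 0) (target - s[i]) / seg[i] else 0
  c(chain$x[i] + w * (chain$x[i + 1] - chain$x[i]),
    chain$y[i] + w * (chain$y[i + 1] - chain$y[i]))
}

# separable Gaussian convolution, sigma in pixels per axis
gauss_blur <- function(mat, sigma_row, sigma_col) {
  blur_1d <- function(m, sigma, along_rows) {
    if (sigma <= 0) return(m)
    half <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(-half:half, sd = sigma)
    k <- k / sum(k)
    apply_k <- function(v) {
      n <- length(v)
      vp <- c(rep(v[1], half), v, rep(v[n], half))
      stats::convolve(vp, rev(k), type = "filter")
    }
    if (along_rows) t(apply(m, 1, apply_k)) else apply(m, 2, apply_k)
  }
  m <- blur_1d(mat, sigma_col, along_rows = TRUE)
  blur_1d(m, sigma_row, along_rows = FALSE)
}

#' Render a synthetic AFM height map
#'
#' Builds a height map from DNA backbones and protein particles: chains are
#' stamped as 1-pixel ridges of height `dna_height`, broadened by an
#' isotropic Gaussian point-spread of sigma `psf_sigma`; particles are added
#' as 2D Gaussian bumps normalised so each integrates to its requested
#' volume; Gaussian background noise (mean `h_b_true`, sd `background_sd`)
#' is added last, after the point-spread convolution.
#'
#' @param chains list of chains from [sample_wlc_chain()] (or any two-column
#'   x/y tables in nm). May be empty.
#' @param particles list of [particle_spec()] objects. May be empty.
#' @param rp an [afm_render_params] object.
#' @return A [height_map]. Attribute `particle_centers` records the rendered
#'   particle centres (nm) for ground-truth checks.
#' @export
render_afm_scene <- function(chains = list(), particles = list(), rp) {
  stopifnot(inherits(rp, "afm_render_params"))
  if (inherits(chains, "data.frame")) chains <- list(chains)
  if (inherits(particles, "particle_spec")) particles <- list(particles)
  ny <- rp$image_size[1]; nx <- rp$image_size[2]
  wx <- nx * rp$rx; wy <- ny * rp$ry

  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    pad <- 3 * rp$psf_sigma
    if (any(ch$x < pad) || any(ch$x > wx - pad) ||
        any(ch$y < pad) || any(ch$y > wy - pad)) {
      abort_rmquant(sprintf("chain %d extends outside the image", i),
                    "rmquant_render_error")
    }
  }

  ideal <- matrix(0, ny, nx)
  step <- min(rp$rx, rp$ry) / 4
  for (ch in chains) {
    seg <- sqrt(diff(ch$x)^2 + diff(ch$y)^2)
    s <- c(0, cumsum(seg))
    total <- s[length(s)]
    ss <- seq(0, total, by = step)
    i <- findInterval(ss, s, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1), length(seg))
    w <- ifelse(seg[i] > 0, (ss - s[i]) / seg[i], 0)
    px <- ch$x[i] + w * (ch$x[i + 1] - ch$x[i])
    py <- ch$y[i] + w * (ch$y[i + 1] - ch$y[i])
    col <- pmin(pmax(floor(px / rp$rx) + 1, 1), nx)
    row <- pmin(pmax(floor(py / rp$ry) + 1, 1), ny)
    ideal[unique(cbind(row, col))] <- rp$dna_height
  }
  if (length(chains) > 0 && rp$psf_sigma > 0) {
    ideal <- gauss_blur(ideal, rp$psf_sigma / rp$ry, rp$psf_sigma / rp$rx)
  }

  centers <- matrix(numeric(0), 0, 2)
  xc <- (seq_len(nx) - 0.5) * rp$rx
  yc <- (seq_len(ny) - 0.5) * rp$ry
  for (i in seq_along(particles)) {
    p <- particles[[i]]
    pos <- if (length(p$position) == 2) {
      p$position
    } else {
      if (p$chain > length(chains)) {
        abort_rmquant(sprintf("particle %d references missing chain %d",
                              i, p$chain), "rmquant_render_error")
      }
      point_at_fraction(chains[[p$chain]], p$position)
    }
    sig <- p$footprint_sigma
    if (pos[1] < 4 * sig || pos[1] > wx - 4 * sig ||
        pos[2] < 4 * sig || pos[2] > wy - 4 * sig) {
      abort_rmquant(sprintf("particle %d extends outside the image", i),
                    "rmquant_render_error")
    }
    h0 <- p$volume / (2 * pi * sig^2)
    jr <- which(abs(xc - pos[1]) <= 6 * sig)
    ir <- which(abs(yc - pos[2]) <= 6 * sig)
    bump <- h0 * exp(-outer((yc[ir] - pos[2])^2, (xc[jr] - pos[1])^2, "+") /
                       (2 * sig^2))
    ideal[ir, jr] <- ideal[ir, jr] + bump
    centers <- rbind(centers, pos)
  }

  noise <- with_seed(rp$seed, {
    if (rp$background_sd > 0) {
      matrix(stats::rnorm(ny * nx, 0, rp$background_sd), ny, nx)
    } else {
      matrix(0, ny, nx)
    }
  })
  hm <- height_map(ideal + rp$h_b_true + noise, rx = rp$rx, ry = rp$ry)
  attr(hm, "particle_centers") <- centers
  hm
}
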