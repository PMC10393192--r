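#' Worm-like-chain parameters
#'
#' Parameter set for sampling surface-equilibrated 2D worm-like-chain (WLC)
#' DNA backbones. The default rise per base pair of 0.383 nm/bp reproduces
#' the expected contour of the 1000-bp linear substrate used throughout the
#' binding and condensation experiments (0.383 um); it is exposed because the
#' canonical B-DNA rise is 0.34 nm/bp and the effective rise of a given
#' amplicon on mica may differ.
#'
#' @param contour_length total backbone arclength in nm. Supply either this
#'   or `n_bp`.
#' @param n_bp number of base pairs; converted via `rise_per_bp` when
#'   `contour_length` is missing.
#' @param persistence_length bending persistence length in nm (~50 nm for
#'   dsDNA adsorbed after 2D equilibration).
#' @param rise_per_bp helical rise in nm/bp used to convert `n_bp`.
#' @param n_segments number of straight segments discretising the chain.
#' @param closed TRUE for a circular (plasmid-like) substrate.
#' @return A list of class `wlc_params`.
#' @export
wlc_params <- function(contour_length = NULL, n_bp = NULL,
                       persistence_length = 50, rise_per_bp = 0.383,
                       n_segments = 200, closed = FALSE) {
  check_positive(rise_per_bp, "rise_per_bp")
  if (is.null(contour_length)) {
    if (is.null(n_bp)) {
      abort_rmquant("supply `contour_length` or `n_bp`",
                    "rmquant_parameter_error")
    }
    contour_length <- n_bp * rise_per_bp
  }
  check_positive(contour_length, "contour_length")
  check_positive(persistence_length, "persistence_length")
  check_flag(closed, "closed")
  if (n_segments < 2) {
    abort_rmquant("`n_segments` must be >= 2", "rmquant_parameter_error")
  }
  structure(
    list(contour_length = contour_length,
         persistence_length = persistence_length,
         rise_per_bp = rise_per_bp,
         n_segments = as.integer(n_segments),
         closed = closed),
    class = "wlc_params"
  )
}

#' Sample a 2D worm-like chain
#'
#' Draws one chain conformation from the 2D WLC ensemble: successive bending
#' angles are Gaussian with variance `l / Lp` (segment length over
#' persistence length), which gives the 2D tangent-correlation decay
#' `<cos theta(s)> = exp(-s / (2 Lp))` appropriate for molecules that
#' equilibrate on the surface before imaging. Total polyline length equals
#' `contour_length` exactly by construction. Closed chains use a Gaussian
#' bridge on the turning angles (total turning 2*pi) followed by an
#' iterative closure of the endpoint gap that preserves segment lengths.
#'
#' @param wlc a [wlc_params] object.
#' @param seed integer seed; the draw is a pure function of `(wlc, seed)`.
#' @return A tibble with columns `x`, `y` (nm). For closed chains the first
#'   vertex is repeated as the last. Attribute `wlc` carries the parameters.
#' @export
sample_wlc_chain <- function(wlc, seed = NULL) {
  stopifnot(inherits(wlc, "wlc_params"))
  n <- wlc$n_segments
  ell <- wlc$contour_length / n
  sd_theta <- sqrt(ell / wlc$persistence_length)
  pts <- with_seed(seed, {
    if (!wlc$closed) {
      phi0 <- stats::runif(1, 0, 2 * pi)
      dphi <- stats::rnorm(n - 1, 0, sd_theta)
      phi <- phi0 + cumsum(c(0, dphi))
      x <- cumsum(c(0, ell * cos(phi)))
      y <- cumsum(c(0, ell * sin(phi)))
      cbind(x, y)
    } else {
      eps <- stats::rnorm(n, 0, sd_theta)
      dphi <- 2 * pi / n + (eps - mean(eps))  # bridge: total turning 2*pi
      phi <- stats::runif(1, 0, 2 * pi) + cumsum(dphi)
      v <- ell * cbind(cos(phi), sin(phi))
      # iterative closure: remove the residual end-to-end gap while keeping
      # every segment at length ell
      for (it in seq_len(500)) {
        gap <- colSums(v)
        if (sqrt(sum(gap^2)) < 1e-10 * ell) break
        v <- sweep(v, 2, gap / n)
        v <- v * (ell / sqrt(rowSums(v^2)))
      }
      r <- rbind(c(0, 0), apply(v, 2, cumsum))
      r[nrow(r), ] <- c(0, 0)  # matched ends
      colnames(r) <- c("x", "y")
      r
    }
  })
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2])
  attr(out, "wlc") <- wlc
  class(out) <- c("wlc_chain", class(out))
  out
}

#' Polyline arclength
#'
#' @param chain a two-column object with `x`, `y` coordinates in nm.
#' @return total length in nm.
#' @export
polyline_length <- function(chain) {
  dx <- diff(chain$x)
  dy <- diff(chain$y)
  sum(sqrt(dx^2 + dy^2))
}
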