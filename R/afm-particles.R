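#' Detect protein particles on a traced molecule
#'
#' Finds discrete bound-protein particles as connected pixel groups whose
#' height exceeds the DNA ridge by a margin. The apparent ridge height is
#' estimated as the median height above background along the skeleton;
#' pixels above `h_b + (1 + margin) * ridge` (margin default 2, i.e. 3x the
#' ridge) are dilated by one pixel and labelled.
#'
#' @param hm a [height_map].
#' @param region the `molecule_region` of the molecule.
#' @param trace the corresponding `molecule_trace`.
#' @param bg a `background_model`.
#' @param margin particle threshold margin in units of the ridge height.
#' @param min_particle_area minimum particle area in pixels.
#' @return A tibble with one row per particle: `particle`, `centroid_row`,
#'   `centroid_col` (pixels), `area_px`, `volume_nm3`, and a list-column
#'   `pixels` of coordinate matrices.
#' @export
detect_particles <- function(hm, region, trace, bg, margin = 2,
                             min_particle_area = 4) {
  stopifnot(inherits(hm, "height_map"), inherits(trace, "molecule_trace"))
  h <- hm$heights
  ridge <- stats::median(h[trace$skeleton_px]) - bg$h_b
  thr <- bg$h_b + (1 + margin) * ridge
  full <- region_full_mask(region, dim(h))
  pmask <- full & h > thr
  if (any(pmask)) {
    pmask <- EBImage::dilate(pmask * 1, EBImage::makeBrush(3, "box")) > 0
    pmask <- pmask & full
  }
  lab <- bwlabel8(pmask)
  out <- list()
  for (i in seq_len(max(lab))) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_particle_area) next
    m <- matrix(FALSE, nrow(h), ncol(h))
    m[idx] <- TRUE
    out[[length(out) + 1]] <- tibble::tibble(
      particle = length(out) + 1L,
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
      area_px = nrow(idx),
      volume_nm3 = hm$rx * hm$ry * sum(pmax(h[idx] - bg$h_b, 0)),
      pixels = list(idx)
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(particle = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area_px = integer(),
                          volume_nm3 = numeric(), pixels = list()))
  }
  dplyr::bind_rows(out)
}

# arclength distance (nm) from each pixel of each segment to the nearest
# free skeleton end; Inf where no free end is reachable along the segment
segment_end_distance <- function(trace, px) {
  best <- Inf
  for (s in trace$segments_raw) {
    hit <- which(s$path[, 1] == px[1] & s$path[, 2] == px[2])
    if (length(hit) == 0) next
    dr <- abs(diff(s$path[, 1])); dc <- abs(diff(s$path[, 2]))
    diag_step <- sqrt(trace$rx^2 + trace$ry^2)
    step <- ifelse(dr & dc, diag_step, ifelse(dc, trace$rx, trace$ry))
    cum <- c(0, cumsum(step))
    total <- cum[length(cum)]
    for (h in hit) {
      if (s$free[1]) best <- min(best, cum[h])
      if (s$free[2]) best <- min(best, total - cum[h])
    }
  }
  best
}

#' Classify particles as end-bound or interstitial
#'
#' Each detected particle is assigned to its nearest skeleton pixel and
#' labelled `end` when its arclength distance to a free skeleton endpoint is
#' within `end_tolerance`, else `interstitial`. Sets `N_p`, the number of
#' particles on the molecule.
#'
#' @param trace a `molecule_trace`.
#' @param particles particle tibble from [detect_particles()].
#' @param end_tolerance arclength tolerance in nm for the `end` call.
#' @return The trace with `particles` (tibble gaining `position` and
#'   `end_distance_nm`) and `n_particles` filled in.
#' @export
classify_particles <- function(trace, particles, end_tolerance = 20) {
  stopifnot(inherits(trace, "molecule_trace"))
  if (nrow(particles) == 0) {
    trace$particles <- particles
    trace$n_particles <- 0L
    return(trace)
  }
  sk <- trace$skeleton_px
  res <- purrr::map_dfr(seq_len(nrow(particles)), function(i) {
    pr <- particles[i, ]
    d2 <- (sk[, 1] - pr$centroid_row)^2 * trace$ry^2 +
      (sk[, 2] - pr$centroid_col)^2 * trace$rx^2
    nearest <- sk[which.min(d2), ]
    d_end <- segment_end_distance(trace, nearest)
    tibble::tibble(end_distance_nm = d_end,
                   position = if (d_end <= end_tolerance) "end" else "interstitial")
  })
  trace$particles <- dplyr::bind_cols(particles, res)
  trace$n_particles <- nrow(particles)
  trace
}

#' Analyse one molecule end to end
#'
#' Convenience wrapper: trace the skeleton, decompose branches, detect and
#' classify particles, and integrate the molecular volume.
#'
#' @param hm a [height_map].
#' @param region a `molecule_region`.
#' @param bg a `background_model`.
#' @param ... passed to [trace_skeleton()].
#' @return A `molecule_trace` with `volume_nm3` attached.
#' @export
analyze_molecule <- function(hm, region, bg, ...) {
  trace <- decompose_branches(trace_skeleton(region, hm, ...))
  particles <- detect_particles(hm, region, trace, bg)
  trace <- classify_particles(trace, particles)
  trace$volume_nm3 <- integrate_volume(hm, region, bg)
  trace
}

#' Tabulate a set of traced molecules
#'
#' @param traces list of `molecule_trace` objects.
#' @return A tibble with one row per molecule: `id`, `contour_length_nm`,
#'   `contour_length_steps_nm`, `n_particles`, `volume_nm3`, `n_segments`.
#' @export
molecule_table <- function(traces) {
  purrr::map_dfr(traces, function(tr) {
    tibble::tibble(
      id = tr$label,
      contour_length_nm = tr$contour_length_nm,
      contour_length_steps_nm = tr$contour_length_steps_nm,
      n_particles = if (is.na(tr$n_particles)) NA_integer_ else tr$n_particles,
      volume_nm3 = tr$volume_nm3 %||% NA_real_,
      n_segments = length(tr$segments_raw)
    )
  })
}
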