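# Skeleton machinery: Zhang-Suen thinning, spur pruning, path ordering and
# length measurement. These primitives are the contour-tracing method under
# study, so they are implemented here rather than delegated.

shift_mat <- function(m, dr, dc) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  rs <- max(1, 1 + dr):min(ny, ny + dr)
  cs <- max(1, 1 + dc):min(nx, nx + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# 8-neighbourhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
zs_offsets <- rbind(
  c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
  c(1, 0), c(1, -1), c(0, -1), c(-1, -1)
)

neighbour_stack <- function(m) {
  lapply(seq_len(8), function(k) shift_mat(m, zs_offsets[k, 1], zs_offsets[k, 2]))
}

neighbour_count <- function(m) {
  Reduce(`+`, lapply(neighbour_stack(m), function(x) x * 1L))
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen iterative thinning to a 1-pixel-wide, 8-connected skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- neighbour_stack(m)
      B <- Reduce(`+`, lapply(P, function(x) x * 1L))
      seqP <- c(P, P[1])
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in seq_len(8)) {
        A <- A + (!seqP[[k]] & seqP[[k + 1]])
      }
      if (step == 1) {
        extra <- !(P[[1]] & P[[3]] & P[[5]]) & !(P[[3]] & P[[5]] & P[[7]])
      } else {
        extra <- !(P[[1]] & P[[3]] & P[[7]]) & !(P[[1]] & P[[5]] & P[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & extra
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Reduce a thinned skeleton to minimal 8-connectivity: a pixel whose
# skeleton neighbours form a single 8-connected component within its 3x3
# ring is redundant (its removal cannot break connectivity) and is deleted.
# This removes the staircase-corner doubling that thinning leaves on
# diagonal runs, which would otherwise read as spurious branch points.
# Deletion is sequential so adjacent redundant pixels cannot both vanish.
clean_skeleton <- function(skel) {
  repeat {
    idx <- which(skel, arr.ind = TRUE)
    changed <- FALSE
    for (i in seq_len(nrow(idx))) {
      p <- idx[i, ]
      if (!skel[p[1], p[2]]) next
      nbrs <- pixel_neighbours(skel, p)
      n <- nrow(nbrs)
      if (n < 2) next
      # connected components of the neighbours within the 3x3 ring
      comp <- seq_len(n)
      for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
          if (max(abs(nbrs[a, ] - nbrs[b, ])) <= 1) {
            comp[comp == comp[b]] <- comp[a]
          }
        }
      }
      if (length(unique(comp)) == 1) {
        skel[p[1], p[2]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  skel
}

# remove spur branches shorter than prune_len pixels that terminate at a
# junction; repeated until stable
prune_spurs <- function(skel, prune_len = 5) {
  if (prune_len <= 0) return(skel)
  repeat {
    nb <- neighbour_count(skel)
    ends <- which(skel & nb == 1, arr.ind = TRUE)
    if (nrow(ends) == 0) break
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      cur <- ends[e, ]
      if (!skel[cur[1], cur[2]]) next
      path <- matrix(cur, 1, 2)
      prev <- c(NA, NA)
      hit_junction <- FALSE
      for (s in seq_len(prune_len + 1)) {
        nbrs <- pixel_neighbours(skel, cur)
        if (!is.na(prev[1])) {
          keep <- !(nbrs[, 1] == prev[1] & nbrs[, 2] == prev[2])
          nbrs <- nbrs[keep, , drop = FALSE]
        }
        if (nrow(nbrs) == 0) break
        if (nrow(nbrs) >= 2) { hit_junction <- TRUE; break }
        nxt <- nbrs[1, ]
        if (neighbour_count_at(skel, nxt) >= 3) { hit_junction <- TRUE; break }
        prev <- cur
        cur <- nxt
        path <- rbind(path, cur)
      }
      if (hit_junction && nrow(path) <= prune_len) {
        skel[path] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skel
}

pixel_neighbours <- function(skel, px) {
  rr <- px[1] + zs_offsets[, 1]
  cc <- px[2] + zs_offsets[, 2]
  ok <- rr >= 1 & rr <= nrow(skel) & cc >= 1 & cc <= ncol(skel)
  rr <- rr[ok]; cc <- cc[ok]
  on <- skel[cbind(rr, cc)]
  cbind(rr[on], cc[on])
}

neighbour_count_at <- function(skel, px) {
  nrow(pixel_neighbours(skel, px))
}

# order a set of degree<=2 pixels into a path, starting from `start`
walk_path <- function(skel, start, visited = NULL) {
  if (is.null(visited)) visited <- matrix(FALSE, nrow(skel), ncol(skel))
  path <- matrix(start, 1, 2)
  visited[start[1], start[2]] <- TRUE
  cur <- start
  repeat {
    nbrs <- pixel_neighbours(skel, cur)
    if (nrow(nbrs) == 0) break
    unv <- nbrs[!visited[nbrs], , drop = FALSE]
    if (nrow(unv) == 0) break
    if (nrow(unv) > 1) {
      # prefer orthogonal continuation for stable ordering on staircases
      d <- abs(unv[, 1] - cur[1]) + abs(unv[, 2] - cur[2])
      unv <- unv[order(d), , drop = FALSE]
    }
    cur <- unv[1, ]
    visited[cur[1], cur[2]] <- TRUE
    path <- rbind(path, cur)
  }
  path
}

# centred running mean with shrinking windows at the ends
running_mean <- function(v, w) {
  n <- length(v)
  if (w <= 1 || n <= 2) return(v)
  half <- floor(w / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# length of an ordered pixel path; returns smoothed Euclidean length and the
# raw orthogonal/diagonal step length
path_length_nm <- function(path, rx, ry, smooth_window = 5, cyclic = FALSE) {
  if (nrow(path) < 2) {
    return(c(smooth = 0, steps = 0))
  }
  x <- (path[, 2] - 0.5) * rx
  y <- (path[, 1] - 0.5) * ry
  # shrink the smoothing window on short paths so they are not collapsed
  smooth_window <- min(smooth_window, max(1, 2 * floor((nrow(path) - 1) / 4) + 1))
  dr <- abs(diff(path[, 1])); dc <- abs(diff(path[, 2]))
  diag_step <- sqrt(rx^2 + ry^2)
  steps <- sum(ifelse(dr & dc, diag_step, ifelse(dc, rx, ry)))
  if (cyclic) {
    steps <- steps + {
      ddr <- abs(path[1, 1] - path[nrow(path), 1])
      ddc <- abs(path[1, 2] - path[nrow(path), 2])
      ifelse(ddr & ddc, diag_step, ifelse(ddc, rx, ry))
    }
    n <- length(x)
    half <- floor(smooth_window / 2)
    if (smooth_window > 1 && n > 2 * half) {
      idx <- c((n - half + 1):n, 1:n, 1:half)
      xs <- running_mean(x[idx], smooth_window)[(half + 1):(half + n)]
      ys <- running_mean(y[idx], smooth_window)[(half + 1):(half + n)]
    } else {
      xs <- x; ys <- y
    }
    sm <- sum(sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2))
  } else {
    xs <- running_mean(x, smooth_window)
    ys <- running_mean(y, smooth_window)
    sm <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }
  c(smooth = sm, steps = steps)
}

# decompose a skeleton into junction nodes and ordered segment paths
skeleton_graph <- function(skel) {
  nb <- neighbour_count(skel)
  junction <- skel & nb >= 3
  endpoints <- which(skel & nb == 1, arr.ind = TRUE)
  n_on <- sum(skel)
  if (n_on == 0) {
    abort_rmquant("empty skeleton", "rmquant_trace_error")
  }
  if (!any(junction)) {
    if (nrow(endpoints) == 0) {
      start <- which(skel, arr.ind = TRUE)[1, , drop = FALSE]
      path <- walk_path(skel, start[1, ])
      return(list(segments = list(list(path = path, free = c(FALSE, FALSE),
                                       cyclic = TRUE)),
                  nodes = list(), endpoints = endpoints, is_cycle = TRUE))
    }
    path <- walk_path(skel, endpoints[1, ])
    return(list(segments = list(list(path = path, free = c(TRUE, TRUE),
                                     cyclic = FALSE)),
                nodes = list(), endpoints = endpoints, is_cycle = FALSE))
  }
  # junction clusters (adjacent >=3-neighbour pixels merged into one node)
  jlab <- bwlabel8(junction)
  n_nodes <- max(jlab)
  nodes <- lapply(seq_len(n_nodes), function(i) {
    which(jlab == i, arr.ind = TRUE)
  })
  body <- skel & !junction
  blab <- bwlabel8(body)
  segments <- list()
  for (i in seq_len(max(blab))) {
    bmask <- blab == i
    bnb <- neighbour_count(bmask)
    ends <- which(bmask & bnb <= 1, arr.ind = TRUE)
    start <- if (nrow(ends) > 0) ends[1, ] else which(bmask, arr.ind = TRUE)[1, ]
    path <- walk_path(bmask, start)
    # attach the nearest junction pixel at each end when one adjoins it
    attach_node <- function(px) {
      nbrs <- pixel_neighbours(junction, px)
      if (nrow(nbrs) == 0) return(NULL)
      nbrs[1, ]
    }
    head_j <- attach_node(path[1, ])
    tail_j <- attach_node(path[nrow(path), ])
    if (!is.null(head_j)) path <- rbind(head_j, path)
    if (!is.null(tail_j)) path <- rbind(path, tail_j)
    segments[[length(segments) + 1]] <-
      list(path = path, free = c(is.null(head_j), is.null(tail_j)),
           cyclic = FALSE)
  }
  list(segments = segments, nodes = nodes, endpoints = endpoints,
       is_cycle = FALSE)
}

#' Trace the skeleton of a segmented molecule
#'
#' Thins the molecule mask to a 1-pixel skeleton, prunes spurs shorter than
#' `prune_len` pixels, decomposes the skeleton into segments between branch
#' points, and measures the contour length. The default length metric is the
#' Euclidean length of the coordinate-smoothed ordered pixel path (window
#' `smooth_window` pixels), which is orientation-unbiased; the raw
#' orthogonal/diagonal step length is also reported as `length_steps_nm`.
#' Because thinning retracts the skeleton from each molecule tip by about
#' half the local ridge width, an end-cap correction is added per free end:
#' with `endcap = "auto"` the local half-width from the Euclidean distance
#' map is used, matching the one-pixel correction for 1-pixel-wide masks.
#'
#' @param region a `molecule_region` from [segment_molecules()].
#' @param hm the [height_map] the region came from.
#' @param prune_len spur-pruning length in pixels.
#' @param smooth_window smoothing window (pixels) for the length metric.
#' @param endcap `"auto"` or a numeric number of pixels added per free end.
#' @param calibration global multiplicative length calibration factor.
#' @return An object of class `molecule_trace`: skeleton pixel coordinates
#'   (global, row/col), segment list, endpoints, `contour_length_nm`,
#'   `contour_length_steps_nm`, `is_cycle`, and provenance fields.
#' @export
trace_skeleton <- function(region, hm, prune_len = 5, smooth_window = 5,
                           endcap = "auto", calibration = 1) {
  stopifnot(inherits(region, "molecule_region"), inherits(hm, "height_map"))
  pad <- 1L
  local <- region$mask
  m <- matrix(FALSE, nrow(local) + 2 * pad, ncol(local) + 2 * pad)
  m[(pad + 1):(pad + nrow(local)), (pad + 1):(pad + ncol(local))] <- local
  skel <- prune_spurs(clean_skeleton(skeletonize(m)), prune_len)
  if (sum(skel) == 0) {
    abort_rmquant("region degenerates to an empty skeleton after pruning",
                  "rmquant_trace_error")
  }
  g <- skeleton_graph(skel)
  rx <- hm$rx; ry <- hm$ry
  seg_info <- purrr::map(g$segments, function(s) {
    len <- path_length_nm(s$path, rx, ry, smooth_window, cyclic = s$cyclic)
    c(s, list(length_nm = unname(len["smooth"]),
              length_steps_nm = unname(len["steps"])))
  })
  n_free_ends <- sum(purrr::map_int(seg_info, ~ sum(.x$free)))
  endcap_nm <- 0
  if (n_free_ends > 0) {
    px_nm <- (rx + ry) / 2
    if (identical(endcap, "auto")) {
      # thinning retracts the skeleton from the molecule tip; restore the
      # distance from the skeleton endpoint to the mask boundary along the
      # backbone direction, minus the lateral half-width (tip overhang from
      # isotropic broadening)
      dm <- EBImage::distmap(m * 1)
      mask_num <- m * 1
      for (s in seg_info) {
        np <- nrow(s$path)
        for (side in 1:2) {
          if (!s$free[side]) next
          p_end <- if (side == 1) s$path[1, ] else s$path[np, ]
          p_back <- if (side == 1) s$path[min(np, 7), ] else s$path[max(1, np - 6), ]
          d <- p_end - p_back
          nd <- sqrt(sum(d^2))
          if (nd == 0) next
          d <- d / nd
          tt <- seq(0, 20, by = 0.25)
          uu <- p_end[1] + tt * d[1]
          vv <- p_end[2] + tt * d[2]
          ok <- uu >= 1 & uu <= nrow(m) & vv >= 1 & vv <= ncol(m)
          vals <- bilinear_at(mask_num, uu[ok], vv[ok])
          out_i <- which(vals < 0.5)
          t_end <- if (length(out_i) > 0) tt[ok][out_i[1]] else max(tt[ok])
          halfw <- dm[p_end[1], p_end[2]]
          endcap_nm <- endcap_nm + max(t_end - halfw, 0) * px_nm
        }
      }
    } else {
      endcap_nm <- n_free_ends * endcap * px_nm
    }
  }
  total_smooth <- sum(purrr::map_dbl(seg_info, "length_nm"))
  total_steps <- sum(purrr::map_dbl(seg_info, "length_steps_nm"))
  # convert local (padded) pixel coordinates back to global image pixels
  off <- c(region$bbox[1] - 1 - pad, region$bbox[3] - 1 - pad)
  globalize <- function(p) cbind(p[, 1] + off[1], p[, 2] + off[2])
  seg_info <- purrr::map(seg_info, function(s) {
    s$path <- globalize(s$path)
    s
  })
  skel_px <- globalize(which(skel, arr.ind = TRUE))
  endpoints <- if (nrow(g$endpoints) > 0) globalize(g$endpoints) else g$endpoints
  structure(
    list(label = region$label, region = region,
         skeleton_px = skel_px, segments_raw = seg_info,
         endpoints = endpoints,
         branch_nodes = purrr::map(g$nodes, globalize),
         is_cycle = g$is_cycle,
         contour_length_nm = calibration * (total_smooth + endcap_nm),
         contour_length_steps_nm = calibration * (total_steps + endcap_nm),
         endcap_nm = endcap_nm, rx = rx, ry = ry,
         n_particles = NA_integer_, particles = NULL),
    class = "molecule_trace"
  )
}

#' @export
print.molecule_trace <- function(x, ...) {
  cat(sprintf(
    "<molecule_trace> label %d: contour %.1f nm, %d segment(s), %d branch node(s)%s\n",
    x$label, x$contour_length_nm, length(x$segments_raw),
    length(x$branch_nodes), if (x$is_cycle) " (cycle)" else ""
  ))
  if (!is.na(x$n_particles)) {
    cat(sprintf("  particles: %d\n", x$n_particles))
  }
  invisible(x)
}

#' Decompose a traced skeleton into branch segments
#'
#' Splits the skeleton at branch points (pixels with >= 3 skeleton
#' neighbours; adjacent branch pixels merged into one junction node) and
#' tabulates per-segment lengths, as done for complex molecules with
#' multiple binding sites.
#'
#' @param trace a `molecule_trace` from [trace_skeleton()].
#' @return The trace with a `segments` tibble (`segment`, `n_px`,
#'   `length_nm`, `length_steps_nm`, `free_ends`) and `n_branch_points`.
#' @export
decompose_branches <- function(trace) {
  stopifnot(inherits(trace, "molecule_trace"))
  trace$segments <- dplyr::bind_rows(purrr::imap(trace$segments_raw, function(s, i) {
    tibble::tibble(segment = i, n_px = nrow(s$path),
                   length_nm = s$length_nm,
                   length_steps_nm = s$length_steps_nm,
                   free_ends = sum(s$free))
  }))
  trace$n_branch_points <- length(trace$branch_nodes)
  trace
}
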