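# Shared scene builders for the test suite. All geometry is in nm with the
# default 1 nm/pixel rendering.

# straight rod of `length_nm` at `angle_deg`, centred in a square image
rod_chain <- function(length_nm, angle_deg, center = 256, n = 200) {
  th <- angle_deg * pi / 180
  s <- seq(-length_nm / 2, length_nm / 2, length.out = n)
  tibble::tibble(x = center + cos(th) * s, y = center + sin(th) * s)
}

circle_chain <- function(radius_nm, center = 256, n = 400) {
  th <- seq(0, 2 * pi, length.out = n)[-n]
  tibble::tibble(x = center + radius_nm * cos(th),
                 y = center + radius_nm * sin(th))
}

# render chains/particles and return the traced largest kept molecule
trace_scene <- function(chains, particles = list(), background_sd = 0,
                        seed = NULL, image_size = 512, ...) {
  rp <- afm_render_params(image_size = image_size,
                          background_sd = background_sd, seed = seed)
  hm <- render_afm_scene(chains, particles, rp)
  bg <- estimate_background(hm)
  segs <- segment_molecules(hm, bg)
  kept <- segs[segs$kept, ]
  region <- kept$region[[which.max(kept$area_px)]]
  list(hm = hm, bg = bg, region = region,
       trace = trace_skeleton(region, hm, ...))
}
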