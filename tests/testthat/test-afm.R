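# AFM module: background, segmentation, skeleton tracing, volumes,
# particles, statistics.

test_that("background estimation recovers pure-noise statistics", {
  set.seed(1)
  hm <- height_map(matrix(stats::rnorm(256 * 256, 0.2, 0.05), 256, 256))
  bg <- estimate_background(hm)
  expect_equal(bg$h_b, 0.2, tolerance = 0.01)
  expect_equal(bg$sigma_b, 0.05, tolerance = 0.1)
})

test_that("background estimation isolates the lower mode of a bimodal map", {
  set.seed(2)
  h <- matrix(stats::rnorm(200 * 200, 0, 0.05), 200, 200)
  h[50:150, 50:150] <- h[50:150, 50:150] + 2  # large plateau
  bg <- estimate_background(height_map(h))
  expect_equal(bg$h_b, 0, tolerance = 0.01)
  expect_lt(bg$background_fraction, 1)
})

test_that("flat maps give zero-sd background and degenerate input errors", {
  bg <- estimate_background(height_map(matrix(1.5, 10, 10)))
  expect_equal(bg$h_b, 1.5)
  expect_equal(bg$sigma_b, 0)
})

test_that("segmentation finds separated molecules and applies filters", {
  rp <- afm_render_params(image_size = 256, background_sd = 0.05, seed = 8)
  ps <- list(particle_spec(c(70, 70), volume = 150, footprint_sigma = 4),
             particle_spec(c(180, 180), volume = 150, footprint_sigma = 4))
  hm <- render_afm_scene(list(), ps, rp)
  bg <- estimate_background(hm)
  segs <- segment_molecules(hm, bg)
  expect_equal(sum(segs$kept), 2)
  # raising min_area above the particle footprint drops both
  segs_big <- segment_molecules(hm, bg, min_area = 10000)
  expect_equal(sum(segs_big$kept), 0)
})

test_that("border-touching molecules are flagged and excluded", {
  rp <- afm_render_params(image_size = 200, background_sd = 0, psf_sigma = 1)
  ch <- rod_chain(120, 0, center = 100)
  ch$y <- ch$y - 97   # ridge at y ~ 3 nm: blurred support reaches row 1
  hm <- render_afm_scene(list(ch), list(), rp)
  bg <- estimate_background(hm)
  segs <- segment_molecules(hm, bg)
  expect_true(any(segs$touches_border))
  expect_false(any(segs$kept[segs$touches_border]))
})

test_that("straight rods trace within 2% at any orientation (noise-free)", {
  for (ang in c(0, 22.5, 45, 60, 77, 105, 160)) {
    sc <- trace_scene(list(rod_chain(300, ang)))
    expect_lt(abs(sc$trace$contour_length_nm - 300) / 300, 0.02,
              label = sprintf("rod at %g deg: %.1f nm", ang,
                              sc$trace$contour_length_nm))
  }
})

test_that("straight rods trace within 2% under study-condition noise", {
  for (ang in c(0, 45, 77)) {
    sc <- trace_scene(list(rod_chain(300, ang)), background_sd = 0.05,
                      seed = 3)
    expect_lt(abs(sc$trace$contour_length_nm - 300) / 300, 0.02)
  }
})

test_that("circles trace within 2% and are flagged as cycles", {
  sc <- trace_scene(list(circle_chain(80)))
  expect_true(sc$trace$is_cycle)
  expect_equal(sc$trace$endcap_nm, 0)
  truth <- 2 * pi * 80
  expect_lt(abs(sc$trace$contour_length_nm - truth) / truth, 0.02)
})

test_that("rod skeletons are simple paths with two endpoints", {
  sc <- trace_scene(list(rod_chain(200, 30)))
  expect_equal(length(sc$trace$segments_raw), 1)
  expect_equal(nrow(sc$trace$endpoints), 2)
  expect_equal(length(sc$trace$branch_nodes), 0)
})

test_that("branch decomposition conserves length and finds the junction", {
  # Y-shaped molecule: three 100 nm arms from a common hub
  arms <- lapply(c(90, 210, 330), function(a) {
    th <- a * pi / 180
    tibble::tibble(x = 256 + cos(th) * seq(0, 100, length.out = 60),
                   y = 256 + sin(th) * seq(0, 100, length.out = 60))
  })
  sc <- trace_scene(arms)
  tr <- decompose_branches(sc$trace)
  expect_equal(tr$n_branch_points, 1)
  expect_equal(nrow(tr$segments), 3)
  expect_equal(sum(tr$segments$free_ends), 3)
  # identity: segment lengths plus end caps assemble the total
  expect_equal(sum(tr$segments$length_nm) + tr$endcap_nm,
               tr$contour_length_nm)
  # oracle: total backbone is 3 x 100 nm
  expect_lt(abs(tr$contour_length_nm - 300) / 300, 0.05)
})

test_that("volume integration is linear in true particle volume", {
  vols <- c(50, 100, 200, 400)
  est <- vapply(vols, function(v) {
    rp <- afm_render_params(image_size = 256, background_sd = 0)
    p <- particle_spec(c(128, 128), volume = v, footprint_sigma = 4)
    hm <- render_afm_scene(list(), list(p), rp)
    bg <- estimate_background(hm)
    segs <- segment_molecules(hm, bg)
    integrate_volume(hm, segs$region[[which.max(segs$area_px)]], bg)
  }, numeric(1))
  expect_equal(est, vols, tolerance = 0.02)
  # linearity: doubling the volume doubles the estimate
  expect_equal(est[-1] / est[-length(est)], c(2, 2, 2), tolerance = 0.02)
})

test_that("integrate_volume validates its region argument", {
  hm <- height_map(matrix(0, 10, 10))
  expect_error(integrate_volume(hm, matrix(FALSE, 5, 5), 0),
               class = "rmquant_parameter_error")
  expect_error(integrate_volume(hm, matrix(FALSE, 10, 10), 0),
               class = "rmquant_volume_error")
})

test_that("trimer_volume implements MW / (rho N_A)", {
  # 20.7 nm^3 at rho 1.44 corresponds to ~17.9 kg/mol... checked by algebra
  expect_equal(trimer_volume(MW = 1.44 * 6.02214076e23 * 1e-21, rho = 1.44), 1)
  expect_equal(trimer_volume(18000, 1.44), 18000 / (1.44 * 6.02214076e23) * 1e21)
  expect_error(trimer_volume(-5), class = "rmquant_parameter_error")
})

test_that("count_trimers reproduces the published worked example", {
  s <- stoichiometry_inputs(V_d = 303, V_p = 20.7, N_p_mean = 2.2)
  ct <- count_trimers(s)
  expect_equal(ct$trimers_per_site, 303 / (20.7 * 2.2))
  expect_equal(ct$trimers_rounded, 7L)
})

test_that("particles on a rod are classified end vs interstitial", {
  ch <- rod_chain(300, 0)
  ps <- list(particle_spec(0.02, volume = 160, footprint_sigma = 4),
             particle_spec(0.50, volume = 160, footprint_sigma = 4))
  rp <- afm_render_params(image_size = 512, background_sd = 0.05, seed = 21)
  hm <- render_afm_scene(list(ch), ps, rp)
  bg <- estimate_background(hm)
  segs <- segment_molecules(hm, bg)
  kept <- segs[segs$kept, ]
  region <- kept$region[[which.max(kept$area_px)]]
  tr <- analyze_molecule(hm, region, bg)
  expect_equal(tr$n_particles, 2)
  expect_setequal(tr$particles$position, c("end", "interstitial"))
  expect_true(is.finite(tr$volume_nm3) && tr$volume_nm3 > 0)
})

test_that("molecule_table collects per-molecule measurements", {
  sc <- trace_scene(list(rod_chain(200, 15)))
  tab <- molecule_table(list(sc$trace))
  expect_equal(nrow(tab), 1)
  expect_true(all(c("contour_length_nm", "contour_length_steps_nm",
                    "n_particles", "volume_nm3", "n_segments") %in% names(tab)))
})

test_that("contour_length_stats groups, tests, and warns on empty groups", {
  set.seed(4)
  mols <- tibble::tibble(
    contour_length_nm = c(stats::rnorm(20, 358, 16), stats::rnorm(10, 290, 40),
                          stats::rnorm(8, 270, 40)),
    n_particles = c(rep(0L, 20), rep(1L, 10), rep(2L, 8))
  )
  expect_warning(st <- contour_length_stats(mols), "empty group")
  expect_equal(as.character(st$groups$group), c("free", "1", "2"))
  expect_equal(st$groups$n, c(20L, 10L, 8L))
  expect_equal(nrow(st$pairwise), 3)
  expect_true(st$pairwise$p_value[st$pairwise$group1 == "free" &
                                    st$pairwise$group2 == "1"] < 0.01)
  expect_false(is.na(st$kruskal_wallis$p_value))
  expect_equal(st$test, "Student")
})
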