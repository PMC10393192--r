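# Generators are tested against their closed-form oracles.

test_that("wlc chains have the exact requested contour length", {
  wlc <- wlc_params(contour_length = 358, n_segments = 150)
  for (s in 1:5) {
    ch <- sample_wlc_chain(wlc, seed = s)
    expect_equal(polyline_length(ch), 358, tolerance = 1e-10)
  }
})

test_that("wlc sampling is a pure function of (params, seed)", {
  wlc <- wlc_params(contour_length = 200)
  expect_identical(sample_wlc_chain(wlc, seed = 3), sample_wlc_chain(wlc, seed = 3))
  expect_false(identical(sample_wlc_chain(wlc, seed = 3),
                         sample_wlc_chain(wlc, seed = 4)))
})

test_that("wlc tangent correlations decay as exp(-s / (2 Lp))", {
  # ensemble average over many seeds at one segment separation
  wlc <- wlc_params(contour_length = 400, persistence_length = 50,
                    n_segments = 100)
  ell <- 400 / 100
  lag <- 10
  cors <- vapply(1:400, function(s) {
    ch <- sample_wlc_chain(wlc, seed = s)
    tx <- diff(ch$x) / ell; ty <- diff(ch$y) / ell
    n <- length(tx)
    mean(tx[1:(n - lag)] * tx[(1 + lag):n] +
           ty[1:(n - lag)] * ty[(1 + lag):n])
  }, numeric(1))
  expected <- exp(-lag * ell / (2 * 50))
  expect_equal(mean(cors), expected, tolerance = 0.05)
})

test_that("closed wlc chains close exactly with unit segment lengths", {
  wlc <- wlc_params(contour_length = 300, n_segments = 120, closed = TRUE)
  ch <- sample_wlc_chain(wlc, seed = 9)
  expect_equal(c(ch$x[1], ch$y[1]), c(ch$x[nrow(ch)], ch$y[nrow(ch)]))
  seg <- sqrt(diff(ch$x)^2 + diff(ch$y)^2)
  expect_equal(max(abs(seg - 300 / 120)), 0, tolerance = 1e-6)
})

test_that("wlc parameter validation", {
  expect_error(wlc_params(), class = "rmquant_parameter_error")
  expect_equal(wlc_params(n_bp = 1000)$contour_length, 383)
  expect_error(wlc_params(contour_length = -1), class = "rmquant_parameter_error")
  expect_error(wlc_params(contour_length = 100, n_segments = 1),
               class = "rmquant_parameter_error")
})

test_that("rendered particle volume matches the closed form exactly", {
  rp <- afm_render_params(image_size = 256, background_sd = 0)
  p <- particle_spec(position = c(128, 128), volume = 200, footprint_sigma = 5)
  hm <- render_afm_scene(list(), list(p), rp)
  # noise-free scene: total rendered volume equals the analytic 2 pi sigma^2 h0
  expect_equal(sum(hm$heights) * hm$rx * hm$ry, 200, tolerance = 1e-3)
  expect_equal(nrow(attr(hm, "particle_centers")), 1)
})

test_that("render_afm_scene rejects out-of-bounds geometry", {
  rp <- afm_render_params(image_size = 128, background_sd = 0)
  expect_error(
    render_afm_scene(list(tibble::tibble(x = c(1, 60), y = c(60, 60))), list(), rp),
    class = "rmquant_render_error"
  )
  expect_error(
    render_afm_scene(list(), list(particle_spec(c(5, 64), volume = 10)), rp),
    class = "rmquant_render_error"
  )
  expect_error(
    render_afm_scene(list(), list(particle_spec(0.5, volume = 10, chain = 1)), rp),
    class = "rmquant_render_error"  # fraction position with no chain
  )
})

test_that("afm rendering noise is seed-deterministic", {
  rp1 <- afm_render_params(image_size = 64, background_sd = 0.05, seed = 5)
  h1 <- render_afm_scene(list(), list(), rp1)
  h2 <- render_afm_scene(list(), list(), rp1)
  expect_identical(h1$heights, h2$heights)
})

test_that("condensate scenes have the requested geometry and intensities", {
  cp <- condensate_scene_params(core_radius = 900, halo_thickness = 600,
                                noise_sd = 0)
  img <- render_condensate_scene(cp)
  expect_s3_class(img, "rm_image")
  expect_identical(img$channels, c("protein", "dna"))
  m <- image_channel(img, "protein")
  expect_setequal(unique(as.vector(m)), c(10, 50, 150))
  # areas match the discs at pixel resolution
  a_core <- sum(m == 150) * 100^2
  expect_equal(sqrt(a_core / pi), 900, tolerance = 0.02)
  expect_error(
    render_condensate_scene(condensate_scene_params(core_radius = 940,
                                                    image_size = 10)),
    class = "rmquant_render_error"
  )
})

test_that("noise-free titrations follow the Hill curve exactly", {
  ip <- isotherm_params(c50_true = 90, hill_n = 2, noise_sd = 0,
                        n_replicates = 2)
  tab <- simulate_titration(ip)
  cc <- tab$concentration_nM
  expect_equal(tab$fraction_bound,
               ifelse(cc == 0, 0, cc^2 / (cc^2 + 90^2)))
  expect_equal(dplyr::n_distinct(tab$replicate), 2)
})

test_that("noisy titrations are clamped to [0, 1] and seed-stable", {
  ip <- isotherm_params(noise_sd = 0.4, seed = 2, n_replicates = 3)
  t1 <- simulate_titration(ip)
  t2 <- simulate_titration(ip)
  expect_identical(t1$fraction_bound, t2$fraction_bound)
  expect_true(all(t1$fraction_bound >= 0 & t1$fraction_bound <= 1))
})

test_that("decay series match the closed form without noise", {
  dp <- decay_sim_params(k_true = 0.05, i0 = 40, background = 3,
                         frame_interval = 1.5, n_frames = 20,
                         noise_model = "none")
  ser <- simulate_decay(dp)
  expect_equal(ser$counts, 3 + 40 * exp(-0.05 * ser$t))
  expect_equal(ser$t, (0:19) * 1.5)
  expect_equal(ser$frame, 0:19)
})

test_that("poisson decay noise is seed-deterministic", {
  dp <- decay_sim_params(seed = 7)
  expect_identical(simulate_decay(dp)$counts, simulate_decay(dp)$counts)
  mv <- simulate_decay_movie(dp, frame_size = 8)
  expect_s3_class(mv, "scan_series")
  expect_equal(dim(mv$frames), c(8, 8, 60))
  expect_equal(mv$frame_interval, 2)
})
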