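test_that("core radius is recovered within one pixel on a noise-free scene", {
  cp <- condensate_scene_params(core_radius = 940, halo_thickness = 657,
                                noise_sd = 0)
  img <- render_condensate_scene(cp)
  masks <- segment_condensate(img)
  expect_lt(abs(core_radius(masks) - 940), 100)
})

test_that("36-ray halo thickness is recovered within one pixel", {
  cp <- condensate_scene_params(core_radius = 940, halo_thickness = 657,
                                noise_sd = 0)
  img <- render_condensate_scene(cp)
  morph <- condensate_morphology(img)
  expect_lt(abs(morph$halo_mean_nm - 657), 100)
  expect_equal(nrow(morph$rays), 36)
  expect_equal(sum(morph$rays$excluded), 0)
  # per-ray thickness of a perfect annulus is nearly isotropic
  expect_lt(stats::sd(morph$rays$thickness_nm), 100)
})

test_that("36 rays converge to the dense-ray oracle", {
  cp <- condensate_scene_params(seed = 3)  # default noisy scene
  img <- render_condensate_scene(cp)
  m36 <- condensate_morphology(img, ray_count = 36)
  m720 <- condensate_morphology(img, ray_count = 720)
  expect_lt(abs(m36$halo_mean_nm - m720$halo_mean_nm), 10)
})

test_that("halo measurement errors out when rays cannot leave the condensate", {
  # condensate filling the whole field: every ray exits the image while
  # still inside the whole mask
  m <- matrix(100, 30, 30)
  m[14:16, 14:16] <- 200
  masks <- segment_condensate(m, whole_threshold = 50, core_threshold = 150,
                              pixel_size = 100)
  expect_error(halo_thickness(masks), class = "rmquant_morphometry_error")
})

test_that("segment_condensate needs a pixel size with bare matrices", {
  expect_error(segment_condensate(matrix(stats::rnorm(100), 10, 10)),
               class = "rmquant_parameter_error")
  expect_error(segment_condensate(matrix(1, 10, 10), pixel_size = 100),
               class = "rmquant_empty_field_error")
})

test_that("detect_foci counts discs and integrates their intensity", {
  centers <- rbind(c(5000, 5000), c(15000, 15000), c(20000, 6000))
  img <- render_foci_scene(centers, radii = c(800, 600, 700),
                           intensities = c(40, 60, 50),
                           background_mean = 10, background_sd = 1, seed = 6)
  fq <- detect_foci(img, channel = "dna")
  expect_equal(fq$n_foci, 3)
  # integrated intensity of each focus ~ area x intensity above background
  ord <- order(fq$foci$centroid_col)  # x = 5000, 15000, 20000 nm
  truth <- pi * c(800, 600, 700)^2 / 100^2 * c(40, 60, 50)
  expect_equal(fq$foci$integrated_intensity[ord], truth, tolerance = 0.1)
})

test_that("detect_foci accepts explicit background parameters", {
  m <- matrix(10, 50, 50)
  m[20:24, 20:24] <- 30
  fq <- detect_foci(m, background = c(10, 2))
  expect_equal(fq$threshold, 14)
  expect_equal(fq$n_foci, 1)
  expect_equal(fq$foci$area_px, 25L)
  expect_equal(fq$foci$integrated_intensity, 25 * 20)
  expect_error(detect_foci(matrix(5, 10, 10), background = c(5, 0)),
               class = "rmquant_threshold_error")
})

test_that("summarize_foci averages across images", {
  m1 <- matrix(10, 40, 40); m1[5:9, 5:9] <- 40
  m2 <- matrix(10, 40, 40); m2[5:9, 5:9] <- 40; m2[25:29, 25:29] <- 40
  q1 <- detect_foci(m1, background = c(10, 2))
  q2 <- detect_foci(m2, background = c(10, 2))
  s <- summarize_foci(list(q1, q2))
  expect_equal(s$n_images, 2)
  expect_equal(s$mean_n_foci, 1.5)
  expect_equal(s$mean_total_intensity, mean(c(750, 1500)))
  expect_error(summarize_foci(list()), class = "rmquant_parameter_error")
})
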