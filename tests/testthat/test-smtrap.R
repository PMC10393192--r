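make_movie <- function(k = 0.05, i0 = 30, background = 2, seed = 1,
                       noise = "none") {
  dp <- decay_sim_params(k_true = k, i0 = i0, background = background,
                         n_frames = 40, noise_model = noise, seed = seed)
  simulate_decay_movie(dp, frame_size = 16)
}

test_that("roi_trace normalises to the first frame", {
  mv <- make_movie()
  tr <- roi_trace(mv, c(3, 10, 3, 10))
  expect_equal(tr$normalized[1], 1)
  expect_equal(tr$frame, 0:39)
  expect_equal(tr$t, mv$t)
  expect_equal(tr$normalized, tr$mean_counts / tr$mean_counts[1])
})

test_that("normalization is invariant to intensity rescaling", {
  mv <- make_movie(noise = "poisson", seed = 9)
  mv_scaled <- mv
  mv_scaled$frames <- mv$frames * 7.3
  t1 <- roi_trace(mv, c(1, 16, 1, 16))
  t2 <- roi_trace(mv_scaled, c(1, 16, 1, 16))
  expect_equal(t1$normalized, t2$normalized, tolerance = 1e-12)
})

test_that("roi_trace validates the ROI and the first frame", {
  mv <- make_movie()
  expect_error(roi_trace(mv, c(0, 5, 1, 5)), class = "rmquant_parameter_error")
  expect_error(roi_trace(mv, c(5, 2, 1, 5)), class = "rmquant_parameter_error")
  zero <- scan_series(array(0, dim = c(4, 4, 6)), frame_interval = 1)
  expect_error(roi_trace(zero, c(1, 4, 1, 4)),
               class = "rmquant_normalization_error")
})

test_that("fit_dissociation recovers k exactly on noise-free data", {
  mv <- make_movie(k = 0.034, i0 = 50, background = 2)
  tr <- roi_trace(mv, c(1, 16, 1, 16))
  fit <- fit_dissociation(tr)
  expect_equal(fit$k, 0.034, tolerance = 1e-6)
  expect_equal(fit$i0, 50, tolerance = 1e-4)
  expect_equal(fit$baseline, 2, tolerance = 1e-4)
  expect_false(fit$flat)
  expect_true(fit$k_ci[1] <= fit$k && fit$k <= fit$k_ci[2])
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "k"], fit$k)
  expect_equal(glance(fit)$k, fit$k)
})

test_that("fit_dissociation handles flat and short series", {
  flat <- tibble::tibble(t = 0:9, mean_counts = rep(5, 10))
  f <- fit_dissociation(flat)
  expect_true(f$flat)
  expect_equal(f$k, 0)
  expect_error(fit_dissociation(tibble::tibble(t = 0:2, mean_counts = 3:1)),
               class = "rmquant_fit_error")
  expect_error(fit_dissociation(tibble::tibble(a = 1:6)),
               class = "rmquant_parameter_error")
})

test_that("waiting_time finds the first super-threshold frame", {
  y <- c(rep(2, 10), rep(30, 10)) + rep(c(0.1, -0.1), 10)
  tr <- tibble::tibble(t = (0:19) * 2, mean_counts = y)
  wt <- waiting_time(tr, n_pre = 5, k = 5)
  expect_equal(wt$frame, 10L)
  expect_equal(wt$waiting_time_s, 20)
  expect_error(waiting_time(tibble::tibble(t = 0:3, mean_counts = rep(1, 4)),
                            n_pre = 5),
               class = "rmquant_parameter_error")
  never <- tibble::tibble(t = 0:19, mean_counts = rep(c(1, 1.01), 10))
  expect_error(waiting_time(never), class = "rmquant_no_binding_error")
})

test_that("focal_growth_profile separates flat from growing traces", {
  tt <- 0:10
  traces <- dplyr::bind_rows(
    tibble::tibble(trace_id = 1, group = "taut", t = tt,
                   normalized = rep(1, 11)),
    tibble::tibble(trace_id = 2, group = "taut", t = tt,
                   normalized = 1 + 0.01 * tt),
    tibble::tibble(trace_id = 3, group = "dangling", t = tt,
                   normalized = 1 + 0.3 * tt)
  )
  gp <- focal_growth_profile(traces)
  expect_equal(gp$ratios$class[gp$ratios$trace_id == 3], "growing")
  expect_true(all(gp$ratios$class[gp$ratios$group == "taut"] == "flat"))
  prof <- gp$profile[gp$profile$group == "taut" & gp$profile$t == 10, ]
  expect_equal(prof$mean_normalized, mean(c(1, 1.1)))
  expect_equal(prof$n, 2L)
  expect_error(focal_growth_profile(tibble::tibble(a = 1)),
               class = "rmquant_parameter_error")
})
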