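test_that("fraction_bound is depletion-based, clamped, and validated", {
  expect_equal(fraction_bound(30, 100), 0.7)
  expect_equal(fraction_bound(c(100, 0), c(100, 50)), c(0, 1))
  expect_error(fraction_bound(10, 0), class = "rmquant_parameter_error")
  expect_error(fraction_bound(60, 50), class = "rmquant_parameter_error")
})

test_that("c50 equals the analytic inverse on noise-free monotone curves", {
  # off-grid half-saturation, fine grid: interpolation within half a step
  for (hn in c(1, 2)) {
    ip <- isotherm_params(c50_true = 77, hill_n = hn,
                          concentrations = seq(10, 500, by = 2),
                          noise_sd = 0, n_replicates = 1)
    res <- c50(simulate_titration(ip))
    expect_lt(abs(res$c50 - 77), 1)  # half the 2 nM grid spacing
  }
})

test_that("c50 takes the first upward crossing and exact hits", {
  tab <- tibble::tibble(concentration_nM = c(10, 20, 40, 80),
                        fraction_bound = c(0.1, 0.5, 0.4, 0.9))
  expect_equal(c50(tab)$c50, 20)  # exact 0.5 hit
  tab2 <- tibble::tibble(concentration_nM = c(10, 20, 40),
                         fraction_bound = c(0.2, 0.4, 0.8))
  # linear interpolation between 20 and 40: 0.5 at 25
  expect_equal(c50(tab2)$c50, 25)
})

test_that("presaturated and unsaturated titrations raise classed errors", {
  pre <- tibble::tibble(concentration_nM = c(10, 20),
                        fraction_bound = c(0.8, 0.9))
  expect_error(c50(pre), class = "rmquant_presaturated_error")
  un <- tibble::tibble(concentration_nM = c(10, 20, 40),
                       fraction_bound = c(0.1, 0.2, 0.3))
  expect_error(c50(un), class = "rmquant_unsaturated_error")
})

test_that("replicate aggregation follows the n = 1 / 2 / >= 3 conventions", {
  one <- aggregate_replicates(85)
  expect_equal(one$rule, "single experiment")
  expect_true(is.na(one$dispersion))

  two <- aggregate_replicates(c(80, 100))
  expect_equal(two$mean, 90)
  expect_equal(two$dispersion, 10)   # half of max - min
  expect_equal(two$rule, "range")

  three <- aggregate_replicates(c(80, 90, 100))
  expect_equal(three$mean, 90)
  expect_equal(three$dispersion, stats::sd(c(80, 90, 100)))
  expect_equal(three$rule, "sd")
})

test_that("c50 aggregates replicates and exposes tidy/glance", {
  ip <- isotherm_params(c50_true = 90, noise_sd = 0.03, n_replicates = 3,
                        seed = 12,
                        concentrations = c(0, 12.5, 25, 50, 100, 200, 400, 800))
  res <- c50(simulate_titration(ip))
  expect_equal(res$n_replicates, 3)
  expect_equal(res$dispersion_rule, "sd")
  expect_equal(nrow(tidy(res)), 3)
  g <- glance(res)
  expect_equal(g$c50_nM, res$c50)
  # mean of replicate c50s stays near truth under mild noise
  expect_lt(abs(res$c50 - 90) / 90, 0.35)
})

test_that("c50 accepts raw band intensities", {
  tab <- tibble::tibble(concentration_nM = c(10, 50, 250),
                        free_intensity = c(95, 60, 5),
                        total_intensity = c(100, 100, 100))
  res <- c50(tab)
  expect_equal(res$dispersion_rule, "single experiment")
  expect_true(res$c50 > 10 && res$c50 < 250)
  expect_error(c50(tibble::tibble(concentration_nM = 1)),
               class = "rmquant_parameter_error")
  expect_error(c50(tibble::tibble(x = 1)), class = "rmquant_parameter_error")
})
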