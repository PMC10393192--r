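test_that("with_seed is reproducible and restores the session RNG", {
  a <- rmquant:::with_seed(11, stats::rnorm(5))
  b <- rmquant:::with_seed(11, stats::rnorm(5))
  expect_identical(a, b)

  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(rmquant:::with_seed(1, stats::rnorm(10)))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("child_seed stays below 2^31 and separates streams", {
  s <- rmquant:::child_seed(2147483646, 1e6)
  expect_lt(s, 2^31)
  expect_gte(s, 0)
  expect_false(rmquant:::child_seed(1, 1) == rmquant:::child_seed(1, 2))
  expect_null(rmquant:::child_seed(NULL, 5))
})

test_that("bwlabel8 keeps diagonal runs connected", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:5, 1:5)] <- TRUE       # pure diagonal: one 8-connected component
  lab <- rmquant:::bwlabel8(m)
  expect_equal(max(lab), 1)

  m2 <- matrix(FALSE, 6, 6)
  m2[cbind(1:3, 1:3)] <- TRUE
  m2[6, 6] <- TRUE                 # separated pixel: second component
  expect_equal(max(rmquant:::bwlabel8(m2)), 2)
})

test_that("parameter checks reject bad input with classed errors", {
  expect_error(height_map(matrix(1, 2, 2), rx = 0), class = "rmquant_error")
  expect_error(height_map("x"), class = "rmquant_parameter_error")
  expect_error(height_map(matrix(c(1, NA, 1, 1), 2, 2)),
               class = "rmquant_parameter_error")
})
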