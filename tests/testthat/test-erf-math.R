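# Analytic ERF ratios, side-kernel rule, binomial path weights, and the
# gradient-probe measurement against a brute-force footprint oracle.

test_that("positive-attention ERF ratio matches the closed form", {
  expect_equal(erf_ratio_pasb(K = 3, K_side = 9, n = 1), 3 * sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(erf_ratio_pasb(3, 9, 1), 2.449, tolerance = 1e-3)
  # identical kernels with vanishing depth correction approach 1
  expect_equal(erf_ratio_pasb(3, 3, 1e6), 1, tolerance = 1e-6)
  # strictly increasing in n for fixed kernels
  vals <- vapply(1:20, function(n) erf_ratio_pasb(3, 9, n), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(erf_ratio_pasb(4, 9, 1), class = "mm_invalid_argument")
  expect_error(erf_ratio_pasb(3, 9, 0), class = "mm_invalid_argument")
})

test_that("minimal side kernel implements the sqrt(2) bound with odd rounding", {
  # doubled design choice: K = 3 gives 9
  expect_identical(minimal_side_kernel(3, doubling = TRUE), 9L)
  # smallest odd integer strictly above sqrt(2) * K
  expect_identical(minimal_side_kernel(1, doubling = FALSE), 3L)
  expect_identical(minimal_side_kernel(3, doubling = FALSE), 5L)
  expect_identical(minimal_side_kernel(5, doubling = FALSE), 9L)
  expect_error(minimal_side_kernel(2), class = "mm_invalid_argument")
  expect_error(minimal_side_kernel(-3), class = "mm_invalid_argument")
})

test_that("binomial path weights are correct and normalised", {
  expect_equal(binomial_path_weight(2, 1, 0.5), 0.5)
  expect_equal(binomial_path_weight(2, 0, 0.5), 0.25)
  expect_equal(binomial_path_weight(2, 2, 0.5), 0.25)
  for (N in 1:6) {
    for (p in seq(0.1, 0.9, by = 0.2)) {
      w <- vapply(0:N, function(k) binomial_path_weight(N, k, p), numeric(1))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  }
  expect_error(binomial_path_weight(2, 3, 0.5), class = "mm_invalid_argument")
  expect_error(binomial_path_weight(2, -1, 0.5),
               class = "mm_invalid_argument")
})

test_that("negative-attention ERF ratio is below 1 and tends to 1", {
  expect_equal(erf_ratio_nasb(1, 0.5),
               0.25 * sqrt(1 / 3) + 0.5 * sqrt(2 / 3) + 0.25,
               tolerance = 1e-12)
  expect_equal(erf_ratio_nasb(1), 0.8026, tolerance = 1e-4)
  vals <- vapply(c(1:20, 100, 1000), erf_ratio_nasb, numeric(1))
  expect_true(all(vals < 1))
  expect_true(all(diff(vals) > 0))
  expect_equal(erf_ratio_nasb(1e7), 1, tolerance = 1e-6)
  expect_error(erf_ratio_nasb(0), class = "mm_invalid_argument")
})

test_that("PASB ratio exceeds 1 whenever the side kernel is admissible", {
  for (K in c(1L, 3L, 5L)) {
    Ks <- minimal_side_kernel(K, doubling = FALSE)
    for (n in c(1L, 2L, 5L, 20L)) {
      expect_gt(erf_ratio_pasb(K, Ks, n), 1)
    }
  }
})

test_that("gradient probe reproduces known receptive-field footprints", {
  # single 3x3 conv, uniform weights: support is exactly the 3x3 window
  s1 <- conv_stack(kernels = 3, weights = "uniform")
  prof1 <- measure_empirical_erf(s1, c(9L, 9L))
  expect_identical(prof1$support_area, 9L)
  expect_identical(prof1$center, c(5L, 5L))
  # two stacked 3x3 convs: 5x5
  s2 <- conv_stack(kernels = c(3, 3), weights = "uniform")
  prof2 <- measure_empirical_erf(s2, c(11L, 11L))
  expect_identical(prof2$support_area, 25L)
  # single 3x3 conv with dilation 5: 9 taps spanning an 11x11 extent
  s3 <- conv_stack(kernels = 3, dilations = 5, weights = "uniform")
  prof3 <- measure_empirical_erf(s3, c(15L, 15L))
  expect_identical(prof3$support_area, 9L)
  nz <- which(prof3$gradient_map > 0, arr.ind = TRUE)
  expect_identical(as.integer(diff(range(nz[, 1]))) + 1L, 11L)
  expect_identical(as.integer(diff(range(nz[, 2]))) + 1L, 11L)
})

test_that("gradient probe agrees with the brute-force footprint oracle", {
  cases <- list(list(kernels = 3, dilations = 1),
                list(kernels = c(3, 3), dilations = 1),
                list(kernels = c(3, 5, 3), dilations = 1),
                list(kernels = c(3, 3), dilations = c(2, 1)))
  for (cs in cases) {
    st <- conv_stack(kernels = cs$kernels, dilations = cs$dilations,
                     weights = "uniform")
    shape <- c(17L, 17L)
    prof <- measure_empirical_erf(st, shape, probe_threshold = 1e-9)
    oracle <- brute_force_footprint(st, shape)
    expect_identical(prof$gradient_map > 0, oracle)
  }
})

test_that("erf profile exports as CSV with a summary line", {
  prof <- measure_empirical_erf(conv_stack(3, weights = "uniform"), c(7L, 7L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_erf_profile(prof, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# support_area=9")
  df <- utils::read.csv(path, comment.char = "#")
  expect_named(df, c("row", "col", "gradient"))
  expect_equal(nrow(df), 49)
  expect_equal(sum(df$gradient > 0), 9)
})

test_that("probing odd shapes is required and dead networks are flagged", {
  expect_error(measure_empirical_erf(conv_stack(3), c(8L, 8L)),
               class = "mm_invalid_argument")
  # a zero-weight network has an all-zero gradient map
  st <- conv_stack(3, weights = "uniform")
  st$layers[[1]]$W[] <- 0
  expect_error(measure_empirical_erf(st, c(7L, 7L)),
               class = "mm_numerical_failure")
})
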