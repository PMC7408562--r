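test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(1:5, rep(1, 5)), "spectrum")
  expect_error(spectrum(c(1, 2, 2, 3), 1:4), class = "spectrobind_invalid_input")
  expect_error(spectrum(c(300, 299), 1:2), "row 2")
  expect_error(spectrum(1:3, 1:2), class = "spectrobind_invalid_input")
  expect_error(spectrum(1:3, c(-1, 0, 1), kind = "extinction"),
               class = "spectrobind_invalid_input")
  expect_error(spectrum(1, 1), class = "spectrobind_invalid_input")
})

test_that("inner filter correction follows the multiplicative law", {
  expect_equal(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 1.0, 1.0), 1000)
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 125.8925, tolerance = 1e-6)
  # element-wise over a spectrum with wavelength-dependent A_em
  s <- spectrum(c(300, 310, 320), c(10, 20, 30), kind = "emission")
  cor <- inner_filter_correct(s, a_ex = 0.2, a_em = c(0, 0.2, 0.4))
  expect_equal(cor$value, c(10, 20, 30) * 10^((0.2 + c(0, 0.2, 0.4)) / 2))
  expect_error(inner_filter_correct(100, NA, 0), class = "spectrobind_invalid_input")
  expect_error(inner_filter_correct(-1, 0, 0), class = "spectrobind_invalid_input")
})

test_that("inner filter correction is monotone in absorbance", {
  a <- seq(0, 1, by = 0.1)
  out <- vapply(a, function(x) inner_filter_correct(50, x, 0.3), numeric(1))
  expect_true(all(diff(out) > 0))
  expect_true(all(out >= 50))
})

test_that("band_area integrates by trapezoid with interpolated endpoints", {
  flat <- spectrum(seq(290, 400, by = 1), rep(1, 111), kind = "emission")
  expect_equal(band_area(flat, 290, 400), 110)
  # limits between grid points are honoured by interpolation
  expect_equal(band_area(flat, 290.25, 399.75), 109.5)
  # Gaussian band vs analytic area, 0.5 nm grid
  g <- gaussian_spectrum(334, 8, amp = 2, from = 280, to = 390, by = 0.5)
  analytic <- 2 * 8 * sqrt(2 * pi)
  expect_rel_equal(band_area(g, 280, 390), analytic, 1e-3)
  expect_error(band_area(flat, 500, 600), class = "spectrobind_range_error")
  expect_error(band_area(flat, 400, 290), class = "spectrobind_invalid_input")
})

test_that("band_area is additive over contiguous subintervals", {
  g <- gaussian_spectrum(334, 20, from = 290, to = 400, by = 1)
  whole <- band_area(g, 290, 400)
  parts <- band_area(g, 290, 317.3) + band_area(g, 317.3, 362.8) +
    band_area(g, 362.8, 400)
  expect_equal(parts, whole, tolerance = 1e-9)
})

test_that("second derivative reproduces polynomials exactly on interior points", {
  g <- seq(300, 350, by = 1)
  quad <- spectrum(g, g^2)
  d2 <- second_derivative(quad, window = 7)
  expect_equal(d2$value, rep(2, length(g)), tolerance = 1e-8)
  lin <- spectrum(g, 3 * g + 7)
  expect_equal(second_derivative(lin, 7)$value, rep(0, length(g)),
               tolerance = 1e-8)
})

test_that("second derivative matches the analytic derivative of a sine", {
  g <- seq(300, 360, by = 0.2)
  s <- spectrum(g, sin(g / 10))
  d2 <- second_derivative(s, window = 7)
  interior <- 10:(length(g) - 10)
  expect_lt(max(abs(d2$value[interior] - (-sin(g / 10) / 100)[interior])),
            0.01 * max(abs(sin(g / 10) / 100)))
})

test_that("second derivative agrees with a uniform-grid Savitzky-Golay filter", {
  skip_if_not_installed("signal")
  g <- seq(300, 360, by = 0.5)
  y <- exp(-(g - 330)^2 / 50) + 0.1 * sin(g / 3)
  ours <- second_derivative(spectrum(g, y), window = 9)$value
  ref <- signal::sgolayfilt(y, p = 2, n = 9, m = 2) / 0.5^2
  interior <- 6:(length(g) - 5)
  expect_equal(ours[interior], ref[interior], tolerance = 1e-6)
})

test_that("second derivative rejects bad windows", {
  s <- spectrum(1:20, rnorm(20))
  expect_error(second_derivative(s, 6), class = "spectrobind_invalid_parameter")
  expect_error(second_derivative(s, 3), class = "spectrobind_invalid_parameter")
  expect_error(second_derivative(s, 21), class = "spectrobind_invalid_parameter")
})

test_that("resample interpolates linearly and refuses extrapolation", {
  g <- seq(300, 400, by = 2)
  s <- spectrum(g, 0.5 * g - 20)
  same <- resample(s, g)
  expect_equal(same$value, s$value)
  fine <- resample(s, seq(301, 399, by = 0.7))
  expect_equal(fine$value, 0.5 * fine$wavelength_nm - 20)
  expect_error(resample(s, seq(250, 350, 10)), class = "spectrobind_range_error")
})

test_that("spectrum files round-trip bit-identically through decimal text", {
  s <- spectrum(seq(290, 310, by = 0.5), runif(41), kind = "emission")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path, comments = c("source: test"))
  r1 <- read_spectrum(path, kind = "emission")
  write_spectrum(r1, path)
  r2 <- read_spectrum(path, kind = "emission")
  expect_identical(r1$wavelength_nm, r2$wavelength_nm)
  expect_identical(r1$value, r2$value)
  expect_equal(r1$value, s$value, tolerance = 1e-9)
})

test_that("readers reject non-monotonic wavelength columns with a row diagnostic", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,absorbance", "300,0.1", "302,0.2", "301,0.3"), path)
  expect_error(read_spectrum(path), "row 3")
})
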