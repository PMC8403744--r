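geom <- display_geometry()

test_that("anticorrelated wavelength follows 2*lambda/F and rejects bad input", {
  expect_equal(anticorrelated_wavelength(5, 2.5), 4)
  expect_equal(anticorrelated_wavelength(6.25, 1.5), 2 * 6.25 / 1.5)
  expect_equal(round(anticorrelated_wavelength(6.25, 1.5), 1), 8.3)
  expect_equal(anticorrelated_wavelength(5.7, 2, strict = FALSE), 5.7)
  expect_error(anticorrelated_wavelength(-1, 1.5), "positive")
  expect_error(anticorrelated_wavelength(5, 3), "f_anti")
})

test_that("contrast split conserves mean and difference and round-trips", {
  expect_equal(unname(split_contrast(0.15, -0.28)), c(0.29, 0.01))
  expect_equal(unname(split_contrast(0.15, 0)), c(0.15, 0.15))
  expect_equal(unname(split_contrast(0.15, -0.30)), c(0.30, 0.00))
  for (dc in seq(-0.28, 0.28, by = 0.04)) {
    cc <- split_contrast(0.15, dc)
    expect_equal(unname(cc["c_anti"] - cc["c_corr"]), dc)
    expect_equal(unname(mean(cc)), 0.15)
  }
  expect_error(split_contrast(0.15, 0.9), "outside")
})

test_that("grating profile has the closed-form luminances and is periodic", {
  spec <- grating_spec(5, phase_rad = 0, contrast = 0.5)
  # peak of the sinusoid: grey * (1 + c)
  x_peak <- 5 / 4  # quarter wavelength, sin = 1
  expect_equal(grating_profile(spec, x_peak, geom), 58.33 * 1.5)
  # zero contrast -> uniform grey
  flat <- grating_spec(5, contrast = 0)
  x <- seq(-10, 10, by = 0.1)
  expect_true(all(grating_profile(flat, x, geom) == geom$luminance_grey))
  # periodicity
  expect_equal(grating_profile(spec, x, geom), grating_profile(spec, x + 5, geom))
  # square wave takes only the two extreme values
  sq <- grating_spec(5, contrast = 0.5, waveform = "square")
  lv <- sort(unique(round(grating_profile(sq, x, geom), 9)))
  expect_equal(lv, round(58.33 * c(0.5, 1.5), 9))
})

test_that("rendered luminances never leave the displayable range", {
  spec <- grating_spec(5, contrast = 1)
  L <- grating_profile(spec, seq(-20, 20, by = 0.05), geom)
  expect_true(all(L >= geom$luminance_black & L <= geom$luminance_white))
})

test_that("generalized-Gaussian window attenuates as the closed form", {
  w <- window_spec(scale_deg = 2.1, shape = 3, center = 0, inverted = TRUE)
  # at the centre: full attenuation to grey
  prof <- rep(100, 3)
  out <- apply_window(prof, c(0, 2.1, 50), w, geom)
  expect_equal(out[1], geom$luminance_grey)
  # at one scale unit: 1 - exp(-1) of the contrast retained
  expect_equal(out[2], geom$luminance_grey + (100 - geom$luminance_grey) * (1 - exp(-1)))
  # far away (>= 5 alpha): attenuation below 1%
  expect_lt(abs(out[3] - 100), 0.01 * (100 - geom$luminance_grey))
  # non-inverted slice window passes the centre untouched
  ws <- window_spec(2.1, 5, center = 0, inverted = FALSE)
  expect_equal(apply_window(100, 0, ws, geom), 100)
})

test_that("gaze displacement of 2*lambda gives correlated 0 / anticorrelated pi", {
  for (lambda in seq(5, 6.25, by = 0.0625)) {
    expect_equal(retinal_phase_shift(2 * lambda, lambda), 0, tolerance = 1e-8)
    for (f in c(1.5, 2.5)) {
      la <- anticorrelated_wavelength(lambda, f)
      expect_equal(retinal_phase_shift(2 * lambda, la), pi, tolerance = 1e-8)
    }
  }
})

test_that("wavelength and frequency ranges of the sampled design", {
  la <- c(anticorrelated_wavelength(5, 2.5), anticorrelated_wavelength(6.25, 1.5))
  expect_equal(la, c(4, 25 / 3))
  sf <- sort(1 / la)
  expect_equal(sf, c(0.12, 0.25))
  # correlated-grating spatial frequencies span 0.16-0.2 cyc/deg
  expect_equal(1 / c(6.25, 5), c(0.16, 0.2))
})

test_that("deg/px conversion is invertible", {
  d <- seq(-20, 20, by = 0.5)
  expect_equal(px_to_deg(deg_to_px(d, geom), geom), d)
})

test_that("noise mask is seed-deterministic with the stated spectrum", {
  m1 <- make_noise_mask(seed = 11)
  m2 <- make_noise_mask(seed = 11)
  expect_identical(m1, m2)
  m3 <- make_noise_mask(seed = 12)
  expect_false(identical(m1$luminance, m3$luminance))
  # spectral centroid within the stated 0.18 +/- 0.02 cyc/deg band
  cents <- vapply(1:20, function(s) make_noise_mask(seed = s)$spectral_centroid,
                  numeric(1))
  expect_true(all(abs(cents - 0.18) <= 0.02))
  # zero contrast -> uniform grey
  m0 <- make_noise_mask(contrast = 0, seed = 1)
  expect_true(all(m0$luminance == geom$luminance_grey))
  # luminances stay within the display range
  expect_true(all(m1$luminance >= geom$luminance_black &
                    m1$luminance <= geom$luminance_white))
})

test_that("rendering is resolution-independent up to interpolation error", {
  up <- grating_spec(5.5, phase_rad = 0.3, contrast = 0.5, half = "upper")
  lo <- grating_spec(4.4, phase_rad = 0.3, contrast = 0.5, half = "lower")
  f1 <- render_frame(up, lo, geom, n_x = 240, n_y = 135)
  f2 <- render_frame(up, lo, geom, n_x = 479, n_y = 269)
  # odd 2k-1 grid shares every sample position of the k grid
  shared_x <- seq(1, 479, by = 2)
  shared_y <- seq(1, 269, by = 2)
  expect_equal(f2$luminance[shared_y, shared_x], f1$luminance,
               tolerance = 1e-10)
  # the grey bar centre renders as pure grey at any resolution
  mid <- which.min(abs(f2$y_deg))
  expect_equal(max(abs(f2$luminance[mid, ] - geom$luminance_grey)), 0,
               tolerance = 0.5)
})
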