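bands <- default_bands()

test_that("band quantifiers behave on canonical single-line spectra", {
  nu <- seq(600, 1800, by = 1)
  A <- 500
  s <- spectrum(nu, lorentz(nu, 1125, 6, A))
  ph <- band_def("1125", 1125, quantifier = "peak-height")
  expect_equal(band_intensity(s, ph), A, tolerance = 1e-6)
  ## flat zero spectrum -> 0 in both modes
  z <- spectrum(nu, rep(0, length(nu)))
  expect_equal(band_intensity(z, bands[["750"]]), 0)
  expect_equal(band_intensity(z, ph), 0)
  ## a line 20 cm^-1 outside a +-8 window contributes < 15% of A
  off <- spectrum(nu, lorentz(nu, 1125 + 28, 6, A))
  expect_lt(band_intensity(off, ph), 0.15 * A)
  ## closed-form tail bound: max of the Lorentzian inside the window is at
  ## the near edge, 20 cm^-1 from the center
  expect_equal(band_intensity(off, ph), lorentz(1125 + 8, 1125 + 28, 6, A),
               tolerance = 1e-6)
  ## window outside the axis errors
  expect_error(band_intensity(s, band_def("x", 1799)), class = "rr_band_error")
})

test_that("band-mean and peak-height agree within 5% for narrow lines on a fine axis", {
  nu <- seq(1000, 1300, by = 0.2)
  set.seed(5)
  for (i in 1:20) {
    center <- 1150 + runif(1, -3, 3)
    A <- runif(1, 10, 1000)
    s <- spectrum(nu, lorentz(nu, center, 30, A))  # broad line, narrow window
    bm <- band_intensity(s, band_def("b", 1150, half_width = 4))
    ph <- band_intensity(s, band_def("b", 1150, half_width = 4,
                                     quantifier = "peak-height"))
    expect_lt(abs(bm - ph) / ph, 0.05)
  }
})

test_that("band maps respect masks and uniform maps give constant values", {
  nu <- seq(700, 820, by = 2)
  cube <- array(rep(lorentz(nu, 750, 6, 10), each = 6), c(2, 3, length(nu)))
  m <- hyperspec_map(nu, cube)
  bm <- band_map(m, bands[["750"]])
  expect_equal(max(bm$values) - min(bm$values), 0, tolerance = 1e-12)
  mask <- matrix(FALSE, 2, 3)
  expect_true(all(is.na(band_map(m, bands[["750"]], mask)$values)))
})

test_that("ratio maps flag invalid pixels and are scale invariant", {
  ph <- make_cell_phantom(phantom_spec("rod", height = 8, width = 12), seed = 4)
  bl <- subtract_baseline_map(ph$map)
  rm0 <- ratio_map(bl$corrected, bands[["750"]], bands[["1640"]])
  for (f in c(0.1, 10)) {
    scaled <- hyperspec_map(bl$corrected$axis, bl$corrected$cube * f)
    rmf <- ratio_map(scaled, bands[["750"]], bands[["1640"]])
    expect_equal(rmf$values, rm0$values, tolerance = 1e-12)
  }
  ## identical bands -> ratio 1 with a warning
  expect_warning(r1 <- ratio_map(bl$corrected, bands[["750"]], bands[["750"]]),
                 "identical")
  expect_true(all(abs(r1$values[r1$valid] - 1) < 1e-12))
  ## non-positive denominator -> invalid, excluded
  nu <- seq(700, 1700, by = 5)
  y <- lorentz(nu, 750, 6, 10)
  y[nu > 1600] <- 0                    # dead 1640 window
  m <- hyperspec_map(nu, array(y, c(1, 1, length(nu))))
  rm <- ratio_map(m, band_def("750", 750), band_def("1640", 1640))
  expect_false(any(rm$valid))
  expect_true(all(is.na(rm$values)))
})

test_that("rod phantom band map shows the cell over background at high SNR", {
  ph <- make_cell_phantom(phantom_spec("rod"), seed = 5)
  bl <- subtract_baseline_map(ph$map)
  bm <- band_map(bl$corrected, bands[["750"]])
  center <- bm$values[ph$truth$regions == "rod_center"]
  backgr <- bm$values[ph$truth$regions == "background"]
  expect_gt(mean(center), mean(backgr) + 10 * sd(backgr))
})

test_that("time-course normalization modes behave as contracted", {
  nu <- seq(600, 1800, by = 1)
  base <- lorentz(nu, 750, 6, 100) + lorentz(nu, 1125, 6, 80) +
    lorentz(nu, 1640, 6, 200)
  ## constant series, to_t0 -> all ones
  rec <- timecourse_record(c(0, 5, 10), rep(list(spectrum(nu, base)), 3))
  n1 <- normalize_timecourse(rec, baseline = NULL)
  expect_equal(unname(n1$values), matrix(1, 3, 3))
  ## common-mode drift: all bands scaled by one per-time factor
  fac <- c(1, 0.8, 0.5)
  rec2 <- timecourse_record(c(0, 5, 10),
                            lapply(fac, function(f) spectrum(nu, f * base)))
  n2 <- normalize_timecourse(rec2, mode = "to_1640", baseline = NULL)
  ## to_1640 removes the factor exactly: series constant over time
  expect_equal(n2$values[1, ], n2$values[2, ], tolerance = 1e-12)
  expect_equal(n2$values[1, ], n2$values[3, ], tolerance = 1e-12)
  ## zero reference errors name the offending time
  rec3 <- timecourse_record(c(0, 5), list(spectrum(nu, base),
                                          spectrum(nu, 0 * base)))
  expect_error(normalize_timecourse(rec3, mode = "to_1640", baseline = NULL),
               class = "rr_norm_error")
  expect_error(normalize_timecourse(
    timecourse_record(c(0, 5), list(spectrum(nu, 0 * base),
                                    spectrum(nu, base))),
    baseline = NULL), class = "rr_norm_error")
})
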