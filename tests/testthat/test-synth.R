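bands <- default_bands()
ax <- default_axis()
lib <- component_library()

test_that("component library honours the published spectral constraints", {
  omb <- render_component(lib$oMb, ax)
  expect_lt(band_intensity(omb, bands[["750"]]),
            0.02 * band_intensity(omb, bands[["1640"]]))
  expect_lt(band_intensity(omb, bands[["1125"]]),
            0.02 * band_intensity(omb, bands[["1640"]]))
  ## dMb: 1603 marker present, 1640 essentially absent
  dmb <- render_component(lib$dMb, ax)
  expect_gt(band_intensity(dmb, bands[["1603"]]),
            5 * band_intensity(dmb, bands[["1640"]]))
  ## reduced : oxidized integrated intensity = configured contrast
  trap <- function(s) sum(diff(as.numeric(s$axis)) *
                            (utils::head(s$intensities, -1) +
                               utils::tail(s$intensities, -1)) / 2)
  r10 <- trap(render_component(lib$cyt_c_reduced, ax)) /
    trap(render_component(lib$cyt_c_oxidized, ax))
  expect_equal(r10, 10, tolerance = 0.01)
  lib5 <- component_library(redox_contrast = 5)
  r5 <- trap(render_component(lib5$cyt_c_reduced, ax)) /
    trap(render_component(lib5$cyt_c_oxidized, ax))
  expect_equal(r5, 5, tolerance = 0.01)
  ## axis must cover every line
  expect_error(render_component(lib$cyt_c_reduced, wn_axis(seq(800, 1800))),
               class = "rr_axis_error")
  ## empty line list -> zero spectrum
  empty <- list(name = "none", lines = data.frame(center = numeric(0),
                                                  hwhm = numeric(0),
                                                  amplitude = numeric(0)),
                scale = 1)
  expect_equal(render_component(empty, ax)$intensities, rep(0, length(ax)))
})

test_that("mixtures are linear in concentrations and reject bad input", {
  one <- render_mixture(c(cyt_c_reduced = 1), ax)
  two <- render_mixture(c(cyt_c_reduced = 2), ax)
  expect_equal(two$intensities, 2 * one$intensities)
  mixed <- render_mixture(c(cyt_c_reduced = 1, oMb = 3), ax)
  omb <- render_mixture(c(oMb = 3), ax)
  expect_equal(mixed$intensities, one$intensities + omb$intensities)
  expect_error(render_mixture(c(cyt_c_reduced = -1), ax),
               class = "rr_synth_error")
  expect_error(render_mixture(c(nonsense = 1), ax), class = "rr_synth_error")
})

test_that("noise is seeded, unbiased, and off when sigma is zero", {
  clean <- render_mixture(c(oMb = 1), ax)
  expect_identical(render_mixture(c(oMb = 1), ax, noise_scale = 0)$intensities,
                   clean$intensities)
  n1 <- render_mixture(c(oMb = 1), ax, noise_scale = 1, seed = 1)
  n1b <- render_mixture(c(oMb = 1), ax, noise_scale = 1, seed = 1)
  n2 <- render_mixture(c(oMb = 1), ax, noise_scale = 1, seed = 2)
  expect_identical(n1$intensities, n1b$intensities)
  expect_false(identical(n1$intensities, n2$intensities))
  ## two seeds share the expectation within 3 sigma / sqrt(n)
  d1 <- n1$intensities - clean$intensities
  d2 <- n2$intensities - clean$intensities
  sd_mean <- sqrt(mean((sqrt(pmax(clean$intensities, 0) + 100))^2) / length(ax))
  expect_lt(abs(mean(d1)), 3 * sd_mean)
  expect_lt(abs(mean(d2)), 3 * sd_mean)
})

test_that("SDT reduction raises the cytochrome bands at least 3-fold", {
  mix <- resting_mixture()
  pre <- render_mixture(mix$resting, ax)
  post <- render_mixture(mix$sdt, ax)
  for (b in c("750", "1125")) {
    fold <- band_intensity(post, bands[[b]]) / band_intensity(pre, bands[[b]])
    expect_gte(fold, 3)
  }
  ## deoxygenation: 1640 collapses, 1603 appears
  expect_lt(band_intensity(post, bands[["1640"]]),
            0.25 * band_intensity(pre, bands[["1640"]]))
  expect_gt(band_intensity(post, bands[["1603"]]),
            band_intensity(pre, bands[["1603"]]))
})

test_that("calibration reproduces arbitrary feasible targets through the quantifier", {
  ## sweep a grid of 20 feasible targets; achieved within 0.5%
  set.seed(8)
  grid <- expand.grid(r1 = seq(0.15, 0.6, length.out = 5),
                      r3 = seq(0.5, 1.4, length.out = 4))
  for (i in seq_len(nrow(grid))) {
    cc <- calibrate_region_concentrations(grid$r1[i], grid$r3[i])
    s <- render_mixture(cc, ax)
    a <- band_intensity(s, bands[["750"]])
    b <- band_intensity(s, bands[["1125"]])
    m <- band_intensity(s, bands[["1640"]])
    expect_lt(abs(a / m - grid$r1[i]) / grid$r1[i], 0.005)
    expect_lt(abs(a / b - grid$r3[i]) / grid$r3[i], 0.005)
  }
  ## zero target -> zero cytochromes
  cc0 <- calibrate_region_concentrations(0, 0)
  expect_equal(unname(cc0[c("cyt_c_reduced", "cyt_b_reduced")]), c(0, 0))
  ## infeasible I750/I1125 beyond the pure c-type component ratio
  expect_error(calibrate_region_concentrations(0.47, 5),
               class = "rr_synth_error")
})

test_that("phantom construction is deterministic with faithful ground truth", {
  sp <- phantom_spec("rod")
  p1 <- make_cell_phantom(sp, seed = 10)
  p2 <- make_cell_phantom(sp, seed = 10)
  expect_identical(p1$map$cube, p2$map$cube)
  expect_false(identical(make_cell_phantom(sp, seed = 11)$map$cube,
                         p1$map$cube))
  ## noiseless phantom: per-region measured ratios equal calibrated targets
  sp0 <- phantom_spec("rod", noise_scale = 0,
                      baseline = NULL)
  ph <- make_cell_phantom(sp0, seed = 1)
  for (reg in c("rod_center", "rod_periphery")) {
    px <- which(ph$truth$regions == reg, arr.ind = TRUE)[1, ]
    s <- pixel_spectrum(ph$map, px[1], px[2])
    tg <- ph$truth$spec$targets[[if (reg == "rod_center") "center" else "periphery"]]
    expect_equal(band_intensity(s, bands[["750"]]) /
                   band_intensity(s, bands[["1640"]]),
                 unname(tg["r750_1640"]), tolerance = 1e-9)
    expect_equal(band_intensity(s, bands[["750"]]) /
                   band_intensity(s, bands[["1125"]]),
                 unname(tg["r750_1125"]), tolerance = 1e-9)
  }
  ## truth record is self-consistent
  expect_equal(unname(ph$truth$true_ratios$center["r750_1640"]), 0.47,
               tolerance = 1e-9)
  ## background pixels carry only baseline + noise (here: nothing)
  bg <- ph$map$cube[ph$truth$regions == "background"]
  expect_equal(max(abs(bg)), 0)
  ## regions partition the footprint
  expect_true(all(ph$truth$regions %in%
                    c("background", "rod_edge", "rod_periphery", "rod_center")))
})

test_that("the round phantom has a single interior composition and the two-cell scene both", {
  pr <- make_cell_phantom(phantom_spec("round"), seed = 2)
  expect_true(all(c("round_interior", "round_edge") %in% pr$truth$regions))
  expect_false(any(grepl("rod", pr$truth$regions)))
  p2 <- make_cell_phantom(phantom_spec("two_cell"), seed = 2)
  expect_true(all(c("rod_center", "rod_periphery", "round_interior") %in%
                    p2$truth$regions))
  expect_equal(dim(p2$map), c(20, 60))
})

test_that("H2O2 simulation declines as configured and zero rates mimic control", {
  spec0 <- h2o2_spec(k_cyt = 0, k_omb = 0, n_replicates = 2)
  sim0 <- simulate_h2o2_course(spec0, seed = 5)
  r0 <- run_timecourse_analysis(sim0$treated, sim0$control,
                                pipeline_config(boot_n = 200))
  ## treated == control in expectation: end-point declines all near zero
  expect_lt(max(abs(unlist(r0$declines))), 0.05)
  ## expected amplitude factors recorded in truth
  sim <- simulate_h2o2_course(h2o2_spec(n_replicates = 2), seed = 5)
  expect_equal(sim$truth$cyt_factor[sim$truth$times <= 10],
               rep(1, sum(sim$truth$times <= 10)))
  expect_equal(utils::tail(sim$truth$cyt_factor, 1), 0.4, tolerance = 1e-12)
  expect_equal(utils::tail(sim$truth$omb_factor, 1), 0.7, tolerance = 1e-12)
})
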