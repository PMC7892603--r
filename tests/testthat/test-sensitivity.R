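test_that("full curve matches melanopsin-alone beyond the cross-point and shows the enhanced/reduced structure", {
  full <- cached_curve("full")
  ref <- cached_curve("melanopsin_only")
  wl <- full$wavelength_nm

  # common scale: raw response per unit irradiance
  yellow <- wl >= 500
  expect_equal(full$raw[yellow], ref$raw[yellow], tolerance = 1e-12)
  expect_gt(full$raw[wl == 460], ref$raw[wl == 460])   # enhanced < 470 nm
  expect_lt(full$raw[wl == 490], ref$raw[wl == 490])   # reduced 470-500 nm

  # monotone branch structure for monochromatic stimuli
  expect_true(all(full$branch[wl < 500] == "blue"))
  expect_true(all(full$branch[wl >= 500] == "yellow"))
  expect_equal(sum(diff(full$branch == "blue") != 0), 1L)

  # peak-normalization invariants and idempotence
  expect_equal(max(full$values), 1)
  expect_true(all(full$values >= 0))
  expect_equal(full$values / max(full$values), full$values)
})

test_that("half-bandwidth metric finds interpolated half-maximum crossings", {
  wl <- 380:780
  gauss <- exp(-4 * log(2) * ((wl - 520) / 80)^2)
  expect_equal(fwhm(gauss, wavelength_nm = wl), 80, tolerance = 0.5 / 80)
  expect_error(fwhm(rep(1, length(wl)), wavelength_nm = wl), "undefined")
  expect_error(fwhm(rep(0, length(wl)), wavelength_nm = wl), "maximum")
  # melanopsin-alone curve: near the 80 nm opsin width, narrowed and skewed
  # by lens filtering of the short flank
  f <- fwhm(cached_curve("melanopsin_only"))
  expect_equal(f, 80, tolerance = 10 / 80)
  expect_equal(f, fwhm(default_model()$sensitivities$mel), tolerance = 1e-6)
})

test_that("the notch sits at the cross-point and fills in as light level rises", {
  full <- cached_curve("full")
  ref <- cached_curve("melanopsin_only")
  nm <- notch_metrics(full, ref)
  expect_equal(nm$notch_wavelength_nm, 500, tolerance = 1)
  expect_gt(nm$notch_depth, 0)
  expect_equal(notch_metrics(ref, ref)$notch_depth, 0)

  depths <- vapply(c(100, 300, 1000, 3000), function(lev) {
    notch_metrics(cached_curve("full", lev),
                  cached_curve("melanopsin_only", lev))$notch_depth
  }, numeric(1))
  expect_true(all(diff(depths) < 0))
  expect_lt(depths[4], depths[2])  # 3000 lx shallower than 300 lx
})

test_that("excluded wavelengths are recorded, not interpolated", {
  m <- default_model()
  full <- cached_curve("full")
  expect_length(full$excluded_nm, 0)  # V' > 0 throughout 400-650 nm
  wide <- spectral_sensitivity(m, range_nm = c(400, 780))
  expect_true(all(wide$excluded_nm > 750))
  expect_false(any(wide$wavelength_nm %in% wide$excluded_nm))
})

test_that("curve files are byte-identical across reruns", {
  full <- cached_curve("full")
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_curve(full, p1)
  write_curve(spectral_sensitivity(default_model(), variant = "full"), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("polychromatic mixtures are subadditive; pure addition needs the opponent difference disabled", {
  m <- default_model()
  g <- m$grid

  # blue line at its criterion-level power (shunt well engaged but dominated
  # by the SB input), yellow line scaled to pull the mixture across b-y = 0
  p450 <- 300 / scotopic_lux(spd_monochromatic(450, 1, g))
  a <- spd_monochromatic(450, p450, g)
  by_a <- predict(m, a, type = "opponent")$b_minus_y
  by_570_unit <- predict(m, spd_monochromatic(570, 1, g),
                         type = "opponent")$b_minus_y
  b <- spd_monochromatic(570, 1.3 * by_a / abs(by_570_unit), g)
  expect_equal(predict(m, a, type = "opponent")$branch, "blue")
  expect_equal(predict(m, b, type = "opponent")$branch, "yellow")
  expect_equal(predict(m, spd_mix(list(a, b)), type = "opponent")$branch,
               "yellow")
  expect_lt(subadditivity_index(m, a, b), 1)

  # strict subadditivity also when the mixture stays on the blue branch
  b_small <- spd_monochromatic(570, 0.3 * by_a / abs(by_570_unit), g)
  expect_equal(predict(m, spd_mix(list(a, b_small)), type = "opponent")$branch,
               "blue")
  expect_lt(subadditivity_index(m, a, b_small), 1)

  # additivity restored when shunt and opponent input are disabled
  m_lin <- circadian_model(params = list(a1 = 0, a2 = 0,
                                         a3 = coef(m)[["a3"]],
                                         rod_sat = coef(m)[["rod_sat"]]))
  expect_equal(subadditivity_index(m_lin, a, b), 1, tolerance = 1e-12)
  expect_equal(subadditivity_index(m_lin, a, a), 1, tolerance = 1e-12)
  # with only the shunt off, response is linear within each branch
  m_noshunt <- circadian_model(params = list(a1 = coef(m)[["a1"]], a2 = 0,
                                             a3 = coef(m)[["a3"]],
                                             rod_sat = coef(m)[["rod_sat"]]))
  expect_equal(subadditivity_index(m_noshunt, a, a), 1, tolerance = 1e-12)

  # additive identity: an all-zero partner contributes nothing
  zero <- spd(rep(0, g$n), g)
  expect_equal(subadditivity_index(m, a, zero), 1, tolerance = 1e-12)
  expect_error(subadditivity_index(m, zero, zero), "undefined")

  # warm/cool white pair straddling the cross-point, at photopic levels
  cool <- spd_blackbody(6500, g, 0.5)
  warm <- spd_blackbody(2700, g, 1.5)
  expect_equal(predict(m, cool, type = "opponent")$branch, "blue")
  expect_equal(predict(m, warm, type = "opponent")$branch, "yellow")
  expect_lt(subadditivity_index(m, cool, warm), 1)
})

test_that("model object methods expose the fit", {
  m <- default_model()
  expect_s3_class(m, "circadian_model")
  expect_named(coef(m), c("k", "a1", "a2", "a3", "rod_sat"))
  expect_output(print(m), "cross-point: 500 nm")
  r <- predict(m, list(spd_monochromatic(460, 0.1, m$grid),
                       spd_monochromatic(600, 0.1, m$grid)))
  expect_length(r, 2)
  expect_true(all(r >= 0))
  exc <- predict(m, spd_monochromatic(430, 1, m$grid), type = "excitations")
  expect_equal(exc$V_ach, exc$X_L + exc$X_M)
  s <- summary(m)
  expect_equal(s$notch_wavelength_nm, 500, tolerance = 1)
  expect_equal(s$fwhm_full, 100, tolerance = 10 / 100)
})
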