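test_that("excitations are template-weighted integrals, linear in the stimulus", {
  g <- wavelength_grid()
  sens <- default_sens()
  z <- excitations(spd(rep(0, g$n), g), sens)
  expect_true(all(unlist(z) == 0))

  e430 <- excitations(spd_monochromatic(430, 1, g), sens)
  expect_gt(e430$X_S, e430$X_L)
  expect_equal(e430$V_ach, e430$X_L + e430$X_M)
  # line excitations reduce to sensitivity value x power
  expect_equal(e430$X_S, sens$S$values[wavelengths(g) == 430])

  set.seed(3)
  a <- spd(runif(g$n), g); b <- spd_blackbody(4000, g)
  ea <- excitations(a, sens); eb <- excitations(b, sens)
  eab <- excitations(spd_mix(list(a, b)), sens)
  for (f in names(ea))
    expect_equal(eab[[f]], ea[[f]] + eb[[f]], tolerance = 1e-12)
})

test_that("opponent channel crosses from blue to yellow at the calibrated point", {
  g <- wavelength_grid()
  sens <- default_sens()
  k <- calibrate_cross_point(sens)
  expect_gt(k, 0)

  at <- function(lambda, power = 1)
    opponent_by(excitations(spd_monochromatic(lambda, power, g), sens), k)
  expect_equal(at(500)$b_minus_y, 0, tolerance = 1e-14)
  expect_equal(at(500)$branch, "yellow")
  expect_equal(at(500, 50)$branch, "yellow")  # branch stable across power
  expect_equal(at(450)$branch, "blue")
  expect_equal(at(580)$branch, "yellow")

  # independent oracle: sign of s_S - k (s_L + s_M) from the template model
  sS <- oracle_corneal(430); sL <- oracle_corneal(565); sM <- oracle_corneal(535)
  wl <- 380:780
  k_o <- sS[wl == 500] / (sL[wl == 500] + sM[wl == 500])
  expect_equal(k, k_o, tolerance = 1e-12)
  expect_gt(sS[wl == 450] - k_o * (sL[wl == 450] + sM[wl == 450]), 0)
  expect_lt(sS[wl == 580] - k_o * (sL[wl == 580] + sM[wl == 580]), 0)
})

test_that("rod shunt saturates towards a2 and is released by cone drive", {
  p <- circuit_params(k = 0.3, a1 = 0.5, a2 = 0.2, a3 = 10, rod_sat = 0.1)
  mk <- function(X_rod, V_ach = 0)
    structure(list(X_S = 0, X_M = V_ach / 2, X_L = V_ach / 2, X_rod = X_rod,
                   X_mel = 0, V_ach = V_ach), class = "excitations")
  expect_equal(rod_shunt(mk(0), p), 0)
  rods <- 10^seq(-3, 0.3, length.out = 50)
  sh <- vapply(rods, function(r) rod_shunt(mk(r), p), numeric(1))
  expect_true(all(diff(sh) > 0))            # monotone in rod excitation
  expect_true(all(sh < p$a2))               # bounded by the amplitude
  expect_equal(rod_shunt(mk(1e6), p), p$a2, tolerance = 1e-6)
  # doubling the achromatic drive strictly reduces the shunt
  for (r in c(0.01, 0.1, 1))
    for (v in c(0.01, 0.1, 1))
      expect_lt(rod_shunt(mk(r, 2 * v), p), rod_shunt(mk(r, v), p))
})

test_that("circuit response follows the piecewise branch rule", {
  g <- wavelength_grid()
  m <- default_model()
  sens <- m$sensitivities
  p <- m$params

  expect_equal(circadian_response(spd(rep(0, g$n), g), p, sens), 0)

  # yellow branch: the ipRGC acts alone at any power
  for (pow in c(1e-4, 0.1, 10, 1000)) {
    line <- spd_monochromatic(600, pow, g)
    expect_equal(circadian_response(line, p, sens),
                 excitations(line, sens)$X_mel)
  }

  # blue branch threshold: a dim blue-rich stimulus is clamped at zero while
  # an equal-power long-wavelength line still drives the ipRGC
  dim_level <- NULL
  for (pow in 10^seq(-2, -7)) {
    line <- spd_monochromatic(490, pow, g)
    e <- excitations(line, sens)
    if (e$X_mel + p$a1 * opponent_by(e, p$k)$b_minus_y < rod_shunt(e, p)) {
      dim_level <- pow; break
    }
  }
  expect_false(is.null(dim_level))
  expect_equal(circadian_response(spd_monochromatic(490, dim_level, g), p, sens), 0)
  expect_gt(circadian_response(spd_monochromatic(600, dim_level, g), p, sens), 0)

  # equivalence oracle: pipeline response equals the one-line formula
  set.seed(9)
  stimuli <- c(lapply(c(430, 470, 500, 540, 620), function(l)
                 spd_monochromatic(l, runif(1, 0.01, 2), g)),
               list(spd_blackbody(2700, g, 0.05), spd_blackbody(6500, g, 0.05),
                    spd(runif(g$n, 0, 0.02), g)))
  for (x in stimuli) {
    e <- excitations(x, sens)
    by <- e$X_S - p$k * e$V_ach
    direct <- if (by > 1e-12 * (e$X_S + p$k * e$V_ach))
      max(0, e$X_mel + p$a1 * by -
            p$a2 * (1 - exp(-(e$X_rod / (1 + p$a3 * e$V_ach)) / p$rod_sat)))
    else e$X_mel
    expect_equal(circadian_response(x, p, sens), direct, tolerance = 1e-14)
  }
})

test_that("exactly one branch applies and the yellow branch ignores the gains", {
  g <- wavelength_grid()
  m <- default_model()
  sens <- m$sensitivities
  p <- m$params
  alt <- circuit_params(p$k, p$a1 * 7 + 0.1, p$a2 * 3 + 0.5, p$a3 * 0.1 + 1,
                        p$rod_sat * 5)
  for (lambda in c(510, 560, 600, 650)) {
    line <- spd_monochromatic(lambda, 0.3, g)
    e <- excitations(line, sens)
    expect_equal(opponent_by(e, p$k)$branch, "yellow")
    expect_equal(circadian_response(line, p, sens),
                 circadian_response(line, alt, sens))
  }
  warm <- spd_blackbody(2700, g, 0.1)
  expect_equal(predict(m, warm, type = "opponent")$branch, "yellow")
  expect_equal(circadian_response(warm, p, sens),
               circadian_response(warm, alt, sens))
})

test_that("response is non-decreasing in intensity on both branches", {
  g <- wavelength_grid()
  m <- default_model()
  scales <- 10^seq(-4, 2, length.out = 80)
  for (base in list(spd_monochromatic(460, 1, g),
                    spd_monochromatic(600, 1, g),
                    spd_blackbody(6500, g, 1))) {
    r <- vapply(scales, function(s)
      circadian_response(spd_mix(list(base), s), m$params, m$sensitivities),
      numeric(1))
    expect_true(all(diff(r) >= -1e-12))
  }
})

test_that("gain calibration is deterministic and hits its targets", {
  m <- default_model()
  expect_equal(m$achieved_fwhm, 100, tolerance = 10 / 100)
  sens <- m$sensitivities
  p1 <- calibrate_gains(sens, target_fwhm = 100, criterion = 300)
  p2 <- calibrate_gains(sens, target_fwhm = 100, criterion = 300)
  expect_identical(unlist(p1), unlist(p2))
  expect_error(calibrate_gains(sens, target_fwhm = 60), "exceed")

  # with the SB input and the shunt disabled the circuit is melanopsin alone
  m0 <- circadian_model(params = list(a1 = 0, a2 = 0, a3 = p1$a3,
                                      rod_sat = p1$rod_sat))
  full0 <- spectral_sensitivity(m0, variant = "full")
  ref0 <- spectral_sensitivity(m0, variant = "melanopsin_only")
  expect_equal(full0$raw, ref0$raw, tolerance = 1e-12)
  expect_equal(fwhm(full0), fwhm(ref0))
})

test_that("moving the cross-point moves the predicted discontinuity", {
  m510 <- circadian_model(cross_point = 510)
  full <- spectral_sensitivity(m510, variant = "full")
  ref <- spectral_sensitivity(m510, variant = "melanopsin_only")
  expect_equal(notch_metrics(full, ref)$notch_wavelength_nm, 510, tolerance = 1)
})
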