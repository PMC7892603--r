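#' Fit (calibrate) the circadian phototransduction circuit model
#'
#' Builds the full retinal circuit model for circadian phototransduction:
#' corneal spectral sensitivities for the five photoreceptor classes
#' (photopigment templates filtered by the crystalline lens), the spectrally
#' opponent blue-yellow channel of the S-cone bipolar, rod shunting
#' inhibition of the M1 ipRGC with cone release, and the A18-mediated
#' decoupling of the shunt for "warm" (yellow-branch) stimuli. The opponent
#' balance gain `k` is calibrated in closed form so the blue/yellow
#' cross-point for monochromatic light falls at `cross_point` nm, and the
#' remaining gains are calibrated by the deterministic search of
#' [calibrate_gains()] so the predicted monochromatic sensitivity curve at
#' `criterion` scotopic lux has the target half-bandwidth (100 nm) with the
#' characteristic enhanced/reduced structure around the notch.
#'
#' @param grid A [wavelength_grid()]; default 380--780 nm at 1 nm.
#' @param pigments Named list of [pigment_spec()]s (default the five human
#'   photopigments; see [default_pigments()]).
#' @param lens `"bundled-table"` (default), `"unity"`, or a [lens_model()].
#' @param cross_point Blue/yellow cross-point wavelength, nm; default 500.
#' @param criterion Calibration light level in scotopic lux; default 300
#'   (approximately the half-saturation level for nocturnal melatonin
#'   suppression, and a level at which rod shunting controls threshold).
#' @param target_fwhm Target circadian half-bandwidth in nm; default 100.
#' @param params Optional [circuit_params()] (or named list/vector with
#'   elements `a1`, `a2`, `a3`, `rod_sat` and optionally `k`) to use
#'   instead of running the gain calibration. A missing `k` is calibrated
#'   in closed form.
#' @return An object of class `"circadian_model"` with components `grid`,
#'   `pigments`, `lens`, `sensitivities` (corneal sensitivity [spd()]s),
#'   `params`, `cross_point`, `criterion`, `target_fwhm`, `calibrated`
#'   (logical) and `achieved_fwhm`.
#' @examples
#' \donttest{
#' m <- circadian_model()
#' coef(m)
#' predict(m, spd_monochromatic(460, 0.1))
#' }
#' @export
circadian_model <- function(grid = wavelength_grid(),
                            pigments = default_pigments(),
                            lens = "bundled-table",
                            cross_point = 500,
                            criterion = 300,
                            target_fwhm = 100,
                            params = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (is.character(lens)) lens <- lens_model(grid, lens)
  stopifnot(inherits(lens, "lens_model"))
  check_same_grid(grid, lens$transmittance$grid, "grid and lens")
  need <- c("rod", "mel", "L", "M", "S")
  if (!all(need %in% names(pigments)))
    stop("pigments must be a named list covering rod, mel, L, M, S")
  sens <- corneal_sensitivities(pigments[need], lens, grid)

  if (is.null(params)) {
    params <- calibrate_gains(sens, grid, target_fwhm = target_fwhm,
                              criterion = criterion,
                              lambda_cross = cross_point)
    calibrated <- TRUE
    achieved <- attr(params, "achieved_fwhm")
  } else {
    p <- as.list(unlist(params))
    if (is.null(p$k))
      p$k <- calibrate_cross_point(sens, cross_point)
    params <- circuit_params(p$k, p$a1, p$a2, p$a3, p$rod_sat)
    calibrated <- FALSE
    achieved <- NA_real_
  }
  attr(params, "achieved_fwhm") <- NULL
  attr(params, "criterion") <- NULL

  structure(
    list(grid = grid, pigments = pigments[need], lens = lens,
         sensitivities = sens, params = params,
         cross_point = cross_point, criterion = criterion,
         target_fwhm = target_fwhm, calibrated = calibrated,
         achieved_fwhm = achieved),
    class = "circadian_model")
}

#' @export
print.circadian_model <- function(x, ...) {
  cat("Circadian phototransduction circuit model\n")
  cat(sprintf("  grid: %g-%g nm at %g nm; lens: %s\n",
              x$grid$start_nm, x$grid$stop_nm, x$grid$step_nm,
              x$lens$source))
  cat(sprintf("  blue/yellow cross-point: %g nm; criterion: %g scotopic lx\n",
              x$cross_point, x$criterion))
  cat(sprintf("  gains %s\n",
              if (x$calibrated)
                sprintf("calibrated (achieved half-bandwidth %.1f nm)",
                        x$achieved_fwhm)
              else "supplied by the user"))
  cat(sprintf("  %s\n", paste(sprintf("%s=%.4g", names(coef(x)), coef(x)),
                              collapse = ", ")))
  invisible(x)
}

#' @export
coef.circadian_model <- function(object, ...) {
  unlist(object$params)
}

#' @export
summary.circadian_model <- function(object, ...) {
  full <- spectral_sensitivity(object, variant = "full")
  ref <- spectral_sensitivity(object, variant = "melanopsin_only")
  nm <- notch_metrics(full, ref)
  out <- list(model = object,
              fwhm_full = fwhm(full),
              fwhm_mel = fwhm(ref),
              notch_wavelength_nm = nm$notch_wavelength_nm,
              notch_depth = nm$notch_depth)
  class(out) <- "summary.circadian_model"
  out
}

#' @export
print.summary.circadian_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  predicted half-bandwidth at criterion: %.1f nm (melanopsin alone: %.1f nm)\n",
              x$fwhm_full, x$fwhm_mel))
  cat(sprintf("  notch: %.0f nm, depth %.3f\n",
              x$notch_wavelength_nm, x$notch_depth))
  invisible(x)
}

#' Predict circuit quantities for new stimuli
#'
#' @param object A fitted [circadian_model()].
#' @param newdata An irradiance [spd()] or a list of them.
#' @param type `"response"` (circadian drive, the default),
#'   `"excitations"` (data frame of the five excitations plus `V_ach`),
#'   `"opponent"` (data frame with `b_minus_y` and `branch`), or
#'   `"shunt"` (rod shunting magnitude).
#' @param ... Unused.
#' @return A numeric vector (`response`, `shunt`) or data frame
#'   (`excitations`, `opponent`), one entry/row per stimulus.
#' @export
predict.circadian_model <- function(object, newdata,
                                    type = c("response", "excitations",
                                             "opponent", "shunt"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "spd")) newdata <- list(newdata)
  if (!is.list(newdata) || !all(vapply(newdata, inherits, logical(1), "spd")))
    stop("newdata must be an spd or a list of spd objects")
  exc <- lapply(newdata, excitations, sens = object$sensitivities)
  switch(type,
    response = vapply(exc, circuit_response, numeric(1),
                      params = object$params),
    shunt = vapply(exc, rod_shunt, numeric(1), params = object$params),
    excitations = do.call(rbind, lapply(exc, function(e)
      data.frame(X_S = e$X_S, X_M = e$X_M, X_L = e$X_L, X_rod = e$X_rod,
                 X_mel = e$X_mel, V_ach = e$V_ach))),
    opponent = do.call(rbind, lapply(exc, function(e) {
      o <- opponent_by(e, object$params$k)
      data.frame(b_minus_y = o$b_minus_y, branch = o$branch)
    }))
  )
}

#' Plot the model's predicted spectral sensitivity
#'
#' Draws the full-circuit monochromatic sensitivity curve at the model's
#' criterion level together with the melanopsin-only reference, showing the
#' enhancement below 470 nm, the reduced region approaching the cross-point
#' and the discontinuity at the notch.
#'
#' @param x A fitted [circadian_model()].
#' @param criterion Criterion level in scotopic lux (default: the model's).
#' @param ... Passed to [graphics::plot()].
#' @return The pair of curves, invisibly.
#' @export
plot.circadian_model <- function(x, criterion = x$criterion, ...) {
  full <- spectral_sensitivity(x, criterion = criterion, variant = "full")
  ref <- spectral_sensitivity(x, criterion = criterion,
                              variant = "melanopsin_only")
  scale <- ref$peak_raw
  graphics::plot(full$wavelength_nm, full$raw / scale, type = "l",
                 col = "blue", lwd = 2, xlab = "wavelength (nm)",
                 ylab = "relative circadian sensitivity",
                 main = sprintf("Predicted spectral sensitivity, %g scotopic lx",
                                criterion), ...)
  graphics::lines(ref$wavelength_nm, ref$raw / scale, lty = 2)
  graphics::abline(v = x$cross_point, col = "grey", lty = 3)
  graphics::legend("topright", c("full circuit", "melanopsin only"),
                   col = c("blue", "black"), lty = c(1, 2), bty = "n")
  invisible(list(full = full, reference = ref))
}
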