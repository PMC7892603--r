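# locate outermost half-maximum crossings of a sampled curve by linear
# interpolation; errors if a flank never falls below half maximum.
fwhm_of <- function(wl, values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0) stop("curve has no positive maximum")
  half <- m / 2
  above <- values >= half
  if (all(above) || !any(above))
    stop("half-maximum crossings undefined for this curve")
  i_peak <- which.max(values)
  first_above <- which(above)[1]
  last_above <- which(above)[length(which(above))]
  if (first_above == 1)
    stop("no half-maximum crossing on the short-wavelength flank")
  if (last_above == length(values))
    stop("no half-maximum crossing on the long-wavelength flank")
  interp <- function(i, j) {
    wl[i] + (half - values[i]) * (wl[j] - wl[i]) / (values[j] - values[i])
  }
  left <- interp(first_above - 1, first_above)
  right <- interp(last_above, last_above + 1)
  right - left
}

#' Model-predicted spectral sensitivity curve
#'
#' For each wavelength in `range_nm`, builds a monochromatic line scaled so
#' its scotopic illuminance equals the criterion level, runs the circuit,
#' and records the circadian drive per unit corneal irradiance. The curve is
#' peak-normalized; the raw per-irradiance values and the raw peak are kept
#' so two curves can be compared on a common scale. The
#' `"melanopsin_only"` variant runs the same pipeline with the response
#' replaced by the intrinsic melanopsin excitation (the ipRGC acting alone).
#'
#' Wavelengths where the scotopic luminous efficiency is zero on the grid
#' cannot be scaled to the criterion; they are excluded and listed in the
#' result's `excluded_nm` field, never interpolated over.
#'
#' @param model A fitted [circadian_model()].
#' @param criterion Criterion level in scotopic lux (default: the model's).
#' @param variant `"full"` (whole circuit) or `"melanopsin_only"`.
#' @param range_nm Wavelength range evaluated; default 400--650 nm.
#' @return An object of class `"sensitivity_curve"`: list with
#'   `wavelength_nm`, `values` (peak 1), `raw` (response per unit
#'   irradiance), `peak_raw`, `branch` (per-wavelength `"blue"`/`"yellow"`),
#'   `criterion_scotopic_lux`, `variant`, `excluded_nm`, `params`.
#' @examples
#' \donttest{
#' m <- circadian_model()
#' curve <- spectral_sensitivity(m)
#' fwhm(curve)
#' }
#' @export
spectral_sensitivity <- function(model, criterion = model$criterion,
                                 variant = c("full", "melanopsin_only"),
                                 range_nm = c(400, 650)) {
  stopifnot(inherits(model, "circadian_model"))
  variant <- match.arg(variant)
  if (!is.finite(criterion) || criterion <= 0)
    stop("criterion must be a positive scotopic illuminance")
  grid <- model$grid
  wl_all <- wavelengths(grid)
  wl <- wl_all[wl_all >= range_nm[1] & wl_all <= range_nm[2]]
  power <- criterion_powers(wl, grid, criterion)
  excluded <- wl[!is.finite(power)]
  keep <- is.finite(power)
  wl <- wl[keep]; power <- power[keep]
  raw <- numeric(length(wl))
  branch <- character(length(wl))
  for (i in seq_along(wl)) {
    line <- spd_monochromatic(wl[i], power[i], grid)
    exc <- excitations(line, model$sensitivities)
    branch[i] <- opponent_by(exc, model$params$k)$branch
    r <- if (variant == "full") circuit_response(exc, model$params)
         else exc$X_mel
    raw[i] <- r / power[i]
  }
  peak <- max(raw)
  if (peak <= 0) stop("sensitivity curve is identically zero")
  structure(
    list(wavelength_nm = wl, values = raw / peak, raw = raw, peak_raw = peak,
         branch = branch, criterion_scotopic_lux = criterion,
         variant = variant, excluded_nm = excluded,
         params = model$params),
    class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("Spectral sensitivity curve (%s) at %g scotopic lx\n",
              x$variant, x$criterion_scotopic_lux))
  cat(sprintf("  %g-%g nm (%d points), peak at %g nm\n",
              min(x$wavelength_nm), max(x$wavelength_nm),
              length(x$wavelength_nm),
              x$wavelength_nm[which.max(x$values)]))
  f <- tryCatch(fwhm(x), error = function(e) NA_real_)
  if (is.finite(f)) cat(sprintf("  half-bandwidth (FWHM): %.1f nm\n", f))
  if (length(x$excluded_nm))
    cat(sprintf("  excluded wavelengths (V' = 0): %d\n", length(x$excluded_nm)))
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ..., col = "black") {
  graphics::plot(x$wavelength_nm, x$values, type = "l", col = col,
                 xlab = "wavelength (nm)", ylab = "relative sensitivity",
                 main = sprintf("%s, %g scotopic lx", x$variant,
                                x$criterion_scotopic_lux), ...)
  invisible(x)
}

#' Half-bandwidth (full width at half maximum) of a curve
#'
#' Distance between the outermost half-maximum crossings, each located by
#' linear interpolation between the bracketing grid points. Errors (rather
#' than extrapolating) if a flank never falls below half maximum.
#'
#' @param x A `sensitivity_curve`, an [spd()], or a numeric vector of curve
#'   values (then supply `wavelength_nm`).
#' @param ... Unused.
#' @return Width in nm.
#' @export
fwhm <- function(x, ...) UseMethod("fwhm")

#' @rdname fwhm
#' @export
fwhm.sensitivity_curve <- function(x, ...) fwhm_of(x$wavelength_nm, x$values)

#' @rdname fwhm
#' @export
fwhm.spd <- function(x, ...) fwhm_of(wavelengths(x$grid), x$values)

#' @rdname fwhm
#' @param wavelength_nm Wavelengths for a bare numeric curve.
#' @export
fwhm.default <- function(x, wavelength_nm, ...) fwhm_of(wavelength_nm, x)

#' Notch location and depth
#'
#' Locates the spectral discontinuity of the full circuit prediction (the
#' "notch") as the largest jump between adjacent grid points of the
#' normalized curve, reported as the wavelength where the new branch begins
#' (the right endpoint of the jump pair). Notch depth is the maximum, over
#' the 470--500 nm transition region, of the melanopsin-only reference minus
#' the full curve, with both curves on a common scale (divided by the
#' reference's raw peak).
#'
#' @param full A full-variant [spectral_sensitivity()] curve.
#' @param reference The melanopsin-only curve at the same criterion level and
#'   on the same wavelengths.
#' @param depth_range_nm Region over which depth is evaluated; default
#'   470--500 nm.
#' @return List with `notch_wavelength_nm` and `notch_depth` (>= 0,
#'   dimensionless).
#' @export
notch_metrics <- function(full, reference, depth_range_nm = c(470, 500)) {
  stopifnot(inherits(full, "sensitivity_curve"),
            inherits(reference, "sensitivity_curve"))
  if (!isTRUE(all.equal(full$wavelength_nm, reference$wavelength_nm)))
    stop("curves are on different wavelength sets")
  if (!isTRUE(all.equal(full$criterion_scotopic_lux,
                        reference$criterion_scotopic_lux)))
    stop("curves were computed at different criterion levels")
  jumps <- abs(diff(full$values))
  j <- which.max(jumps)
  notch_wl <- full$wavelength_nm[j + 1]
  scale <- reference$peak_raw
  sel <- full$wavelength_nm >= depth_range_nm[1] &
    full$wavelength_nm <= depth_range_nm[2]
  depth <- max(c(0, (reference$raw[sel] - full$raw[sel]) / scale))
  list(notch_wavelength_nm = notch_wl, notch_depth = depth)
}

#' Subadditivity index of a stimulus pair
#'
#' `response(A + B) / (response(A) + response(B))`. Spectrally opponent
#' differencing makes the circuit subadditive for polychromatic light: the
#' index is 1 for perfectly additive pairs and below 1 when one component
#' pulls the mixture's b-y balance towards or across zero.
#'
#' @param model A fitted [circadian_model()].
#' @param a,b Irradiance [spd()] stimuli on the model grid.
#' @return Dimensionless ratio.
#' @export
subadditivity_index <- function(model, a, b) {
  stopifnot(inherits(model, "circadian_model"))
  ra <- circadian_response(a, model$params, model$sensitivities)
  rb <- circadian_response(b, model$params, model$sensitivities)
  if (ra + rb <= 0)
    stop("subadditivity index undefined: both component responses are zero")
  rab <- circadian_response(spd_mix(list(a, b)), model$params,
                            model$sensitivities)
  rab / (ra + rb)
}

#' Write a sensitivity curve to CSV
#'
#' CSV with `#`-prefixed metadata (criterion, variant, parameter hash,
#' per-wavelength branch labels as a companion column) and a
#' `wavelength_nm,value` header. Identical model parameters and criterion
#' produce byte-identical files.
#'
#' @param x A `sensitivity_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path) {
  stopifnot(inherits(x, "sensitivity_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# criterion_scotopic_lux: %.10g", x$criterion_scotopic_lux), con)
  writeLines(sprintf("# variant: %s", x$variant), con)
  writeLines(sprintf("# params_hash: %s", params_hash(x$params)), con)
  if (length(x$excluded_nm))
    writeLines(sprintf("# excluded_nm: %s",
                       paste(x$excluded_nm, collapse = ";")), con)
  writeLines("wavelength_nm,value,branch", con)
  writeLines(sprintf("%.10g,%.10g,%s", x$wavelength_nm, x$values, x$branch), con)
  invisible(path)
}

# md5 of the canonical parameter string; ties outputs to a configuration
params_hash <- function(params) {
  s <- paste(sprintf("%s=%.12g", names(params), unlist(params)), collapse = ";")
  tf <- tempfile()
  writeLines(s, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}
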