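#' Photopigment specification
#'
#' Peak wavelength and bandwidth for one photoreceptor class. The defaults
#' are the five human photopigments feeding the circadian circuit: rhodopsin
#' (rod, 498 nm), melanopsin (ipRGC, 480 nm) and the L/M/S cone opsins
#' (565/535/430 nm), each modelled with an 80 nm half-bandwidth.
#'
#' @param name One of `"rod"`, `"mel"`, `"L"`, `"M"`, `"S"`.
#' @param lambda_max Peak wavelength in nm.
#' @param half_bandwidth Full width at half maximum of the template, nm.
#' @return An object of class `"pigment_spec"`.
#' @seealso [pigment_template()], [default_pigments()]
#' @export
pigment_spec <- function(name = c("rod", "mel", "L", "M", "S"),
                         lambda_max = NULL, half_bandwidth = 80) {
  name <- match.arg(name)
  if (is.null(lambda_max))
    lambda_max <- c(rod = 498, mel = 480, L = 565, M = 535, S = 430)[[name]]
  stopifnot(is.numeric(lambda_max), length(lambda_max) == 1,
            is.numeric(half_bandwidth), length(half_bandwidth) == 1)
  if (!is.finite(lambda_max) || lambda_max <= 0)
    stop("lambda_max must be a positive wavelength in nm")
  if (!is.finite(half_bandwidth) || half_bandwidth <= 0)
    stop("half_bandwidth must be positive")
  structure(list(name = name, lambda_max = lambda_max,
                 half_bandwidth = half_bandwidth),
            class = "pigment_spec")
}

#' @rdname pigment_spec
#' @param lambda_max_overrides Optional named numeric vector overriding
#'   individual peak wavelengths, e.g. `c(mel = 483)`.
#' @return `default_pigments()` returns a named list of the five specs.
#' @export
default_pigments <- function(lambda_max_overrides = NULL) {
  lm <- c(rod = 498, mel = 480, L = 565, M = 535, S = 430)
  if (!is.null(lambda_max_overrides)) {
    bad <- setdiff(names(lambda_max_overrides), names(lm))
    if (length(bad)) stop("unknown pigment name(s): ", paste(bad, collapse = ", "))
    lm[names(lambda_max_overrides)] <- lambda_max_overrides
  }
  lapply(stats::setNames(names(lm), names(lm)),
         function(nm) pigment_spec(nm, lambda_max = lm[[nm]]))
}

#' Photopigment spectral template
#'
#' Peak-normalized Gaussian-in-wavelength opsin template whose full width at
#' half maximum equals the pigment's `half_bandwidth`. Single-opsin action
#' spectra are close to Gaussian with a half-bandwidth of roughly 80 nm, and
#' the Gaussian form makes that bandwidth an exact property of the template.
#'
#' @param spec A [pigment_spec()]; its `lambda_max` must lie within the grid.
#' @param grid A [wavelength_grid()].
#' @return A sensitivity [spd()] with maximum 1 at `lambda_max`.
#' @examples
#' mel <- pigment_template(pigment_spec("mel"))
#' max(mel$values)
#' @export
pigment_template <- function(spec, grid = wavelength_grid()) {
  stopifnot(inherits(spec, "pigment_spec"))
  if (spec$lambda_max < grid$start_nm || spec$lambda_max > grid$stop_nm)
    stop(sprintf("lambda_max %g nm lies outside the grid (%g-%g nm)",
                 spec$lambda_max, grid$start_nm, grid$stop_nm))
  wl <- wavelengths(grid)
  v <- exp(-4 * log(2) * ((wl - spec$lambda_max) / spec$half_bandwidth)^2)
  v <- v / max(v)
  spd(v, grid, kind = "sensitivity")
}

#' Crystalline-lens transmittance model
#'
#' Pre-retinal filtering is dominated by the crystalline lens, which absorbs
#' progressively more at shorter wavelengths. `source = "bundled-table"`
#' returns the package's fixed standard-observer-style transmittance curve (a
#' synthetic smooth table shipped with the package, see
#' `inst/extdata/lens_transmittance_synthetic.csv`); `source = "unity"`
#' returns a transparent lens for ablation studies.
#'
#' @param grid A [wavelength_grid()].
#' @param source `"bundled-table"` or `"unity"`.
#' @return An object of class `"lens_model"` with a `transmittance` [spd()]
#'   (values in 0--1) and the `source` tag.
#' @export
lens_model <- function(grid = wavelength_grid(),
                       source = c("bundled-table", "unity")) {
  source <- match.arg(source)
  v <- if (source == "unity") rep(1, grid$n) else bundled_on_grid("lens", grid)
  structure(list(transmittance = spd(v, grid, kind = "sensitivity"),
                 source = source),
            class = "lens_model")
}

#' @export
print.lens_model <- function(x, ...) {
  cat(sprintf("Lens model (%s)\n", x$source))
  invisible(x)
}

#' Corneal spectral sensitivity of a photoreceptor class
#'
#' Pointwise product of a retinal photopigment template and the lens
#' transmittance, re-normalized to peak 1: the sensitivity of the receptor as
#' seen from the cornea. Peak normalization uses the first grid index in the
#' (measure-zero) event of ties.
#'
#' @param template A sensitivity [spd()] from [pigment_template()].
#' @param lens A [lens_model()] on the same grid.
#' @return A sensitivity [spd()] with maximum exactly 1.
#' @export
corneal_sensitivity <- function(template, lens) {
  stopifnot(inherits(template, "spd"), inherits(lens, "lens_model"))
  if (template$kind != "sensitivity")
    stop("template must be a sensitivity-kind spd")
  check_same_grid(template$grid, lens$transmittance$grid,
                  "template and lens")
  v <- template$values * lens$transmittance$values
  m <- max(v)
  if (m <= 0) stop("cannot normalize an all-zero corneal sensitivity")
  spd(v / m, template$grid, kind = "sensitivity")
}

corneal_sensitivities <- function(pigments, lens, grid) {
  lapply(pigments, function(p)
    corneal_sensitivity(pigment_template(p, grid), lens))
}

#' Scotopic and photopic illuminance of a stimulus
#'
#' `scotopic_lux()` is 1700 x the integral of the stimulus weighted by the
#' bundled scotopic luminous-efficiency function V'(lambda) (peak 1 at
#' 507 nm); `photopic_lux()` is 683 x the integral weighted by the photopic
#' V(lambda) (peak 1 at 555 nm). Both are linear in the stimulus. The
#' scotopic measure is the criterion quantity for sensitivity curves because
#' rod signalling is modelled as controlling the ipRGC threshold.
#'
#' @param x An irradiance [spd()].
#' @return Illuminance in (scotopic) lux.
#' @examples
#' scotopic_lux(spd_monochromatic(507, 1))  # 1700
#' @export
scotopic_lux <- function(x) {
  stopifnot(inherits(x, "spd"))
  if (x$kind != "irradiance")
    stop("illuminance is defined for irradiance-kind distributions")
  1700 * band_integral(bundled_on_grid("scotopic", x$grid), x)
}

#' @rdname scotopic_lux
#' @export
photopic_lux <- function(x) {
  stopifnot(inherits(x, "spd"))
  if (x$kind != "irradiance")
    stop("illuminance is defined for irradiance-kind distributions")
  683 * band_integral(bundled_on_grid("photopic", x$grid), x)
}
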