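#' Spectral distribution
#'
#' The universal currency of the package: a vector of nonnegative values on a
#' [wavelength_grid()], tagged either as a stimulus (`"irradiance"`, in
#' W m-2 nm-1) or as a dimensionless `"sensitivity"` function.
#'
#' @param values Numeric vector, one value per grid point; finite and >= 0.
#' @param grid A [wavelength_grid()].
#' @param kind `"irradiance"` or `"sensitivity"`.
#' @param quadrature Integration rule for this distribution: `"trapezoid"`
#'   for continuous spectra, `"rectangle"` (value x step) for line spectra.
#'   See Details.
#'
#' @details A single-bin monochromatic line integrates to half its nominal
#'   power under the trapezoid rule, so generated line spectra carry the
#'   rectangle convention (each bin represents `value * step_nm` of power)
#'   while continuous spectra use the trapezoid rule. [spd_integral()] and
#'   all excitation integrals honour the tag.
#'
#' @return An object of class `"spd"`.
#' @examples
#' g <- wavelength_grid()
#' flat <- spd(rep(1, g$n), g)
#' spd_integral(flat)  # 400 under the trapezoid rule
#' @export
spd <- function(values, grid, kind = c("irradiance", "sensitivity"),
                quadrature = c("trapezoid", "rectangle")) {
  stopifnot(inherits(grid, "wavelength_grid"))
  kind <- match.arg(kind)
  quadrature <- match.arg(quadrature)
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop(sprintf("values has length %d but grid has %d points",
                 length(values), grid$n))
  if (any(!is.finite(values)))
    stop("spectral values must be finite")
  if (any(values < 0))
    stop("spectral values must be nonnegative")
  structure(list(values = values, grid = grid, kind = kind,
                 quadrature = quadrature),
            class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  tot <- spd_integral(x)
  cat(sprintf("Spectral distribution (%s, %s rule): %g-%g nm at %g nm\n",
              x$kind, x$quadrature,
              x$grid$start_nm, x$grid$stop_nm, x$grid$step_nm))
  cat(sprintf("  integral: %.6g%s; peak %.6g at %g nm\n", tot,
              if (x$kind == "irradiance") " W m-2" else "",
              max(x$values), wavelengths(x$grid)[which.max(x$values)]))
  invisible(x)
}

#' Integrate a spectral distribution over wavelength
#'
#' Applies the distribution's own quadrature convention: trapezoid for
#' continuous spectra, rectangle for line spectra.
#'
#' @param x An [spd()].
#' @return The integral, in W m-2 for irradiance inputs.
#' @export
spd_integral <- function(x) {
  stopifnot(inherits(x, "spd"))
  h <- x$grid$step_nm
  v <- x$values
  if (x$quadrature == "rectangle") sum(v) * h
  else (sum(v) - (v[1] + v[length(v)]) / 2) * h
}

# integral of sens(lambda) * E(lambda) d lambda, under the stimulus's rule
band_integral <- function(sens_values, e) {
  h <- e$grid$step_nm
  v <- sens_values * e$values
  if (e$quadrature == "rectangle") sum(v) * h
  else (sum(v) - (v[1] + v[length(v)]) / 2) * h
}

#' Read a spectral power distribution from a delimited text file
#'
#' Reads a two-column (wavelength nm, spectral irradiance W m-2 nm-1) file,
#' comma- or whitespace-delimited, with optional `#` comment lines and an
#' optional non-numeric header row, and linearly interpolates it onto `grid`.
#' Grid points outside the file's wavelength range are zero-filled (with a
#' warning), never extrapolated.
#'
#' @param path Path to the file.
#' @param grid Target [wavelength_grid()].
#' @return An irradiance [spd()] on `grid`.
#' @seealso [write_spd()]
#' @export
read_spd <- function(path, grid = wavelength_grid()) {
  if (!file.exists(path)) stop(sprintf("SPD file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) >= 1) {
    # tolerate a single header row like "wavelength_nm,value"
    first <- strsplit(trimws(lines[1]), "[,;\\s]+", perl = TRUE)[[1]]
    if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[1])))) {
      lines <- lines[-1]
      lineno <- lineno[-1]
    }
  }
  if (length(lines) < 2)
    stop("SPD file must contain at least 2 data rows")
  wl <- numeric(length(lines))
  irr <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[,;\\s]+", perl = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2 || any(is.na(vals[1:2])))
      stop(sprintf("cannot parse SPD file line %d: '%s'", lineno[i], raw[lineno[i]]))
    wl[i] <- vals[1]
    irr[i] <- vals[2]
  }
  if (any(diff(wl) <= 0))
    stop("SPD wavelengths must be strictly increasing")
  if (any(irr < 0))
    stop("negative spectral irradiance in SPD file")
  gw <- wavelengths(grid)
  out <- approx(wl, irr, xout = gw, method = "linear", rule = 1)$y
  oob <- is.na(out)
  if (any(oob)) {
    message(sprintf("read_spd: %d grid points outside file range [%g, %g] nm set to 0",
                    sum(oob), min(wl), max(wl)))
    out[oob] <- 0
  }
  spd(out, grid, kind = "irradiance")
}

#' Write a spectral distribution or sensitivity curve to CSV
#'
#' Writes `#`-prefixed metadata lines, a `wavelength_nm,value` header and one
#' row per grid point, at full precision so a read/write round trip is exact
#' to well beyond 6 significant digits.
#'
#' @param x An [spd()].
#' @param path Output path.
#' @param metadata Optional named character/numeric vector written as
#'   `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_spd <- function(x, path, metadata = NULL) {
  stopifnot(inherits(x, "spd"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s: %s", names(metadata), as.character(metadata)), con)
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%.10g,%.10g", wavelengths(x$grid), x$values), con)
  invisible(path)
}

#' Monochromatic line spectrum
#'
#' A single-wavelength stimulus carrying `power_wm2` of irradiance in one
#' grid bin (bin value `power_wm2 / step_nm`, rectangle quadrature, so the
#' integrated power equals `power_wm2` exactly). Off-grid wavelengths are an
#' error: lines are never silently snapped to the grid.
#'
#' @param lambda_nm Line wavelength, must lie on the grid.
#' @param power_wm2 Total irradiance in W m-2; >= 0.
#' @param grid A [wavelength_grid()].
#' @return An irradiance [spd()].
#' @examples
#' line <- spd_monochromatic(500, 1)
#' spd_integral(line)
#' @export
spd_monochromatic <- function(lambda_nm, power_wm2, grid = wavelength_grid()) {
  stopifnot(is.numeric(power_wm2), length(power_wm2) == 1)
  if (!is.finite(power_wm2) || power_wm2 < 0)
    stop("power_wm2 must be finite and nonnegative")
  i <- grid_index(grid, lambda_nm)
  v <- numeric(grid$n)
  v[i] <- power_wm2 / grid$step_nm
  spd(v, grid, kind = "irradiance", quadrature = "rectangle")
}

#' Blackbody (Planckian) spectrum
#'
#' The Planck spectral radiance shape at temperature `temp_k`, sampled on the
#' grid, peak-normalized and multiplied by `scale` (so `scale` is the peak
#' spectral irradiance in W m-2 nm-1). Used to generate "warm" (low CCT) and
#' "cool" (high CCT) polychromatic white stimuli.
#'
#' @param temp_k Temperature in kelvin; > 0.
#' @param grid A [wavelength_grid()].
#' @param scale Peak spectral irradiance multiplier; >= 0.
#' @return An irradiance [spd()].
#' @export
spd_blackbody <- function(temp_k, grid = wavelength_grid(), scale = 1) {
  stopifnot(is.numeric(temp_k), length(temp_k) == 1)
  if (!is.finite(temp_k) || temp_k <= 0)
    stop("temp_k must be a positive temperature in kelvin")
  if (!is.finite(scale) || scale < 0)
    stop("scale must be finite and nonnegative")
  lam_m <- wavelengths(grid) * 1e-9
  h <- 6.62607015e-34; c0 <- 299792458; kb <- 1.380649e-23
  b <- (2 * h * c0^2) / lam_m^5 / expm1(h * c0 / (lam_m * kb * temp_k))
  if (max(b) > 0) b <- b / max(b)
  spd(b * scale, grid, kind = "irradiance")
}

#' Weighted mixture of spectral distributions
#'
#' Pointwise weighted sum of irradiance spectra on a common grid. If any
#' component carries the rectangle (line-spectrum) quadrature convention the
#' mixture does too, so mixtures of monochromatic lines integrate exactly.
#'
#' @param spds List of irradiance [spd()] objects on the same grid.
#' @param weights Nonnegative multipliers, one per component (default all 1).
#' @return An irradiance [spd()].
#' @examples
#' m <- spd_mix(list(spd_monochromatic(450, 1), spd_monochromatic(570, 1)),
#'              weights = c(2, 3))
#' spd_integral(m)  # 5
#' @export
spd_mix <- function(spds, weights = rep(1, length(spds))) {
  if (!is.list(spds) || length(spds) == 0)
    stop("spds must be a non-empty list of spd objects")
  if (!all(vapply(spds, inherits, logical(1), "spd")))
    stop("spds must be a list of spd objects")
  if (length(weights) != length(spds))
    stop("one weight per component is required")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  g <- spds[[1]]$grid
  for (s in spds) check_same_grid(g, s$grid, "mixture components")
  if (any(vapply(spds, function(s) s$kind, character(1)) != "irradiance"))
    stop("mixtures are defined for irradiance distributions")
  v <- numeric(g$n)
  for (i in seq_along(spds)) v <- v + weights[i] * spds[[i]]$values
  quad <- if (any(vapply(spds, function(s) s$quadrature, character(1)) ==
                 "rectangle")) "rectangle" else "trapezoid"
  spd(v, g, kind = "irradiance", quadrature = quad)
}
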