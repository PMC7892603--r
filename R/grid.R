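#' Wavelength grid
#'
#' A regular wavelength grid on which all spectral quantities in the package
#' live. Every spectral distribution, sensitivity function and bundled table
#' is resampled onto one common grid at entry, so that integrals and
#' pointwise products are always aligned.
#'
#' @param start_nm First wavelength in nm.
#' @param stop_nm Last wavelength in nm; must exceed `start_nm`.
#' @param step_nm Grid spacing in nm; `stop_nm - start_nm` must be an
#'   integer multiple of it.
#'
#' @details The default grid, 380--780 nm at 1 nm, covers the support of all
#'   five photopigment templates and resolves the circuit's spectral
#'   discontinuity near 500 nm.
#'
#' @return An object of class `"wavelength_grid"` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and `n` (number of points).
#' @examples
#' g <- wavelength_grid()
#' g$n
#' head(wavelengths(g))
#' @export
wavelength_grid <- function(start_nm = 380, stop_nm = 780, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm),
            length(start_nm) == 1, length(stop_nm) == 1, length(step_nm) == 1)
  if (!is.finite(start_nm) || !is.finite(stop_nm) || !is.finite(step_nm))
    stop("grid endpoints and step must be finite")
  if (start_nm >= stop_nm)
    stop("start_nm must be smaller than stop_nm")
  if (step_nm <= 0)
    stop("step_nm must be positive")
  k <- (stop_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-8)
    stop("(stop_nm - start_nm) must be an integer multiple of step_nm")
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         n = as.integer(round(k)) + 1L),
    class = "wavelength_grid"
  )
}

#' @rdname wavelength_grid
#' @param grid A `wavelength_grid`.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + grid$step_nm * (seq_len(grid$n) - 1)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("Wavelength grid: %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$start_nm, b$start_nm)) &&
    isTRUE(all.equal(a$stop_nm, b$stop_nm)) &&
    isTRUE(all.equal(a$step_nm, b$step_nm))
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s are on different wavelength grids", what))
  invisible(TRUE)
}

# index of wavelength on the grid, or error: off-grid requests fail loudly
# (silent snapping would corrupt notch localization).
grid_index <- function(grid, lambda_nm) {
  idx <- (lambda_nm - grid$start_nm) / grid$step_nm
  if (idx < -1e-9 || idx > grid$n - 1 + 1e-9)
    stop(sprintf("wavelength %g nm is outside the grid (%g-%g nm)",
                 lambda_nm, grid$start_nm, grid$stop_nm))
  if (abs(idx - round(idx)) > 1e-6)
    stop(sprintf("wavelength %g nm is not on the %g nm grid (no snapping)",
                 lambda_nm, grid$step_nm))
  as.integer(round(idx)) + 1L
}
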