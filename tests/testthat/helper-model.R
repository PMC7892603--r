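# Shared fixtures: the default calibrated model and its sensitivity curves
# are deterministic and moderately expensive, so compute each at most once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(.fixture_cache$model))
    .fixture_cache$model <- circadian_model()
  .fixture_cache$model
}

cached_curve <- function(variant = "full", criterion = 300) {
  key <- sprintf("%s|%g", variant, criterion)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- spectral_sensitivity(default_model(),
                                                  criterion = criterion,
                                                  variant = variant)
  .fixture_cache[[key]]
}

default_sens <- function() default_model()$sensitivities

# independent oracle for corneal sensitivities: Gaussian-in-wavelength
# template times the bundled lens transmittance read straight from the CSV,
# peak-normalized; duplicates the pipeline from its definition, not its code
oracle_corneal <- function(lambda_max, fwhm_nm = 80) {
  wl <- 380:780
  lens <- read.csv(system.file("extdata", "lens_transmittance_synthetic.csv",
                               package = "circphot"), comment.char = "#")
  v <- exp(-4 * log(2) * ((wl - lambda_max) / fwhm_nm)^2) * lens$value
  v / max(v)
}

write_spd_file <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(apply(rows, 1, paste, collapse = ","), path)
  path
}
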