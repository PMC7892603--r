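#' Run configuration
#'
#' A flat set of keys that fully determines every output of the pipeline:
#' the wavelength grid, lens source, photopigment peak overrides, the
#' blue/yellow cross-point, the scotopic criterion level, the calibration
#' target and the output directory. Persisted as a `key = value` text file
#' so runs are reproducible.
#'
#' @param grid_start_nm,grid_stop_nm,grid_step_nm Grid specification, nm.
#' @param lens_source `"bundled-table"` or `"unity"`.
#' @param cross_point_nm Blue/yellow cross-point wavelength, nm.
#' @param criterion_scotopic_lux Criterion light level, scotopic lux.
#' @param target_fwhm_nm Calibration target half-bandwidth, nm.
#' @param out_dir Output directory for CLI commands.
#' @param lambda_max_overrides Named numeric vector of photopigment peak
#'   overrides (see [default_pigments()]), or NULL.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(grid_start_nm = 380, grid_stop_nm = 780,
                       grid_step_nm = 1, lens_source = "bundled-table",
                       cross_point_nm = 500, criterion_scotopic_lux = 300,
                       target_fwhm_nm = 100, out_dir = ".",
                       lambda_max_overrides = NULL) {
  cfg <- list(grid_start_nm = grid_start_nm, grid_stop_nm = grid_stop_nm,
              grid_step_nm = grid_step_nm, lens_source = lens_source,
              cross_point_nm = cross_point_nm,
              criterion_scotopic_lux = criterion_scotopic_lux,
              target_fwhm_nm = target_fwhm_nm, out_dir = out_dir,
              lambda_max_overrides = lambda_max_overrides)
  class(cfg) <- "run_config"
  cfg
}

config_grid <- function(cfg) {
  wavelength_grid(cfg$grid_start_nm, cfg$grid_stop_nm, cfg$grid_step_nm)
}

config_model <- function(cfg, params = NULL) {
  circadian_model(grid = config_grid(cfg),
                  pigments = default_pigments(cfg$lambda_max_overrides),
                  lens = cfg$lens_source,
                  cross_point = cfg$cross_point_nm,
                  criterion = cfg$criterion_scotopic_lux,
                  target_fwhm = cfg$target_fwhm_nm,
                  params = params)
}

#' Read and write flat key/value text files
#'
#' `read_run_config()`/`write_run_config()` persist a [run_config()];
#' `write_params()`/`read_params()` persist calibrated [circuit_params()]
#' together with the cross-point, criterion level and bundled-table
#' identifiers, so a stored calibration fully determines later outputs.
#' Rewriting the same values produces byte-identical files.
#'
#' @param path File path.
#' @return `read_run_config()` a [run_config()]; `read_params()` a list
#'   with `params` ([circuit_params()]) and the stored metadata.
#' @export
read_run_config <- function(path) {
  kv <- read_keyvalues(path)
  cfg <- run_config()
  for (nm in setdiff(names(cfg), "lambda_max_overrides")) {
    if (!is.null(kv[[nm]])) {
      cfg[[nm]] <- if (is.character(cfg[[nm]])) kv[[nm]] else as.numeric(kv[[nm]])
    }
  }
  ov <- kv[grepl("^lambda_max_", names(kv))]
  if (length(ov)) {
    names(ov) <- sub("^lambda_max_", "", names(ov))
    cfg$lambda_max_overrides <- vapply(ov, as.numeric, numeric(1))
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg A [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- c("# circphot run configuration")
  for (nm in setdiff(names(cfg), "lambda_max_overrides")) {
    v <- cfg[[nm]]
    lines <- c(lines, sprintf("%s = %s", nm,
                              if (is.numeric(v)) sprintf("%.10g", v) else v))
  }
  ov <- cfg$lambda_max_overrides
  if (!is.null(ov))
    lines <- c(lines, sprintf("lambda_max_%s = %.10g", names(ov), ov))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_run_config
#' @param params A [circuit_params()].
#' @param cross_point_nm,criterion_scotopic_lux Metadata stored alongside.
#' @export
write_params <- function(params, path, cross_point_nm = 500,
                         criterion_scotopic_lux = 300) {
  stopifnot(inherits(params, "circuit_params"))
  lines <- c(
    "# circphot calibrated circuit parameters",
    sprintf("%s = %.12g", names(params), unlist(params)),
    sprintf("cross_point_nm = %.10g", cross_point_nm),
    sprintf("criterion_scotopic_lux = %.10g", criterion_scotopic_lux),
    "scotopic_table = scotopic_luminous_efficiency.csv",
    "photopic_table = photopic_luminous_efficiency.csv",
    "lens_table = lens_transmittance_synthetic.csv"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
read_params <- function(path) {
  kv <- read_keyvalues(path)
  need <- c("k", "a1", "a2", "a3", "rod_sat")
  if (!all(need %in% names(kv)))
    stop("parameter file is missing: ", paste(setdiff(need, names(kv)), collapse = ", "))
  num <- function(nm, default = NA_real_)
    if (is.null(kv[[nm]])) default else as.numeric(kv[[nm]])
  list(params = circuit_params(num("k"), num("a1"), num("a2"), num("a3"),
                               num("rod_sat")),
       cross_point_nm = num("cross_point_nm", 500),
       criterion_scotopic_lux = num("criterion_scotopic_lux", 300))
}

read_keyvalues <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  kv <- list()
  for (ln in raw) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop(sprintf("cannot parse config line: '%s'", ln))
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  kv
}
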