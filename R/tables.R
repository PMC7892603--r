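# Bundled photometric tables (inst/extdata), cached per (table, grid).

.table_cache <- new.env(parent = emptyenv())

table_file <- function(name) {
  fn <- switch(name,
    scotopic = "scotopic_luminous_efficiency.csv",
    photopic = "photopic_luminous_efficiency.csv",
    lens = "lens_transmittance_synthetic.csv",
    stop(sprintf("unknown bundled table '%s'", name))
  )
  path <- system.file("extdata", fn, package = "circphot")
  if (!nzchar(path)) stop(sprintf("bundled table %s not found", fn))
  path
}

read_bundled_table <- function(name) {
  d <- utils::read.csv(table_file(name), comment.char = "#")
  list(wl = d[[1]], value = d[[2]])
}

# Resample a bundled table onto a grid. Outside the tabulated range the
# luminous-efficiency tables fall to zero while the lens transmittance holds
# its end values (it is ~0 deep in the UV only below our grids, and 1 in the
# IR).
bundled_on_grid <- function(name, grid) {
  key <- sprintf("%s|%g|%g|%g", name, grid$start_nm, grid$stop_nm, grid$step_nm)
  if (!is.null(.table_cache[[key]])) return(.table_cache[[key]])
  tb <- read_bundled_table(name)
  rule <- if (name == "lens") 2 else 1
  v <- approx(tb$wl, tb$value, xout = wavelengths(grid),
              method = "linear", rule = rule)$y
  v[is.na(v)] <- 0
  v <- pmin(pmax(v, 0), 1)
  .table_cache[[key]] <- v
  v
}
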