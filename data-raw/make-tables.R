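# Regenerates the bundled photometric tables in inst/extdata/.
# Run from the package root: Rscript data-raw/make-tables.R
#
# Scotopic V'(lambda): CIE 1951 scotopic luminous-efficiency values at 5 nm,
# with the defined unit peak at 507 nm included as an anchor.
# Photopic V(lambda): CIE 1924 photopic luminous-efficiency values at 5 nm.
# Both are interpolated to 1 nm with a monotone Hermite spline (no overshoot,
# so the tabulated peaks remain the global maxima).
#
# Lens transmittance: a synthetic standard-observer-style curve. Optical
# density anchors are hand-set to follow the qualitative shape of published
# young-adult crystalline-lens density data (steeply rising below 450 nm,
# negligible beyond 650 nm); transmittance = 10^(-density). It is a
# package-constructed stand-in, not a copy of any published table, hence the
# "synthetic" filename.

grid_nm <- 380:780

mono_interp <- function(wl, val, out) {
  f <- splinefun(wl, val, method = "monoH.FC")
  v <- f(out)
  pmin(pmax(v, 0), 1)
}

vprime_wl <- c(seq(380, 505, 5), 507, seq(510, 780, 5))
vprime_val <- c(
  0.000589, 0.001108, 0.002209, 0.00453, 0.00929, 0.01852, 0.03484,
  0.0604, 0.0966, 0.1436, 0.1998, 0.2625, 0.3281, 0.3931, 0.455,
  0.513, 0.567, 0.620, 0.676, 0.734, 0.793, 0.851, 0.904, 0.949,
  0.982, 0.998,
  1.000,
  0.997, 0.975, 0.935, 0.880, 0.811, 0.733, 0.650, 0.564, 0.481,
  0.402, 0.3288, 0.2639, 0.2076, 0.1602, 0.1212, 0.0899, 0.0655,
  0.0469, 0.03315, 0.02312, 0.01593, 0.01088, 0.00737, 0.00497,
  0.003335, 0.002235, 0.001497, 0.001005, 0.000677, 0.000459,
  0.0003129, 0.0002146, 0.0001480, 0.0001026, 0.0000715, 0.0000501,
  0.0000353, 0.0000250, 0.0000178, 0.0000127, 0.00000914, 0.00000660,
  0.00000478, 0.00000348, 0.00000254, 0.00000186, 0.00000137,
  0.00000101, 0.00000075, 0.00000056, 0.00000042, 0.00000031,
  0.00000023, 0.00000018, 0.00000014
)
stopifnot(length(vprime_wl) == length(vprime_val))

v_wl <- seq(380, 780, 5)
v_val <- c(
  0.0000390, 0.0000640, 0.000120, 0.000217, 0.000396, 0.000640,
  0.00121, 0.00218, 0.00400, 0.00730, 0.0116, 0.01684, 0.023,
  0.0298, 0.038, 0.048, 0.060, 0.0739, 0.09098, 0.1126, 0.13902,
  0.1693, 0.20802, 0.2586, 0.323, 0.4073, 0.503, 0.6082, 0.710,
  0.7932, 0.862, 0.91485, 0.954, 0.9803, 0.99495, 1.0000, 0.995,
  0.9786, 0.952, 0.9154, 0.870, 0.8163, 0.757, 0.6949, 0.631,
  0.5668, 0.503, 0.4412, 0.381, 0.321, 0.265, 0.217, 0.175, 0.1382,
  0.107, 0.0816, 0.061, 0.04458, 0.032, 0.0232, 0.017, 0.01192,
  0.00821, 0.005723, 0.004102, 0.002929, 0.002091, 0.001484,
  0.001047, 0.00074, 0.00052, 0.000361, 0.000249, 0.000172, 0.00012,
  0.0000848, 0.0000600, 0.0000424, 0.0000300, 0.0000212, 0.0000149
)
stopifnot(length(v_wl) == length(v_val))

lens_wl <- c(
  380, 390, 400, 410, 420, 430, 440, 450, 460, 470, 480, 490, 500,
  510, 520, 530, 540, 550, 560, 570, 580, 590, 600, 620, 640, 660,
  680, 700, 720, 740, 760, 780
)
lens_density <- c(
  2.00, 1.45, 1.00, 0.73, 0.55, 0.42, 0.33, 0.26, 0.21, 0.17, 0.14,
  0.12, 0.10, 0.085, 0.070, 0.060, 0.050, 0.042, 0.036, 0.030,
  0.026, 0.022, 0.019, 0.013, 0.009, 0.006, 0.004, 0.003, 0.002,
  0.001, 0.0005, 0.0
)
stopifnot(length(lens_wl) == length(lens_density))

dens_f <- splinefun(lens_wl, lens_density, method = "monoH.FC")
lens_t <- 10^(-pmax(dens_f(grid_nm), 0))

write_table <- function(path, values, header) {
  con <- file(path, "w")
  writeLines(header, con)
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%d,%.7g", grid_nm, values), con)
  close(con)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_table(
  "inst/extdata/scotopic_luminous_efficiency.csv",
  mono_interp(vprime_wl, vprime_val, grid_nm),
  c("# CIE 1951 scotopic luminous efficiency V'(lambda), peak 1 at 507 nm,",
    "# interpolated to 1 nm by monotone Hermite spline from the 5 nm table.")
)
write_table(
  "inst/extdata/photopic_luminous_efficiency.csv",
  mono_interp(v_wl, v_val, grid_nm),
  c("# CIE 1924 photopic luminous efficiency V(lambda), peak 1 at 555 nm,",
    "# interpolated to 1 nm by monotone Hermite spline from the 5 nm table.")
)
write_table(
  "inst/extdata/lens_transmittance_synthetic.csv",
  lens_t,
  c("# Synthetic standard-observer-style crystalline lens transmittance.",
    "# Constructed from hand-set optical-density anchors (monotone Hermite",
    "# interpolation); transmittance = 10^(-density). Not a published table.")
)
cat("wrote 3 tables,", length(grid_nm), "rows each\n")
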