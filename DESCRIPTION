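Package: circphot
Title: Retinal Circuit Model of Human Circadian Phototransduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Spectral computation for the revised retinal circuit model of
    human circadian phototransduction. From any corneal spectral irradiance
    distribution the package computes photoreceptor excitations for the five
    human photopigments (rhodopsin, melanopsin and the L/M/S cone opsins)
    behind crystalline-lens filtering, the spectrally opponent blue-yellow
    channel of the S-cone bipolar, rod shunting inhibition of the M1
    intrinsically photosensitive retinal ganglion cell with cone release and
    its dopaminergic-amacrine decoupling for "warm" stimuli, and the
    resulting circadian drive to the suprachiasmatic nuclei. Includes
    deterministic gain calibration, prediction of the monochromatic
    spectral-sensitivity function with its discontinuity ("notch") near
    500 nm, subadditivity diagnostics for polychromatic light, synthetic
    spectrum generators, scotopic/photopic photometry with bundled
    luminous-efficiency tables, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
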