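Package: edogsim
Title: Extended Difference-of-Gaussians Model of the dLGN Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate simulator of the early visual pathway built on the
    extended difference-of-Gaussians (eDOG) model of the dorsal lateral
    geniculate nucleus (dLGN). Retinal input, feedforward inhibition via
    intrageniculate interneurons, and phase-reversed excitatory, inhibitory or
    mixed corticothalamic feedback are combined into a closed-form Fourier
    domain transfer function for relay cells, so that responses to arbitrary
    visual stimuli (drifting gratings, patch gratings, spots, flashing spots,
    grayscale movies) follow from fast Fourier transforms.  Ships the standard
    battery of spatial and temporal response measures: receptive-field
    geometry, area-summation curves and suppression index, spatial and
    temporal frequency tuning, biphasic index and peak latency, response maps
    for natural images, and temporal decorrelation of naturalistic movies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
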