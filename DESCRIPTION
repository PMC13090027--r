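Package: suntagr
Title: Single-mRNA Translation Kinetics from SunTag Run-Off Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse single-molecule SunTag translation
    imaging experiments. Provides an exact event-driven (Gillespie) simulator
    of the l-TASEP model of ribosome traffic with optional two-state bursty
    initiation, a nascent-chain fluorescence signal model with lognormal
    acquisition noise, closed-form low-density results (ribosome current,
    density, run-off correction factors), a hidden Markov model that infers
    initiation and elongation rates from harringtonine run-off intensity
    traces and decodes the number of translating ribosomes per trace, trace
    preprocessing (despiking, filtering, burst segmentation, empirical density
    estimates), and Bayesian quantification of diffraction-limited spot
    intensities in image patches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
NeedsCompilation: yes
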