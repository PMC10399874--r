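Package: fluctr
Title: Number & Brightness and Scanning FCS Analysis of Photon-Count Fluctuations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fluorescence fluctuation spectroscopy toolkit for confocal
    photon-counting data: pixel-wise Number & Brightness (N&B) moment
    analysis with detector-saturation masking and boxcar photobleaching
    correction, scanning fluorescence correlation spectroscopy (sFCS) of
    membrane line scans with multi-tau autocorrelation and 2D Brownian
    diffusion fits, point-FCS calibration of the confocal detection volume
    with a 3D diffusion plus triplet model, and estimation of the apparent
    fluorescence probability (pf) of fluorescent proteins from monomer and
    tandem-dimer brightness. Includes Brownian-dynamics simulators of
    photon-count image stacks, membrane line-scan kymographs, and point
    detection traces, so every stage of the pipeline can be validated
    against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
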