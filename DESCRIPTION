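Package: ppsftools
Title: Axial Precision of Two-Photon Optogenetic Photostimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the axial physiological point spread function (PPSF)
    of two-photon optogenetic photostimulation from calcium-imaging data.
    Provides bead z-stack analysis for the optical point spread function
    (OPSF; Gaussian fits, FWHM summaries), a trial-based dF/F response
    pipeline turning movies, synchronization traces and ROI masks into
    per-neuron axial response curves and group FWHM at half prominence, a
    convolution model predicting PPSF FWHM from cell diameter and OPSF,
    and a synthetic-data generator (bead stacks, photostimulation movies,
    response curves) with known ground truth so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
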