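Package: evraman
Title: Size-Exclusion Routing and Self-Organizing-Map Classification of
    Extracellular-Vesicle Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for label-free extracellular-vesicle (EV)
    diagnostics from Raman spectra. Simulates fingerprint-region (700-1700 1/cm)
    EV spectra and particle size populations, models a five-membrane
    size-exclusion cascade with a separation-efficiency statistic, cleans and
    normalizes spectra (cosmic-ray despiking, iterative polynomial baseline
    subtraction, replicate averaging, standard normal variate), classifies EV
    subgroups and disease state with a supervised self-organizing map carrying
    per-neuron class-label weights (SKiNET) and its discriminant index (SOMDI),
    derives binary spectral barcodes from thresholded Savitzky-Golay second
    derivatives, and evaluates diagnostic performance with confusion-matrix
    metrics, Mann-Whitney rank tests and ROC/AUC curves with Hanley-McNeil
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    withr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
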