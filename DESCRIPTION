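Package: gcimpurity
Title: Quantification of Trace Odorant Impurities from GC-Coupled Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying trace impurities in odorant
    samples from gas-chromatography-coupled calcium imaging of olfactory
    receptor neurons. Provides bleach-corrected dF/F trace processing
    (exponential decay fit with response masking), chromatogram and imaging
    channel peak detection and alignment, sigmoidal logistic dose-response
    (EC50) calibration on a log10-dilution axis, and inverse read-off of
    contaminant concentration in ppm. A synthetic-data module simulates
    GC-FID chromatograms and receptor fluorescence traces with known ground
    truth so that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
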