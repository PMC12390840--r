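Package: feocproxy
Title: Iron Oxide Co-Precipitated Organic Carbon as a Proxy for Marine
    Dissolved Organic Carbon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for calibrating and inverting the iron (oxyhydr)oxide
    co-precipitated organic carbon (Fe-OC) proxy for marine dissolved
    organic carbon (DOC). Fits Freundlich loading isotherms and
    dual-exponential carbon-isotope offset curves to co-precipitation
    experiments, inverts geologic iron-ooid Fe-OC loadings and delta13C
    values to relative DOC concentration ([DOC]*) and delta13C_DOC by
    Monte Carlo under end-member mixing scenarios, computes DOC optical
    metrics (spectral slopes, slope ratio, SUVA254, fluorescence index,
    FDOM), maps Fe-OC in Raman line scans and images by G-band ratio
    thresholding, and provides record binning, group comparison,
    radiocarbon age conversion and schema-validated table I/O. A
    synthetic-data generator with known ground truth supports end-to-end
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
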