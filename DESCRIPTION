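Package: chromatophore
Title: Quantitative Analysis of Squid Chromatophore Proteomics and Structural Color
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the quantitative analyses behind
    cephalopod chromatophore structural-color studies. Implements in-silico
    tryptic digestion and expected-peptide counting, peptide-scaled
    spectral-count protein quantitation with loading normalization and
    contaminant filtering, identification and annotation acceptance filters
    for search-engine and BLAST tabular output, transfer-matrix thin-film
    interference modeling of sheath-cell multilayers with expansion-driven
    color shifts and sRGB rendering, Lorentzian broadening of excited-state
    line lists into pigment absorption spectra with two-state pH-titration
    fitting, and region-of-interest RGB time-series extraction from movie
    frame stacks. A synthetic-data generator produces inputs with the
    statistical structure each stage assumes, so the full pipeline is
    testable without raw data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    Biostrings,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    tiff
Config/testthat/edition: 3
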