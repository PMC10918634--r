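Package: zoomsid
Title: Automated Taxonomic Identification of Collagen Peptide Mass Fingerprints (ZooMS)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for Zooarchaeology by Mass Spectrometry (ZooMS):
    reads raw MALDI-ToF bone-collagen spectra (mzML or two-column text),
    preprocesses technical replicates (Savitzky-Golay smoothing, SNIP
    baseline removal, total-ion-current calibration, noise estimation,
    peak detection, monoisotopic de-isotoping, replicate quality control
    and averaging), and ranks candidate taxa by correlating detected
    peptide-marker peaks against geographically partitioned reference
    databases.  Includes contaminant scanning, fail logic, evaluation
    statistics against manual identifications (confusion matrices,
    weighted accuracies, t-tests on correlation scores), and a seeded
    synthetic-spectrum generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    mzR,
    base64enc,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
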