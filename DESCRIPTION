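Package: ms2deconv
Title: Chimeric MS2 Spectrum Deconvolution and Spectral Library Search
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tandem mass-spectrometry spectral processing for untargeted
    metabolomics. Deconvolves chimeric data-dependent-acquisition (DDA) MS2
    spectra with an auto-tuned penalized elastic-net regression over candidate
    component spectra (predicted orphan-isotopologue spectra, clean in-data
    spectra, reference-library spectra, and transformation-network predicted
    spectra), reconstructs pseudo-MS2 spectra from SWATH-DIA cycles by
    extracted-ion-chromatogram clustering and decomposition, collapses
    replicate spectra into consensus spectra with frequency-based and
    database-assisted fragment retention, scores spectra against SQLite
    reference libraries with a composite matching score combining MS2, MS1,
    retention-time and isotope-pattern similarity, performs neutral-loss
    fallback searching via one-hop biotransformation networks, evaluates
    false-positive behaviour with decoy acquisitions, and filters
    empirical-compound candidate lists with MS2 identifications for
    pathway-level enrichment. Includes seeded synthetic-data generators for
    reference libraries, DDA and SWATH-DIA runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    DBI,
    RSQLite,
    signal,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
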