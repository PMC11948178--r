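Package: adcbiotx
Title: Antibody-Drug Conjugate Biotransformation Analysis from Intact Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open workflow for characterising antibody-drug conjugate (ADC)
    biotransformation from intact LC-MS data. Builds a linker-payload
    delta-mass library by constrained bond-cleavage enumeration on the
    molecular graph, computes theoretical antibody-chain proteoform masses
    (drug load, glycans, cysteinylation, thiosuccinimide hydrolysis),
    deconvolutes multiply charged electrospray spectra to neutral masses by
    charge-envelope summation, annotates peaks against the candidate space
    within a mass tolerance, and quantifies fractional abundances over
    pharmacokinetic time courses. Includes a synthetic-data generator for
    structures, sequences, kinetics and raw-style spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    ChemmineR,
    Biostrings,
    stats,
    utils
Suggests:
    mzR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
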