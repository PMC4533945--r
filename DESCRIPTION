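Package: simcquant
Title: Quantification of Isobaric Peptide Isoforms by Specific Fragment-Ion
    Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free bottom-up mass-spectrometry quantification of
    isobarically modified peptide isoforms, such as the pentamethylated
    histone H3 K27-R40 pair (K27me3-K36me2 versus K27me2-K36me3). Computes
    monoisotopic peptide and b/y fragment-ion masses, discovers the
    isoform-specific fragment ions that discriminate positional isomers,
    performs in-silico tryptic digestion with methylation-dependent cleavage
    blocking, reads and writes mzML and MGF runs, sums matched specific-ion
    intensities across MS/MS scans into per-isoform chromatograms (SIMC) to
    obtain constituent percentages, and combines them with MS1 selected-ion
    chromatograms (SIC) normalized to a constitutive peptide for relative
    abundances. Includes a seeded simulator of coeluting isobaric LC-MS/MS
    runs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
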