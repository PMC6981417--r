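Package: gangliotools
Title: Compositional Annotation and O-Acetylation Analysis of Ganglioside
    MALDI Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling O-acetylated gangliosides from negative-mode
    MALDI-QIT-TOF spectra of acidic glycosphingolipid extracts. Builds
    theoretical monoisotopic ion libraries for the 0/a/b/c ganglioside series
    with ceramide heterogeneity, sialo-lactonization and O-acetyl adducts;
    annotates MS1 peak lists with explicit isobar groups; predicts glycosidic
    B/C/Y/Z fragment ions and localizes the O-acetylated sialic acid from
    MS/MS spectra; computes per-sample relative ganglioside abundances; and
    maps differential abundance and glycosyltransferase qPCR expression onto
    the ganglioside biosynthesis pathway graph. Includes seeded simulators
    for MS1 spectra, fragment spectra and qPCR Ct tables so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    grDevices,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
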