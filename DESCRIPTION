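Package: proppinkit
Title: Membrane-Binding Kinetics, Cross-Link Matching and Native-MS
    Deconvolution for PROPPIN-Family Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for three complementary analyses of peripheral
    membrane-protein binding and oligomerization, exemplified by the
    PROPPIN family beta-propeller Atg18. Simulates and fits stopped-flow
    FRET membrane-binding time courses under a two-step
    binding/oligomerization scheme and extracts association and apparent
    dissociation rate constants by pseudo-first-order analysis;
    enumerates tryptic peptides and their BS3 lipid-adduct and
    di-peptide cross-link masses and matches them to observed precursor
    masses at ppm tolerance; assigns native-ESI charge-state series to
    oligomer orders and reports oligomer masses and relative
    intensities. Ground-truthed synthetic-data generators make every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    Biostrings,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    deSolve,
    optparse,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
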