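Package: allohex
Title: Subgenome Integrity Analysis for Recurrent Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing the integrity of progenitor subgenomes in
    allopolyploid species. Implements depth-window detection of homeologous
    exchange (HE) against concatenated progenitor reference genomes,
    including quantification of the reference-mismatch false-positive
    effect; syntenic collinearity block chaining and coordinate liftover;
    Nei-Gojobori (NG86) Ka/Ks estimation with Ks-peak divergence dating;
    zero-Ks closeness testing over quadruple ortho-homeologous gene chains;
    homeolog expression bias (HEB) classification across tissues and
    conditions; transposable-element density association tests; and a
    seeded simulator that generates every pipeline input together with a
    ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
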