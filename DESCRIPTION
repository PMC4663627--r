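Package: srnaduplex
Title: Small RNA Duplex Discovery and p19 Capture Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of miRNA/miRNA* duplex pairs in collapsed small-RNA
    read libraries using four pairing criteria (read count, 2-nt 3' overhangs,
    at most three mismatches, G:U wobble permitted), mapping of called pairs to
    pre-miRNA hairpin stems with a wobble-aware base-pair-maximisation folder,
    read-count spectrum and strand-balance statistics for input versus
    p19-enriched libraries, Langmuir-isotherm dissociation-constant estimation
    with relative affinities, Debye-Hueckel screening-length calculations for
    measurement buffers, and a seeded synthetic-data generator that simulates
    p19 sequestration of duplexes so the whole pipeline is testable end to end.
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
    minpack.lm,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
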