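Package: igkit
Title: Immunoglobulin Domain Numbering, Junction Decomposition and
    Repertoire Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for standardized immunoglobulin sequence analysis built
    on the IMGT unique numbering. Numbers V and C domains (gap insertion,
    FR/CDR delimitation, hallmark verification, identity percentages), lays
    out and renders Collier de Perles plots, decomposes V-(D)-J junctions
    into germline, P and N segments, identifies clonotypes from AIRR-style
    rearrangement tables with diversity/expression statistics and
    multiple-testing-adjusted set comparison, infers Gm/Km/lambda allotype
    markers and engineered-variant names from constant-domain residues, and
    queries packaged human IG locus gene tables. A seeded simulator
    generates toy germline sets and ground-truth-annotated repertoires for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
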