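Package: topohic
Title: Topological Feature Extraction and Multi-View Subgroup Discovery
    from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Topohic", "Developers", email = "topohic@example.org",
           role = c("aut", "cre"))
Description: Extracts A/B compartments, contact domains (TADs), insulation
    boundary scores, and focal chromatin loops from binned Hi-C contact
    matrices; discriminates tumor subgroups from those features with
    similarity network fusion and consensus non-negative matrix
    factorization; tests boundaries for subgroup differences and associates
    them with differential gene expression; and scans contact maps for
    copy-number segments and structural-variant "butterfly" signatures.
    Ships a synthetic-cohort generator with planted ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
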