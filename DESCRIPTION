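Package: funmapper
Title: Functional Potential Inference and Analysis for 16S Microbial Community Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers functional-unit and metabolic-pathway abundance profiles of
    microbial communities from 16S-derived taxonomic abundance matrices using
    genome-function copy-number maps, under either a co-metabolism or an
    independent-contributions community assumption.  Provides 16S copy-number
    correction, cross-mapping between functional-unit namespaces (EC, KO, COG,
    Pfam, TIGRfam), pathway quorum filtering over a sweep of exclusion
    cut-offs, top/core/differentiating function analytics with nonparametric
    tests and Benjamini-Hochberg correction, Jensen-Shannon-divergence
    ordination, function-driven taxa co-contribution networks, single-pathway
    enzyme drill-down with KEGG Mapper colour-file export, and a synthetic
    genome-function database generator for fully reproducible testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
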