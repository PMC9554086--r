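Package: CAITscan
Title: Discovery and Quantification of Semi-Invariant T Cell Clonotypes in
    Bulk and Paired Single-Cell TCR Repertoires
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying disease-associated semi-invariant T cell
    receptor (TCR) clonotypes from bulk AIRR-format repertoires and paired
    single-cell contig tables. Implements family-level (V gene, J gene, CDR3
    length) enrichment scanning between cohorts, per-sequence Fisher presence
    testing, position-frequency-matrix based CDR3 consensus motif derivation,
    rule-based classification of invariant T cells (MAIT, iNKT and
    Crohn-associated invariant T clonotypes), per-individual cumulative
    abundance statistics with cohort comparisons, cross-tissue clonotype
    tracking and sharing networks, paired alpha/beta chain analysis, and a
    reproducible synthetic repertoire generator with planted semi-invariant
    clonotypes for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
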