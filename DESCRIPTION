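Package: scrapseek
Title: Cross-Reactivity Scoring and Antigen Prioritization for Peptide-Centric Immunotherapies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for MHC class I immunopeptidomics antigen discovery and
    receptor-safety screening. Implements a positional cross-reactivity score
    that compares a query tumour peptide-MHC against every same-length window
    of the normal proteome (scoring 5 for identity, 2 for shared chemical
    class, -2 otherwise, with MHC anchor positions masked), combines it with
    predicted binding affinity and maximum normal-tissue expression into an
    overall risk score, and emits ranked cross-reactivity reports. Also
    provides the antigen-discovery funnel (binding-affinity filter,
    per-tissue differential expression, benign-ligandome exclusion),
    candidate prioritization, cross-HLA presentation scans, MS1 matched-peptide
    searching, alanine-scan contact-residue calling, and deterministic
    synthetic-data generators with planted ground truth so the whole pipeline
    is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
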