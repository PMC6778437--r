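Package: TaxaMapR
Title: Clade-Based Taxonomic Assignment and Bootstrap-Weighted Proteome
    Profiling from Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for placing a query proteome taxonomically from large sets
    of per-protein gene trees. Implements TaxaMap-style clade assignment
    (ancestral walk to the smallest bootstrap-supported clade containing a
    non-query homologue, with root fallback), mapping of clade species codes
    onto six taxonomic ranks with unknown-taxon labels, and combination of
    per-protein assignments into proteome-level profiles by unweighted and
    bootstrap-weighted scoring with iterative exclusion of low-scoring taxa.
    Also provides gene-tree curation (midpoint rooting, paralogous-subfamily
    detection, in-paralogue filtering), global pairwise identity utilities
    (non-redundant sequence reduction keeping the longer representative,
    multi-copy consensus and identity statistics), and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    phangorn,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
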