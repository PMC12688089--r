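Package: DomainScope
Title: Domain Parsing of Predicted Protein Structures and Comparison of
    Domain Segmentations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for placing structure-based candidate novel-fold domains
    in an evolutionary context. Implements PAE- and distance-based parsing of
    predicted protein models into (possibly discontinuous) domains, a
    four-way quality classification of domain-to-reference assignments
    (well-assigned, unassigned, simple-topology, partial), dual
    overlap-fraction comparison of two independent domain segmentations of
    the same proteins, and full summary-statistics reporting. Includes a
    synthetic ground-truth generator (block-structured PAE, disordered tails
    and linkers, co-alignment support, perturbed alternative segmentations,
    mock assignment metadata) so that every pipeline stage is testable
    without large-scale downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
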