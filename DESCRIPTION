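Package: remort
Title: Remote Orthology Detection from Relaxed Similarity Searches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects remotely conserved orthologs of a query protein from
    relaxed (high E-value) local-alignment searches. Pairwise alignments are
    binarized into per-query-position conservation profiles, clustered by a
    consensus-based modification of average-linkage hierarchical clustering,
    and the dendrogram is cut where the climbing rate of an exponential fit
    to the merge-height distribution turns from flat to steep. Orthology
    candidates are then verified by iterative reciprocal best-hit searches
    with per-species rank rules and a rejection vote, and the verified set is
    scored E-value-independently by edge-weighted eigenvector centrality on a
    typed orthology network. Includes an internal Smith-Waterman search
    backend, a BLAST+ adapter, a canned-results fixture backend, and a
    seeded generator of synthetic protein families with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
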