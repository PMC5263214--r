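Package: pgmmap
Title: Linkage Map Construction with Probabilistic Graphical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs genetic linkage maps from doubled-haploid and RIL
    marker data using probabilistic graphical models. Learns an
    order-independent conditional-independence skeleton over markers
    (PC-stable with Fisher-z tests on the marker correlation matrix),
    extracts a linear marker order by frequentist diagonal ordering of the
    adjacency matrix, and assembles centiMorgan maps with Haldane distances,
    flagging error-laden markers that are pulled aside from the main marker
    string. Includes an exact closed-form layer for ordered marker triplets
    (genotypic frequencies, pairwise and partial correlations, observed
    recombination frequencies, nearest-neighbour stress) under locus-specific
    genotyping error, a doubled-haploid population simulator under Haldane
    meiosis with genotyping errors, missing data and reciprocal-translocation
    scenarios, and preprocessing utilities (missing-data filters,
    heterozygote masking, duplicate-marker collapsing, linkage grouping by
    recombination-frequency threshold, k-medoids representative selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
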