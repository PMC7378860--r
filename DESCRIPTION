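Package: coevotrace
Title: Reconstructing Host-Parasite RNA Coevolution from Serial-Transfer Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing antagonistic coevolution of a self-replicating
    host RNA and its parasitic deletion mutants across a serial-transfer
    replication experiment. Reads of four RNA length classes (a ~2040 nt host
    and three parasite classes of ~220, ~1070 and ~510 nt) are classified by
    size, filtered by circular-consensus pass count, globally aligned to class
    references with an affine-gap aligner, and reduced to mutation events in
    host reference coordinates. Per-round mutation frequency tables yield the
    dominant mutations (population frequency above 10 percent in at least one
    sequenced round), reads are projected onto genotypes over the dominant
    sites, and the genotype cloud is embedded with principal coordinate
    analysis of the squared-Hamming distance matrix. Hamming-1 networks within
    a class and deletion-masked zero-distance links across classes expose
    lineage structure and parasite generation events; parasite-unique mutations
    and mutation persistence are tracked across rounds. A serial-transfer
    coevolution simulator with exact ground truth (droplet Poisson occupancy,
    length-dependent replication, per-base mutation, large internal deletions,
    five-fold dilution and multinomial read sampling) supports validation of
    every stage by parameter and structure recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
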