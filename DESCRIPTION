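Package: ctcfCycle
Title: Cell-Cycle Phase-Specific Analysis of CTCF Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to partition ChIP-seq peak sets of an insulator protein
    (such as Drosophila CTCF) into interphase-mitosis-common (IM),
    interphase-only (IO) and mitosis-only (MO) classes and to characterize
    each class: genomic category relative to gene models, cross-species
    conservation through chain-file lift-over with observed/expected ratios,
    two-part motif occurrence by position weight matrix scanning, GC content,
    binding-intensity meta-profiles around peak summits, nearest-same-class
    spacing against chromosome-shuffled nulls, and enrichment and
    minimum-domain-number spacing at topological and syntenic domain
    boundaries. Includes a synthetic-data generator that emulates every input
    with controllable planted structure, and a pipeline runner with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    withr,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
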