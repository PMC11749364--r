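Package: editomics
Title: RNA Editome Discovery, Differential Editing and Co-Editing Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection of A-to-I (read out as A-to-G) RNA editing sites from
    read-level RNA and genomic DNA evidence via a configurable filter cascade
    with distinct handling of Alu and non-Alu regions; annotation of the
    resulting editome against gene models with substitution-spectrum,
    level-distribution and region-enrichment summaries; differential editing
    between cell types using replicate concordance (Fisher's exact test), an
    exact conditional rate test on pooled counts and a fold-change gate, plus
    a rank-sum confirmation analysis on larger sample sets; classification of
    microRNA target gain and loss at edited 3'UTR positions with a two-phase
    complementarity-then-energy scanner; and weighted co-editing network
    construction with topological overlap, average-linkage module detection,
    module eigen-profiles, membership and hub calling. A synthetic-data
    generator with planted ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    methods,
    stats,
    utils,
    tools,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
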