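Package: rdnsv
Title: Relative Density of Nonsynonymous Variants in Gene Sets
Version: 0.1.0
Authors@R:
    person("rdnsv", "developers", email = "rdnsv@example.org", role = c("aut", "cre"))
Description: Estimates the relative density of nonsynonymous single-nucleotide
    variants (rdnsv) in sets of protein-coding genes, compared with the neutral
    expectation inferred from synonymous variants. Counts synonymous and
    nonsynonymous mutational opportunities ("sites") in coding sequences,
    partitioned into transition and transversion opportunities, and corrects
    the nsSNV/sSNV density ratio for the genetic code's enrichment of
    transitions among synonymous changes. Models the change of rdnsv over the
    derived allele frequency spectrum with a log-frequency linear regression,
    separating the proportion of mutation-intolerant nonsynonymous sites
    (intercept) from ongoing purifying selection on segregating variants
    (slope). Includes permutation tests and random-gene-set background
    envelopes for comparing gene categories, tissue-specific gene-set
    selection from expression matrices, and a selection-aware exome SNV
    simulator for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
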