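Package: gamcross
Title: Haplotype Phasing and Meiotic Crossover Mapping from Single-Gamete Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing an individual's chromosome-scale
    haplotypes from barcoded single-gamete DNA sequencing data and for calling
    meiotic crossovers in each gamete. Phasing seeds a template haplotype from
    a putatively crossover-free gamete, fills missing markers from SNP linkage
    across gametes, and repairs switch errors with a likelihood-based switch
    score. Crossovers are decoded per gamete with a two-state hidden Markov
    model with binomial allele-count emissions (Viterbi path plus per-segment
    log-likelihood-ratio confidence). Downstream functions filter crossover
    calls, count them over genomic intervals, convert rates to genetic
    distances (Kosambi or Haldane), and compare gamete groups with bootstrap
    and permutation resampling. A synthetic-gamete simulator with known truth
    supports validation end to end, and a command-line interface mirrors the
    phase / swphase / autophase / xo / sxo workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
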