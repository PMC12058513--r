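Package: rohprofiler
Title: Runs of Homozygosity Calling, Profiling and Error-Aware Benchmarking
Version: 0.1.0
Authors@R: person("ROH", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Whole-genome runs-of-homozygosity (ROH) profiling on diploid SNP
    genotypes. Calls ROH per sample with a two-state autozygosity hidden Markov
    model (Viterbi decoded, genetic-map-scaled transitions, genotype-error-aware
    emissions) and with a sliding-window homozygosity scanner with a tunable
    per-window heterozygote allowance. Computes per-individual and cohort
    statistics (NROH, SROH, F_ROH, length-interval distributions), detects ROH
    islands as top-percentile loci of cross-individual overlap, and quantifies
    the effect of genotyping errors via pedigree-based Mendelian QC and
    density-matched site pruning. Includes a cohort simulator with planted
    autozygous segments, three-generation pedigrees with Haldane recombination,
    and configurable genotype-error models, providing ground truth for recovery
    benchmarks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
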