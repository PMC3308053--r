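Package: enufunnel
Title: Causal-Variant Prioritization and Segregation Analysis for ENU Mouse Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies induced causal point mutations in chemically mutagenized
    (ENU) mouse lines from exome variant calls, without linkage mapping. Implements
    a variant filtration funnel (background-strain subtraction, known-variant panel
    subtraction, quality thresholds, codon-aware consequence annotation and
    candidate selection), indel-proximity artifact flagging, capillary-style
    validation adjudication, physical-distance linkage exclusion, and
    segregation/penetrance statistics for partially penetrant dominant phenotypes
    (Wilson intervals, exact binomial homozygote-deficit and Mendelian-ratio
    tests). A seeded simulator generates reference sequence, gene models, variant
    call sets with planted causal mutations and realistic artifact modes, and
    genotype-phenotype cohorts with bimodal hearing thresholds, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
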