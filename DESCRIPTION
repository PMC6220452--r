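Package: epiregseek
Title: Differential Methylation and Epiregulation Screening for
    Environment-Driven Plant Sex Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a whole-genome bisulfite
    sequencing and transcriptome integration workflow for studying how
    temperature and photoperiod reshape the cucumber shoot-apex methylome
    and sex expression. Provides methylcytosine calling against a
    bisulfite-conversion binomial background, Fisher-exact differential
    cytosine (DmC) calling, a seed-and-extend differentially methylated
    region (DMR) caller with Wilcoxon rank-sum testing, gene and
    transposable-element association of DmCs and DMRs, a
    divergence-probability screen for differentially expressed genes and
    TEs, a negative promoter-methylation/expression epiregulation screen,
    and the nested and factorial ANOVA decompositions used for
    multi-year femaleness (PNPF) phenotype tables. A synthetic-data
    module generates genomes, annotations, methylomes, expression
    matrices and phenotype tables with planted, recoverable truth so the
    whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
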