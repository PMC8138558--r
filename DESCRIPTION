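Package: hervscape
Title: Virus-Metagenome Quantification of Endogenous Retrovirus Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying human endogenous retrovirus (HERV)
    expression in bulk RNA-seq against a purpose-built virus metagenome
    reference: reference construction with family and category structure,
    uniqueness-constrained assignment of paired-end fragments, element- and
    family-level FPKM (family values use summed member counts over summed
    member lengths), median-calibrated 2^-delta-delta-Ct relative
    quantification of qPCR data with two-way ANOVA and Tukey HSD group
    statistics, and an anchor-gene screen selecting transcripts by Pearson
    correlation with a qPCR anchor profile plus a fold-change cutoff.
    Includes simulators for every pipeline input (paired-end reads with
    controlled multi-mapping, negative-binomial count tables, FPKM
    matrices, Ct tables) with ground-truth sidecars, and a deterministic
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    graphics,
    grDevices,
    stats,
    utils,
    tools,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
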