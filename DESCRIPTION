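Package: omegaGC
Title: GC-Corrected Evolutionary Pressure Scores for Protein-Coding Genes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scan for selective constraint and positive selection
    on protein-coding genes. Estimates per-gene, per-taxon dN/dS from pairwise
    codon alignments against a reconstructed ancestor using Nei-Gojobori-style
    pathway counting with Jukes-Cantor correction and a zero-synonymous
    protection rule; converts raw ratios into GC12-corrected, genome-wide
    Z-standardized scores (omega_GC12); combines them with polymorphism data
    into McDonald-Kreitman statistics (neutrality index, Direction of
    Selection); scores tissue specificity of expression (Z-profiles, tau);
    tests gene sets with Wilcoxon signed-rank statistics, rank-biserial effect
    sizes and covariate-matched bootstrap empirical p-values; and extracts
    positively selected (PSG) and selectively constrained (SCG) gene classes.
    Ships a full synthetic-data generator with known ground truth so the whole
    pipeline is testable without external genome-scale resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, SequenceAnalysis, GeneExpression
RoxygenNote: 7.3.3
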