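Package: epioverlap
Title: Quantifying Overlap Between GWAS and EWAS Association Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates genome-wide and epigenome-wide association study
    summary statistics to ask whether the two study designs implicate the
    same genes and pathways. Maps trait-associated SNPs and CpG sites to
    nearest genes and to genesets, quantifies overlap with odds-ratio and
    enrichment-score-correlation statistics against resampling null
    distributions (random genomic positions and fixed-shift positions that
    preserve the spacing of the observed sites), and provides two simulation
    frameworks: power to detect gene/geneset overlap under varying study
    power and causal fractions (scored by ROC AUC), and inference of the
    underlying genetic/epigenetic architecture from observed enrichment
    correlations over a grid of candidate architectures. A synthetic-data
    generator with a known causal/associated gene architecture drives all
    stages so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    pROC,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    optparse,
    IRanges,
    S4Vectors,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
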