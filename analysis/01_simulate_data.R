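#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study system every later stage consumes.
#
# One trait with a known architecture: 60 causal genes (what a GWAS can
# find) and 60 associated genes (what an EWAS can find), half of the
# associated genes being causal. Both studies detect 80% of their pool.
# Writes the full input bundle (chrom.sizes, gene models, GMT genesets, two
# summary-statistics tables, ground-truth JSON) under results/data/.

suppressPackageStartupMessages(library(epioverlap))

out <- "results/data"
b <- simulate_trait_bundle(
  out,
  n_chromosomes = 4, chrom_length = 3e7, n_genes = 4000,
  n_sets = 60, size_range = c(10, 300), broad_fraction = 0.3,
  n_causal = 60, n_associated = 60, overlap_proportion = 0.5,
  gwas_design = study_design("gwas", power = 0.8),
  ewas_design = study_design("ewas", power = 0.8),
  seed = 2026)

cat("Synthetic trait bundle written to", out, "\n")
cat(sprintf("  genome: %d chromosomes x %.0f Mb, %d genes\n",
            length(b$layout$chrom), b$layout$length[1] / 1e6, nrow(b$genes)))
cat(sprintf("  genesets: %d (sizes %d-%d)\n", length(b$annotation$sets),
            min(b$annotation$set_sizes), max(b$annotation$set_sizes)))
cat(sprintf("  architecture: %d causal, %d associated, overlap %d genes\n",
            length(b$architecture$causal_genes),
            length(b$architecture$associated_genes),
            length(intersect(b$architecture$causal_genes,
                             b$architecture$associated_genes))))
cat(sprintf("  detected: %d GWAS genes, %d EWAS genes (power 0.8)\n",
            length(b$gwas$detected_genes), length(b$ewas$detected_genes)))
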