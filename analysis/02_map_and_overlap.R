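#!/usr/bin/env Rscript

# Stage 2: the per-trait empirical analysis on the simulated bundle.
#
# Thresholds the summary statistics (GWAS 5e-8, EWAS 1e-7), tallies 500 kb
# region co-occurrence at the lenient region threshold, maps significant
# sites to nearest genes, and computes the three overlap statistics with
# their random-position null comparisons. Writes the per-trait tables under
# results/trait/.

suppressPackageStartupMessages(library(epioverlap))

data_dir <- "results/data"
stopifnot(dir.exists(data_dir))  # run analysis/01_simulate_data.R first
gen <- read_genome(file.path(data_dir, "chrom.sizes"),
                   file.path(data_dir, "genes.tsv"))
ann <- read_gmt(file.path(data_dir, "genesets.gmt"),
                universe = gen$genes$gene_id)

cfg <- run_config(rng_seed = 2026, resample_reps = 500, region_width = 5e5)
rep <- run_trait(file.path(data_dir, "gwas.tsv"),
                 file.path(data_dir, "ewas.tsv"),
                 gen$layout, gen$genes, ann, config = cfg,
                 out_dir = "results/trait")

cat("\nRegion co-occurrence (", sum(rep$region_tally$counts),
    "regions with a measured probe):\n")
print(rep$region_tally$counts)
rows <- report_rows(rep)
cat("\nGene overlap:\n")
print(rows$gene_table, row.names = FALSE)
cat("\nGeneset enrichment correlation:\n")
print(rows$cor_table, row.names = FALSE)
cat("\nThe trait was simulated with half of the associated genes causal:",
    "\nthe observed gene-overlap OR sits far above its null expectation",
    "\n(p_diff column); the enrichment correlation is positive but tested",
    "\nagainst a much wider null at this geneset count.\n")
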