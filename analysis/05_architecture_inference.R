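#!/usr/bin/env Rscript

# Stage 5: what architectures are consistent with the observed overlap?
#
# Takes the mapped GWAS/EWAS gene lists of the simulated trait as the
# "known" genes, simulates candidate architectures over the multiplier
# {1,2,3,5,10,20} x overlap {0,0.01,0.1,0.5,1} grid, and scores each
# against the observed enrichment correlation with a z-test + BH-FDR.
# Because the trait was generated with a known architecture, the grid's
# verdicts can be checked against the truth. Writes results/architecture/.

suppressPackageStartupMessages(library(epioverlap))

data_dir <- "results/data"
stopifnot(dir.exists(data_dir))
gen <- read_genome(file.path(data_dir, "chrom.sizes"),
                   file.path(data_dir, "genes.tsv"))
ann <- read_gmt(file.path(data_dir, "genesets.gmt"),
                universe = gen$genes$gene_id)
gwas <- read_summary_stats(file.path(data_dir, "gwas.tsv"), "gwas")
ewas <- read_summary_stats(file.path(data_dir, "ewas.tsv"), "ewas")
kgg <- map_sites_to_genes(gwas$sites, gen$genes)$genes
keg <- map_sites_to_genes(ewas$sites, gen$genes)$genes
emp_rho <- enrichment_correlation(enrichment_profile(keg, ann),
                                  enrichment_profile(kgg, ann))
cat(sprintf("known genes: %d GWAS, %d EWAS; observed correlation %.3f\n",
            length(kgg), length(keg), emp_rho))

res <- run_arch_grid(kgg, keg, ann, emp_rho, reps = 500, seed = 2026)
dir.create("results/architecture", showWarnings = FALSE, recursive = TRUE)
write_results_table(res, "results/architecture/arch_grid.tsv")
print(res[, c("multiplier", "overlap_proportion", "total_genes",
              "sim_median", "z_p", "fdr_q", "rejected")],
      row.names = FALSE, digits = 3)

cat(sprintf("\n%d of %d scenarios show evidence against reflecting reality (FDR < 0.05).\n",
            sum(res$rejected, na.rm = TRUE), nrow(res)))
cat("The trait was generated from pools of 60+60 genes (about 1x the known",
    "\ngene count) with 50% causal/associated overlap; scenarios near that",
    "\ncorner survive, as they must. Note how little the simulated median",
    "\ncorrelation moves across the grid: many architectures are compatible",
    "\nwith one observed correlation, which is what makes this inference",
    "\nhard and why only the most extreme corners ever get rejected.\n")
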