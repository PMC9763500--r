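#' Run the full overlap analysis for one GWAS/EWAS trait pair
#'
#' Orchestrates the per-trait pipeline: read and threshold summary
#' statistics, bin the genome and tally region co-occurrence, map
#' significant sites to genes, compute the gene-overlap OR, the
#' geneset-overlap OR and the enrichment-score correlation, and compare each
#' against the random-position and shifted-position resampling nulls.
#'
#' @param gwas,ewas [study_hits()] objects or paths to summary-statistics
#'   tables.
#' @param layout A [genome_layout()].
#' @param genes Gene table.
#' @param annotation A [geneset_annotation()].
#' @param config A [run_config()].
#' @param gwas_full,ewas_full Optional full (unthresholded) site tables; the
#'   EWAS panel defines which regions are measurable and both feed the
#'   lenient region tally. Required when `gwas`/`ewas` are pre-thresholded
#'   objects; read from the paths otherwise.
#' @param out_dir Optional directory to write all intermediate tables into.
#' @return An object of class `pipeline_report`.
#' @export
run_trait <- function(gwas, ewas, layout, genes, annotation,
                      config = run_config(), gwas_full = NULL,
                      ewas_full = NULL, out_dir = NULL) {
  if (is.character(gwas)) {
    gwas_full <- gwas_full %||% read_site_table(gwas)
    gwas <- read_summary_stats(gwas, "gwas", config$gwas_p)
  }
  if (is.character(ewas)) {
    ewas_full <- ewas_full %||% read_site_table(ewas)
    ewas <- read_summary_stats(ewas, "ewas", config$ewas_p)
  }
  if (is.null(ewas_full)) stop("ewas_full (probe panel) is required")
  if (is.null(gwas_full)) stop("gwas_full is required")

  universe <- switch(config$universe_mode,
                     all_genes = genes$gene_id,
                     protein_coding = genes$gene_id[genes$biotype == "protein_coding"])
  universe <- intersect(universe, annotation$universe)

  # --- region co-occurrence -------------------------------------------
  regions <- filter_regions(bin_genome(layout, config$region_width),
                            ewas_full)
  region_p <- resolve_region_threshold(max(ewas_full$p), config$region_p)
  tally <- tally_regions(regions, gwas_full, ewas_full, region_p = region_p)
  auc_region <- tryCatch(
    region_effect_auc(regions, gwas_full[gwas_full$p < region_p, , drop = FALSE],
                      ewas$sites),
    error = function(e) {
      message("region effect AUC unavailable: ", conditionMessage(e))
      NULL
    })

  # --- site -> gene mapping -------------------------------------------
  gmap <- map_sites_to_genes(gwas$sites, genes)
  emap <- map_sites_to_genes(ewas$sites, genes)
  gwas_genes <- intersect(gmap$genes, universe)
  ewas_genes <- intersect(emap$genes, universe)
  message(sprintf("mapped %d GWAS and %d EWAS genes (universe %d)",
                  length(gwas_genes), length(ewas_genes), length(universe)))

  sub_ann <- annotation
  if (length(universe) < length(annotation$universe)) {
    sub_ann <- geneset_annotation(
      lapply(annotation$sets, function(s) intersect(s, universe)),
      universe = universe)
  }

  # --- observed statistics --------------------------------------------
  or_gene <- tryCatch(gene_overlap(ewas_genes, gwas_genes, universe),
                      error = function(e) NULL)
  or_sets <- tryCatch(geneset_overlap(ewas_genes, gwas_genes, sub_ann),
                      error = function(e) NULL)
  rho <- tryCatch(
    enrichment_correlation(enrichment_profile(ewas_genes, sub_ann, "ewas"),
                           enrichment_profile(gwas_genes, sub_ann, "gwas")),
    error = function(e) {
      message("enrichment correlation unavailable: ", conditionMessage(e))
      NA_real_
    })

  # --- resampling nulls -----------------------------------------------
  stats_wanted <- c("gene_overlap_or", "enrichment_correlation")
  rnull <- random_position_null(nrow(ewas$sites), layout, genes, sub_ann,
                                gwas_genes, reps = config$resample_reps,
                                seed = child_seed(config$rng_seed, "random_null"),
                                statistics = stats_wanted)
  snull <- shifted_null_distributions(ewas$sites, layout, genes, sub_ann,
                                      gwas_genes,
                                      reps = config$resample_reps,
                                      statistics = stats_wanted)
  summarise <- function(obs, nd) {
    if (is.null(obs) || is.na(obs)) return(list(expected = nd$mean, p_diff = NA_real_))
    tryCatch(expected_overlap_summary(obs, nd),
             error = function(e) list(expected = nd$mean, p_diff = NA_real_))
  }
  or_obs <- if (!is.null(or_gene)) or_gene$odds_ratio else NA_real_
  report <- structure(list(
    trait = gwas$trait,
    config = config,
    region_tally = tally,
    region_threshold = region_p,
    region_auc = auc_region,
    gwas_genes = gwas_genes, ewas_genes = ewas_genes,
    gwas_map = gmap, ewas_map = emap,
    gene_overlap = or_gene,
    geneset_overlap = or_sets,
    enrichment_correlation = rho,
    null_random = list(
      or = summarise(or_obs, rnull$gene_overlap_or),
      rho = summarise(rho, rnull$enrichment_correlation)),
    null_shifted = list(
      or = summarise(or_obs, snull$gene_overlap_or),
      rho = summarise(rho, snull$enrichment_correlation)),
    nulls = list(random = rnull, shifted = snull)),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' One-row gene-overlap and correlation summaries of a pipeline report
#'
#' The two summary schemas of the per-trait analysis: gene counts, observed
#' and expected (null-mean) OR and correlation, and the z-test p for the
#' difference.
#'
#' @param report A [run_trait()] report.
#' @return A list of two one-row data.frames: `gene_table`, `cor_table`.
#' @export
report_rows <- function(report) {
  og <- report$gene_overlap
  gene_table <- data.frame(
    trait = report$trait,
    n_ewas_genes = length(report$ewas_genes),
    n_gwas_genes = length(report$gwas_genes),
    gene_overlap = if (!is.null(og)) og$table$a else NA_integer_,
    obs_or = if (!is.null(og)) og$odds_ratio else NA_real_,
    exp_overlap = report$null_random$or$expected,
    p_diff = report$null_random$or$p_diff,
    stringsAsFactors = FALSE)
  os <- report$geneset_overlap
  cor_table <- data.frame(
    trait = report$trait,
    n_ewas_genes = length(report$ewas_genes),
    n_gwas_genes = length(report$gwas_genes),
    geneset_overlap = if (!is.null(os)) os$table$a else NA_integer_,
    obs_cor = report$enrichment_correlation,
    exp_cor = report$null_random$rho$expected,
    p_diff = report$null_random$rho$p_diff,
    stringsAsFactors = FALSE)
  list(gene_table = gene_table, cor_table = cor_table)
}

#' Write a pipeline report's tables to a directory
#' @param report A [run_trait()] report.
#' @param out_dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- report_rows(report)
  write_results_table(rows$gene_table, file.path(out_dir, "gene_overlap.tsv"))
  write_results_table(rows$cor_table, file.path(out_dir, "enrichment_correlation.tsv"))
  write_results_table(report$region_tally$regions,
                      file.path(out_dir, "region_tally.tsv"))
  write_results_table(report$gwas_map$map, file.path(out_dir, "gwas_gene_map.tsv"))
  write_results_table(report$ewas_map$map, file.path(out_dir, "ewas_gene_map.tsv"))
  nd <- report$nulls
  write_results_table(
    data.frame(rep = seq_along(nd$random$gene_overlap_or$draws),
               random_or = nd$random$gene_overlap_or$draws,
               random_rho = nd$random$enrichment_correlation$draws,
               shifted_or = nd$shifted$gene_overlap_or$draws,
               shifted_rho = nd$shifted$enrichment_correlation$draws),
    file.path(out_dir, "null_draws.tsv"))
  write_run_metadata(report$config, file.path(out_dir, "run_metadata.json"))
  invisible(out_dir)
}

#' Run the pipeline for a manifest of trait pairs
#'
#' Per-trait failures are isolated: a failing trait contributes a failure
#' record and the run continues. Benjamini-Hochberg FDR is applied across
#' traits to the null-comparison p-values in the combined tables.
#'
#' @param manifest data.frame with columns `trait`, `gwas`, `ewas` (paths to
#'   summary-statistics tables).
#' @param layout,genes,annotation,config As in [run_trait()].
#' @param out_dir Optional root directory; each trait writes into a
#'   subdirectory.
#' @return A list: `reports` (per trait), `gene_table` and `cor_table`
#'   (combined, with `fdr_q`), `failures` (data.frame of trait/error).
#' @export
run_all <- function(manifest, layout, genes, annotation,
                    config = run_config(), out_dir = NULL) {
  reports <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    trait <- manifest$trait[i]
    res <- tryCatch(
      run_trait(manifest$gwas[i], manifest$ewas[i], layout, genes, annotation,
                config = config,
                out_dir = if (!is.null(out_dir)) file.path(out_dir, trait)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        trait = trait, error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      res$trait <- trait
      reports[[trait]] <- res
    }
  }
  combine <- function(which_tab) {
    tabs <- lapply(reports, function(r) report_rows(r)[[which_tab]])
    if (!length(tabs)) return(NULL)
    tab <- do.call(rbind, tabs)
    tab$trait <- names(reports)
    ok <- !is.na(tab$p_diff)
    tab$fdr_q <- NA_real_
    tab$fdr_q[ok] <- bh_fdr(tab$p_diff[ok])
    rownames(tab) <- NULL
    tab
  }
  list(reports = reports,
       gene_table = combine("gene_table"),
       cor_table = combine("cor_table"),
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}
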