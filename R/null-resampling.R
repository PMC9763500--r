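#' Shift configuration for the spacing-preserving null
#'
#' The shifted null advances every observed site by a fixed offset
#' `max_gene_size * iteration` along the concatenated genome, preserving the
#' hit list's internal spacing while relocating it. `max_gene_size` is taken
#' as the maximum gene length in the loaded annotation (the only reading
#' that gives a single fixed shift per iteration).
#'
#' @param max_gene_size Maximum gene size in bp (> 0).
#' @param iteration Positive integer iteration index.
#' @param wrap_order Optional chromosome order for the wrap-around; defaults
#'   to the layout order when the null is applied.
#' @return An object of class `shift_config`.
#' @export
shift_config <- function(max_gene_size, iteration, wrap_order = NULL) {
  stopifnot(max_gene_size > 0, iteration >= 1, iteration == round(iteration))
  structure(list(max_gene_size = max_gene_size,
                 iteration = as.integer(iteration),
                 wrap_order = wrap_order),
            class = "shift_config")
}

#' Shift observed sites along the concatenated genome
#'
#' Each site's position is advanced by `max_gene_size * iteration` along the
#' concatenated genome in the layout's chromosome order; positions running
#' off the end of a chromosome carry over into the next, and positions past
#' the end of the last chromosome wrap around to the first. Shifts of at
#' least one genome length are reduced modulo the total length (with a
#' note).
#'
#' @param dmps data.frame of sites (`site_id`, `chr`, `pos`).
#' @param config A [shift_config()].
#' @param layout A [genome_layout()].
#' @return The sites with updated `chr`/`pos`; count and same-genome spacing
#'   are preserved.
#' @export
shifted_position_null <- function(dmps, config, layout) {
  stopifnot(inherits(config, "shift_config"))
  if (nrow(dmps) == 0) stop("no sites to shift")
  if (!is.null(config$wrap_order)) {
    if (!setequal(config$wrap_order, layout$chrom)) {
      stop("wrap_order must be a permutation of the layout chromosomes")
    }
    ord <- match(config$wrap_order, layout$chrom)
    layout <- genome_layout(layout$chrom[ord], layout$length[ord],
                            layout$build)
  }
  total <- genome_size(layout)
  shift <- config$max_gene_size * config$iteration
  if (shift >= total) {
    message(sprintf("shift %g exceeds genome length %g; reduced modulo total",
                    shift, total))
  }
  gpos <- to_global(layout, dmps$chr, dmps$pos)
  newpos <- (gpos + shift) %% total
  coords <- from_global(layout, newpos)
  out <- dmps
  out$chr <- coords$chr
  out$pos <- coords$pos
  out
}

# One set of resampled statistics for a null EWAS gene list against fixed
# GWAS genes. Failures (e.g. an empty mapped list) yield NA for the
# affected statistic, not an abort.
.null_statistics <- function(ewas_genes, gwas_genes, annotation,
                             gwas_profile, statistics) {
  out <- setNames(rep(NA_real_, length(statistics)), statistics)
  ewas_genes <- intersect(ewas_genes, annotation$universe)
  if ("gene_overlap_or" %in% statistics) {
    out["gene_overlap_or"] <- tryCatch(
      gene_overlap(ewas_genes, gwas_genes, annotation$universe)$odds_ratio,
      error = function(e) NA_real_)
  }
  if ("geneset_overlap_or" %in% statistics) {
    out["geneset_overlap_or"] <- tryCatch(
      geneset_overlap(ewas_genes, gwas_genes, annotation)$odds_ratio,
      error = function(e) NA_real_)
  }
  if ("enrichment_correlation" %in% statistics) {
    out["enrichment_correlation"] <- tryCatch(
      enrichment_correlation(enrichment_profile(ewas_genes, annotation),
                             gwas_profile),
      error = function(e) NA_real_)
  }
  out
}

#' Random-position null distributions of the overlap statistics
#'
#' Per replicate, `n_sites` positions are drawn uniformly over the
#' concatenated genome (length-weighted per chromosome), mapped to genes
#' exactly as the observed pipeline maps them, and the requested statistics
#' are computed against the fixed GWAS gene set.
#'
#' @param n_sites Number of positions per replicate (the number of observed
#'   DMPs); must be >= 1.
#' @param layout A [genome_layout()].
#' @param genes Gene table.
#' @param annotation A [geneset_annotation()].
#' @param gwas_genes Fixed GWAS gene set the null lists are compared with.
#' @param reps Number of replicates.
#' @param seed Integer seed; replicate `i` uses an independent child stream.
#' @param statistics Which statistics to collect.
#' @return Named list of [null_distribution()] objects, one per statistic.
#' @export
random_position_null <- function(n_sites, layout, genes, annotation,
                                 gwas_genes, reps = 1000L, seed = 1L,
                                 statistics = c("gene_overlap_or",
                                                "geneset_overlap_or",
                                                "enrichment_correlation")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (n_sites < 1) stop("n_sites must be >= 1 (no DMPs to resample)")
  stopifnot(reps >= 1)
  total <- genome_size(layout)
  gwas_profile <- if ("enrichment_correlation" %in% statistics) {
    enrichment_profile(intersect(gwas_genes, annotation$universe), annotation,
                       study = "gwas")
  }
  draws <- matrix(NA_real_, nrow = reps, ncol = length(statistics),
                  dimnames = list(NULL, statistics))
  for (i in seq_len(reps)) {
    gpos <- with_seed(child_seed(seed, "random_position_null", i),
                      floor(runif(n_sites, 0, total)))
    coords <- from_global(layout, gpos)
    coords$site_id <- sprintf("null%06d", seq_len(n_sites))
    mapped <- suppressWarnings(map_sites_to_genes(coords, genes))
    draws[i, ] <- .null_statistics(mapped$genes, gwas_genes, annotation,
                                   gwas_profile, statistics)
  }
  setNames(lapply(statistics, function(s) null_distribution(draws[, s], s)),
           statistics)
}

#' Shifted-position null distributions of the overlap statistics
#'
#' Replicate `i` shifts the observed DMPs by `max_gene_size * i` along the
#' concatenated genome ([shifted_position_null()]), preserving their
#' internal spacing (and hence local correlation structure), then recomputes
#' the requested statistics against the fixed GWAS gene set.
#'
#' @param dmps data.frame of observed DMPs (`site_id`, `chr`, `pos`).
#' @param layout,genes,annotation,gwas_genes,reps,statistics As in
#'   [random_position_null()].
#' @param max_gene_size Shift unit in bp; default the maximum gene length in
#'   `genes`.
#' @return Named list of [null_distribution()] objects.
#' @export
shifted_null_distributions <- function(dmps, layout, genes, annotation,
                                       gwas_genes, reps = 1000L,
                                       max_gene_size = NULL,
                                       statistics = c("gene_overlap_or",
                                                      "geneset_overlap_or",
                                                      "enrichment_correlation")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  max_gene_size <- max_gene_size %||% max(genes$end - genes$start)
  gwas_profile <- if ("enrichment_correlation" %in% statistics) {
    enrichment_profile(intersect(gwas_genes, annotation$universe), annotation,
                       study = "gwas")
  }
  draws <- matrix(NA_real_, nrow = reps, ncol = length(statistics),
                  dimnames = list(NULL, statistics))
  for (i in seq_len(reps)) {
    shifted <- shifted_position_null(dmps, shift_config(max_gene_size, i),
                                     layout)
    mapped <- suppressWarnings(map_sites_to_genes(shifted, genes))
    draws[i, ] <- .null_statistics(mapped$genes, gwas_genes, annotation,
                                   gwas_profile, statistics)
  }
  setNames(lapply(statistics, function(s) null_distribution(draws[, s], s)),
           statistics)
}

#' Expected value and z-test p against a null distribution
#'
#' The "expected" value of an overlap statistic is the mean of its
#' resampling null; the difference between observed and expected is scored
#' by the two-sided z-test.
#'
#' @param observed Observed statistic.
#' @param null A [null_distribution()].
#' @return A list: `expected` (null mean), `p_diff` (two-sided z-test
#'   p-value).
#' @export
expected_overlap_summary <- function(observed, null) {
  list(expected = null$mean, p_diff = z_test_vs_null(observed, null))
}
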