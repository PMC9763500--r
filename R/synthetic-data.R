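#' Generate a synthetic genome layout and gene models
#'
#' Places `n_genes` non-overlapping genes uniformly on `n_chromosomes` equal
#' chromosomes. Genes are assigned to chromosomes uniformly at random; within
#' a chromosome the inter-gene gaps are drawn by stick-breaking, so
#' placement is uniform over all non-overlapping arrangements. Errors if the
#' total gene footprint cannot fit.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Total number of genes.
#' @param gene_length_range Length-2 vector `(min, max)` of gene lengths
#'   (bp), drawn uniformly.
#' @param seed Integer seed; the output is deterministic given it.
#' @param coding_fraction Fraction of genes labelled `protein_coding`
#'   (default 0.35, roughly the protein-coding share of annotated human
#'   genes); the rest are `other`.
#' @return A list with `layout` ([genome_layout()]) and `genes`
#'   (data.frame: gene_id, chr, start, end, biotype; 0-based half-open).
#' @export
generate_genome <- function(n_chromosomes, chrom_length, n_genes,
                            gene_length_range = c(1e3, 5e4), seed = 1L,
                            coding_fraction = 0.35) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, n_genes >= 0,
            length(gene_length_range) == 2,
            gene_length_range[1] >= 1,
            gene_length_range[1] <= gene_length_range[2],
            coding_fraction >= 0, coding_fraction <= 1)
  layout <- genome_layout(paste0("chr", seq_len(n_chromosomes)),
                          rep(chrom_length, n_chromosomes))
  if (n_genes == 0) {
    genes <- data.frame(gene_id = character(), chr = character(),
                        start = numeric(), end = numeric(),
                        biotype = character(), stringsAsFactors = FALSE)
    return(list(layout = layout, genes = genes))
  }
  with_seed(seed, {
    chrom <- sample(layout$chrom, n_genes, replace = TRUE)
    lens <- floor(runif(n_genes, gene_length_range[1], gene_length_range[2] + 1))
    starts <- numeric(n_genes)
    for (cn in layout$chrom) {
      idx <- which(chrom == cn)
      if (!length(idx)) next
      footprint <- sum(lens[idx])
      slack <- chrom_length - footprint
      if (slack < 0) {
        stop("infeasible packing: ", length(idx), " genes (", footprint,
             " bp) exceed chromosome length ", chrom_length, " on ", cn)
      }
      # stick-breaking: distribute the slack over n+1 gaps
      cuts <- sort(floor(runif(length(idx), 0, slack + 1)))
      ord <- sample(idx)  # random gene order along the chromosome
      starts[ord] <- cuts + c(0, cumsum(lens[ord]))[seq_along(ord)]
    }
    biotype <- ifelse(runif(n_genes) < coding_fraction, "protein_coding", "other")
    genes <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      chr = chrom, start = starts, end = starts + lens,
      biotype = biotype, stringsAsFactors = FALSE)
  })
  validate_genes(genes, layout)
  list(layout = layout, genes = genes)
}

#' Generate a geneset annotation with broad and narrow sets
#'
#' Emulates the mix of broad and narrow functional terms found in curated
#' annotations: a configurable fraction of sets are "broad" (over 100
#' members) and the remainder "narrow" (under 100). Within each class, set
#' sizes are drawn log-uniformly between the bounds, giving a heavy-tailed
#' size distribution. Members are sampled uniformly without replacement.
#'
#' @param genes Gene table (or character vector of gene ids) defining the
#'   universe.
#' @param n_sets Number of genesets.
#' @param size_range Length-2 `(min, max)` bounds on set sizes.
#' @param broad_fraction Fraction of sets with more than 100 members
#'   (requires `max > 100` unless 0).
#' @param seed Integer seed.
#' @return A [geneset_annotation()] whose universe is all supplied genes.
#' @export
generate_genesets <- function(genes, n_sets, size_range = c(10, 500),
                              broad_fraction = 0.5, seed = 1L) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  stopifnot(n_sets >= 1, length(size_range) == 2,
            size_range[1] >= 1, size_range[1] <= size_range[2],
            broad_fraction >= 0, broad_fraction <= 1)
  if (size_range[2] > length(ids)) {
    stop("requested geneset size ", size_range[2],
         " exceeds universe size ", length(ids))
  }
  n_broad <- round(broad_fraction * n_sets)
  if (n_broad > 0 && size_range[2] <= 100) {
    stop("broad_fraction > 0 requires max set size > 100")
  }
  with_seed(seed, {
    rlog <- function(n, lo, hi) {
      if (n == 0) return(integer())
      pmin(hi, pmax(lo, round(exp(runif(n, log(lo), log(hi))))))
    }
    lo_b <- max(size_range[1], 101)
    hi_n <- min(size_range[2], 100)
    sizes <- c(rlog(n_broad, lo_b, size_range[2]),
               rlog(n_sets - n_broad, size_range[1], max(size_range[1], hi_n)))
    sizes <- sizes[sample.int(n_sets)]
    sets <- lapply(sizes, function(k) sample(ids, k))
    names(sets) <- sprintf("GS%04d", seq_len(n_sets))
  })
  geneset_annotation(sets, universe = ids)
}

#' Trait architecture: causal and associated gene pools
#'
#' A trait's genetic/epigenetic architecture is summarised by a pool of
#' causal genes (genes whose products influence the trait -- what GWAS hits
#' tag) and a pool of associated genes (genes correlated with the trait via
#' causation, confounding or reverse causation -- what EWAS hits tag), with
#' a configurable overlap between the two.
#'
#' @param genes Gene table or character vector of gene ids.
#' @param n_causal,n_associated Pool sizes.
#' @param overlap_proportion Fraction of associated genes that are also
#'   causal, in `[0, 1]`; the realised intersection is
#'   `round(overlap_proportion * n_associated)`.
#' @param seed Integer seed.
#' @return An object of class `trait_architecture` with elements
#'   `causal_genes`, `associated_genes`, `overlap_proportion`.
#' @export
generate_architecture <- function(genes, n_causal, n_associated,
                                  overlap_proportion, seed = 1L) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  stopifnot(n_causal >= 0, n_associated >= 0,
            overlap_proportion >= 0, overlap_proportion <= 1)
  n_overlap <- round(overlap_proportion * n_associated)
  if (n_overlap > n_causal) {
    stop("overlap (", n_overlap, ") cannot exceed n_causal (", n_causal, ")")
  }
  n_total <- n_causal + n_associated - n_overlap
  if (n_total > length(ids)) {
    stop("infeasible: need ", n_total, " distinct genes but universe has ",
         length(ids))
  }
  with_seed(seed, {
    drawn <- sample(ids, n_total)
  })
  shared <- drawn[seq_len(n_overlap)]
  causal <- c(shared, drawn[n_overlap + seq_len(n_causal - n_overlap)])
  assoc <- c(shared, drawn[n_causal + seq_len(n_associated - n_overlap)])
  structure(list(causal_genes = causal, associated_genes = assoc,
                 overlap_proportion = overlap_proportion),
            class = "trait_architecture")
}

#' Study design for synthetic summary statistics
#'
#' @param study_type `"gwas"` or `"ewas"`; selects which architecture pool
#'   drives the signal (GWAS: causal pool; EWAS: associated pool).
#' @param power Probability that a signal gene's best site passes the study
#'   threshold ("power" here is the proportion of its pool the study
#'   detects).
#' @param n_sites_per_gene Sites placed within each signal gene body.
#' @param panel_density Background sites per megabase of genome.
#' @param threshold Significance threshold; `NULL` uses the study-type
#'   default (GWAS 5e-8, EWAS 1e-7).
#' @return An object of class `study_design`.
#' @export
study_design <- function(study_type = c("gwas", "ewas"), power = 0.8,
                         n_sites_per_gene = 3L, panel_density = 10,
                         threshold = NULL) {
  study_type <- match.arg(study_type)
  stopifnot(power >= 0, power <= 1, n_sites_per_gene >= 1, panel_density >= 0)
  structure(list(study_type = study_type, power = power,
                 n_sites_per_gene = as.integer(n_sites_per_gene),
                 panel_density = panel_density,
                 threshold = threshold %||% default_threshold(study_type)),
            class = "study_design")
}

#' Generate full summary statistics for one synthetic study
#'
#' Realises a study over a known architecture as site-level data. For each
#' signal gene (causal pool for GWAS, associated pool for EWAS),
#' `n_sites_per_gene` sites are placed uniformly within the gene body. With
#' probability `design$power` the gene is "detected": its minimum p-value is
#' drawn log-uniformly between 1e-30 and the study threshold; otherwise all
#' its sites get null Uniform(0,1] p-values. Background sites are placed
#' uniformly over the genome at `panel_density` per Mb with null p-values.
#' Effects are standard-normal-derived z-scores (signed), so significant
#' sites carry large absolute effects.
#'
#' @param architecture A [generate_architecture()] result.
#' @param design A [study_design()].
#' @param genome A [genome_layout()].
#' @param genes Gene table.
#' @param seed Integer seed.
#' @param trait Trait label.
#' @return A list: `sites` (full summary table: site_id, chr, pos, p,
#'   effect), `truth` (site_id, gene_id for signal sites), `signal_genes`,
#'   `detected_genes` (ground truth), `design`.
#' @export
generate_study <- function(architecture, design, genome, genes, seed = 1L,
                           trait = "synthetic") {
  signal_genes <- switch(design$study_type,
                         gwas = architecture$causal_genes,
                         ewas = architecture$associated_genes)
  gsub <- genes[match(signal_genes, genes$gene_id), , drop = FALSE]
  if (anyNA(gsub$gene_id)) stop("architecture genes missing from gene table")
  k <- design$n_sites_per_gene
  thr <- design$threshold
  total <- genome_size(genome)
  n_bg <- round(design$panel_density * total / 1e6)
  prefix <- if (design$study_type == "ewas") "cg" else "rs"
  with_seed(seed, {
    n_sig <- nrow(gsub) * k
    sig_gene <- rep(gsub$gene_id, each = k)
    sig_chr <- rep(gsub$chr, each = k)
    sig_pos <- floor(runif(n_sig, rep(gsub$start, each = k),
                           rep(gsub$end, each = k)))
    detected <- runif(nrow(gsub)) < design$power
    p_sig <- runif(n_sig)  # null draws for all signal sites...
    # ...then overwrite the lead site of each detected gene with a
    # sub-threshold p, log-uniform in [1e-30, thr)
    lead <- (which(detected) - 1L) * k + sample.int(k, sum(detected), replace = TRUE)
    p_sig[lead] <- exp(runif(sum(detected), log(1e-30), log(thr)))
    bg_gpos <- floor(runif(n_bg, 0, total))
    bg <- from_global(genome, bg_gpos)
    p_bg <- runif(n_bg)
  })
  p_all <- c(p_sig, p_bg)
  # signed z-score implied by the p-value: monotone in significance
  z <- qnorm(pmin(p_all, 1 - 1e-16) / 2, lower.tail = FALSE)
  with_seed(child_seed(seed, "effect_signs"), {
    effect <- z * sign(runif(length(p_all)) - 0.5)
  })
  sites <- data.frame(
    site_id = sprintf("%s%06d", prefix, seq_along(p_all)),
    chr = c(sig_chr, bg$chr),
    pos = c(sig_pos, bg$pos),
    p = p_all,
    effect = effect,
    stringsAsFactors = FALSE)
  truth <- data.frame(site_id = sites$site_id[seq_len(length(p_sig))],
                      gene_id = sig_gene, stringsAsFactors = FALSE)
  list(sites = sites, truth = truth,
       signal_genes = gsub$gene_id,
       detected_genes = gsub$gene_id[detected],
       design = design)
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates genome, genes, genesets, a trait architecture and a GWAS/EWAS
#' study pair, and writes them in the package's standard external formats:
#' `chrom.sizes`, `genes.tsv`, `genesets.gmt`, `gwas.tsv`, `ewas.tsv`, and
#' `truth.json` (the ground-truth architecture and detected genes).
#'
#' @param dir Output directory (created if missing).
#' @param n_chromosomes,chrom_length,n_genes,gene_length_range Genome shape;
#'   see [generate_genome()].
#' @param n_sets,size_range,broad_fraction Annotation shape; see
#'   [generate_genesets()].
#' @param n_causal,n_associated,overlap_proportion Architecture; see
#'   [generate_architecture()].
#' @param gwas_design,ewas_design [study_design()] objects.
#' @param seed Integer master seed.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_trait_bundle <- function(dir,
                                  n_chromosomes = 4, chrom_length = 2e7,
                                  n_genes = 800,
                                  gene_length_range = c(2e3, 2e4),
                                  n_sets = 100, size_range = c(10, 200),
                                  broad_fraction = 0.3,
                                  n_causal = 100, n_associated = 100,
                                  overlap_proportion = 0.5,
                                  gwas_design = study_design("gwas", power = 0.8),
                                  ewas_design = study_design("ewas", power = 0.8),
                                  seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- generate_genome(n_chromosomes, chrom_length, n_genes,
                           gene_length_range, seed = child_seed(seed, "genome"))
  annotation <- generate_genesets(world$genes, n_sets, size_range,
                                  broad_fraction,
                                  seed = child_seed(seed, "genesets"))
  arch <- generate_architecture(world$genes, n_causal, n_associated,
                                overlap_proportion,
                                seed = child_seed(seed, "architecture"))
  gwas <- generate_study(arch, gwas_design, world$layout, world$genes,
                         seed = child_seed(seed, "gwas"), trait = "synthetic")
  ewas <- generate_study(arch, ewas_design, world$layout, world$genes,
                         seed = child_seed(seed, "ewas"), trait = "synthetic")
  paths <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    genes = file.path(dir, "genes.tsv"),
    gmt = file.path(dir, "genesets.gmt"),
    gwas = file.path(dir, "gwas.tsv"),
    ewas = file.path(dir, "ewas.tsv"),
    truth = file.path(dir, "truth.json"))
  writeLines(paste(world$layout$chrom, format(world$layout$length, scientific = FALSE, trim = TRUE),
                   sep = "\t"), paths$chrom_sizes)
  write_results_table(world$genes, paths$genes)
  write_gmt(annotation, paths$gmt)
  write_results_table(gwas$sites, paths$gwas)
  write_results_table(ewas$sites, paths$ewas)
  jsonlite::write_json(
    list(seed = seed,
         causal_genes = arch$causal_genes,
         associated_genes = arch$associated_genes,
         overlap_proportion = arch$overlap_proportion,
         gwas_detected = gwas$detected_genes,
         ewas_detected = ewas$detected_genes),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(layout = world$layout, genes = world$genes,
                 annotation = annotation, architecture = arch,
                 gwas = gwas, ewas = ewas, paths = paths))
}
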