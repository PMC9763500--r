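#' Define a genome coordinate frame
#'
#' A `genome_layout` is the ordered set of chromosomes with their lengths.
#' The order is fixed and defines the wrap-around order used by the
#' shifted-position null ([shifted_position_null()]): positions that run off
#' the last chromosome re-enter on the first. All coordinates in the package
#' are 0-based, half-open.
#'
#' @param chromosomes Character vector of unique chromosome names, in order.
#' @param lengths Numeric vector of strictly positive lengths (bp).
#' @param build_label Free-text label for the assembly the frame describes.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, lengths, build_label = "synthetic") {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths)) {
    stop("chromosomes and lengths must have equal length")
  }
  if (length(chromosomes) == 0L) stop("layout needs at least one chromosome")
  if (anyDuplicated(chromosomes)) stop("duplicate chromosome names in layout")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be strictly positive")
  }
  structure(list(chrom = chromosomes, length = lengths, build = build_label),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %s: %d chromosomes, %.0f bp total\n",
              x$build, length(x$chrom), sum(x$length)))
  invisible(x)
}

#' Total genome length of a layout
#' @param layout A [genome_layout()].
#' @return Total length in bp.
#' @export
genome_size <- function(layout) sum(layout$length)

# Named vector of 0-based global offsets of each chromosome start.
chrom_offsets <- function(layout) {
  setNames(c(0, cumsum(layout$length))[seq_along(layout$chrom)], layout$chrom)
}

# Convert per-chromosome positions to 0-based positions along the
# concatenated genome, and back.
to_global <- function(layout, chrom, pos) {
  off <- chrom_offsets(layout)
  bad <- !(chrom %in% layout$chrom)
  if (any(bad)) stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  unname(off[chrom]) + pos
}

from_global <- function(layout, gpos) {
  brks <- c(0, cumsum(layout$length))
  if (any(gpos < 0 | gpos >= brks[length(brks)])) stop("global position out of range")
  k <- findInterval(gpos, brks, rightmost.closed = FALSE)
  data.frame(chr = layout$chrom[k], pos = gpos - brks[k],
             stringsAsFactors = FALSE)
}

#' Validate a table of gene records against a genome layout
#'
#' Checks the invariants every gene table must satisfy: unique ids,
#' `start < end` (0-based half-open), chromosome present in the layout and
#' gene body within its bounds, biotype one of `protein_coding`/`other`.
#'
#' @param genes data.frame with columns `gene_id`, `chr`, `start`, `end`,
#'   `biotype`.
#' @param layout A [genome_layout()].
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_genes <- function(genes, layout) {
  need <- c("gene_id", "chr", "start", "end", "biotype")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chr <- as.character(genes$chr)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  bad <- genes$start >= genes$end
  if (any(bad)) {
    stop("start >= end for gene(s): ", paste(genes$gene_id[bad], collapse = ", "))
  }
  unknown <- !(genes$chr %in% layout$chrom)
  if (any(unknown)) {
    stop("gene(s) on chromosome absent from layout: ",
         paste(genes$gene_id[unknown], collapse = ", "))
  }
  len <- setNames(layout$length, layout$chrom)
  over <- genes$end > len[genes$chr] | genes$start < 0
  if (any(over)) {
    stop("gene(s) outside chromosome bounds: ",
         paste(genes$gene_id[over], collapse = ", "))
  }
  if (!all(genes$biotype %in% c("protein_coding", "other"))) {
    stop("biotype must be 'protein_coding' or 'other'")
  }
  invisible(genes)
}

#' Significant sites of one association study
#'
#' Container for a study's sites passing its p-value threshold, with study
#' metadata. Construction is a pure filter contract: every retained site has
#' `p < threshold`.
#'
#' @param sites data.frame with columns `site_id`, `chr`, `pos`, `p` and
#'   optionally `effect`.
#' @param trait Trait label.
#' @param study_type `"gwas"` or `"ewas"`.
#' @param threshold Significance threshold the sites were filtered at.
#' @param sample_size Optional study sample size.
#' @return An object of class `study_hits`.
#' @export
study_hits <- function(sites, trait = "", study_type = c("gwas", "ewas"),
                       threshold = NULL, sample_size = NULL) {
  study_type <- match.arg(study_type)
  threshold <- threshold %||% default_threshold(study_type)
  need <- c("site_id", "chr", "pos", "p")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites missing column(s): ", paste(miss, collapse = ", "))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$site_id <- as.character(sites$site_id)
  sites$chr <- as.character(sites$chr)
  if (nrow(sites) && (any(sites$p <= 0) || any(sites$p > 1))) {
    stop("p-values must lie in (0, 1]")
  }
  if (nrow(sites) && any(sites$p >= threshold)) {
    stop("all sites must satisfy p < threshold")
  }
  structure(list(trait = trait, study_type = study_type, sites = sites,
                 threshold = threshold, sample_size = sample_size),
            class = "study_hits")
}

#' @export
print.study_hits <- function(x, ...) {
  cat(sprintf("<study_hits> %s %s: %d sites at p < %g\n",
              toupper(x$study_type), x$trait, nrow(x$sites), x$threshold))
  invisible(x)
}

default_threshold <- function(study_type) {
  switch(study_type, gwas = 5e-8, ewas = 1e-7)
}

#' Run configuration
#'
#' Collects every tunable constant of the pipeline in one explicit place:
#' significance thresholds, the region width for genome binning, the gene
#' universe mode for the 2x2 tables, the number of resampling replicates and
#' the master RNG seed.
#'
#' @param rng_seed Integer master seed; all stochastic stages derive child
#'   streams from it via [child_seed()].
#' @param gwas_p,ewas_p Genome-wide / epigenome-wide significance thresholds.
#' @param region_p Lenient threshold for the region co-occurrence analysis;
#'   resolved per trait as `min(region_p, max reported EWAS p)`.
#' @param region_width Region width in bp for genome binning.
#' @param universe_mode Gene universe for overlap tables: all genes or
#'   protein-coding only.
#' @param resample_reps Number of null-resampling replicates.
#' @return An object of class `run_config`.
#' @export
run_config <- function(rng_seed = 1L, gwas_p = 5e-8, ewas_p = 1e-7,
                       region_p = 1e-5, region_width = 5e5,
                       universe_mode = c("all_genes", "protein_coding"),
                       resample_reps = 1000L) {
  universe_mode <- match.arg(universe_mode)
  stopifnot(region_width > 0, resample_reps >= 1,
            gwas_p > 0, gwas_p <= 1, ewas_p > 0, ewas_p <= 1,
            region_p > 0, region_p <= 1)
  structure(list(rng_seed = as.integer(rng_seed), gwas_p = gwas_p,
                 ewas_p = ewas_p, region_p = region_p,
                 region_width = region_width, universe_mode = universe_mode,
                 resample_reps = as.integer(resample_reps)),
            class = "run_config")
}

# Column-name aliases accepted in summary-statistics tables.
.col_aliases <- list(
  site_id = c("site_id", "id", "snp", "cpg", "probe_id", "rsid", "marker"),
  chr     = c("chr", "chrom", "chromosome"),
  pos     = c("pos", "position", "bp", "base_pair"),
  p       = c("p", "pval", "p_value", "pvalue", "p.value"),
  effect  = c("effect", "beta", "b", "estimate")
)

# Read a raw summary-statistics table with canonical column names; no
# threshold filtering. Row-level parse failures are fatal and name the
# offending file lines (header is line 1).
read_site_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  names(dt) <- tolower(names(dt))
  for (canon in names(.col_aliases)) {
    hit <- intersect(.col_aliases[[canon]], names(dt))
    if (length(hit)) names(dt)[match(hit[1], names(dt))] <- canon
  }
  required <- c("site_id", "chr", "pos", "p")
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop("summary-statistics file ", path,
         " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  dt$chr <- as.character(dt$chr)
  for (col in c("pos", "p")) {
    raw <- dt[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad)) {
      stop("unparseable ", col, " in ", path, " at line(s): ",
           paste(bad + 1L, collapse = ", "))
    }
    dt[[col]] <- val
  }
  if (any(dt$p <= 0 | dt$p > 1)) {
    bad <- which(dt$p <= 0 | dt$p > 1)
    stop("p-values outside (0, 1] in ", path, " at line(s): ",
         paste(bad + 1L, collapse = ", "))
  }
  dt[, intersect(c("site_id", "chr", "pos", "p", "effect"), names(dt))]
}

#' Read study summary statistics and keep sites passing a threshold
#'
#' Reads a delimited table (columns: site id, chromosome, position, p-value,
#' optional effect) and returns a [study_hits()] holding only rows with
#' `p < threshold`. Rows with unparseable positions or p-values abort with
#' the offending line numbers.
#'
#' @param path Path to the delimited table.
#' @param study_type `"gwas"` or `"ewas"`; also sets the default threshold
#'   (5e-8 and 1e-7 respectively).
#' @param threshold Significance threshold in (0, 1]; `NULL` uses the
#'   study-type default.
#' @param trait Trait label carried in the result.
#' @return A [study_hits()].
#' @export
read_summary_stats <- function(path, study_type = c("gwas", "ewas"),
                               threshold = NULL, trait = "") {
  study_type <- match.arg(study_type)
  threshold <- threshold %||% default_threshold(study_type)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  dt <- read_site_table(path)
  keep <- dt$p < threshold
  message(sprintf("%s: %d of %d sites pass p < %g (%d discarded)",
                  basename(path), sum(keep), nrow(dt), threshold,
                  sum(!keep)))
  study_hits(dt[keep, , drop = FALSE], trait = trait,
             study_type = study_type, threshold = threshold)
}

#' Gene-to-geneset annotation over a declared gene universe
#'
#' Holds the bidirectional gene/geneset map: the member sets, the inverse
#' (gene to geneset ids) map, and a sparse membership matrix
#' (genes x genesets) used by the enrichment computations.
#'
#' @param sets Named list of character vectors of member gene ids.
#' @param universe Optional explicit gene universe; defaults to the union of
#'   all members. Every member must belong to it.
#' @return An object of class `geneset_annotation`.
#' @export
geneset_annotation <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "") || anyDuplicated(names(sets))) {
    stop("sets must be a uniquely named list")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(members)
  } else {
    universe <- unique(as.character(universe))
    out <- setdiff(members, universe)
    if (length(out)) {
      stop("geneset member(s) outside universe: ",
           paste(head(out, 5), collapse = ", "))
    }
  }
  gi <- unlist(lapply(sets, function(g) match(g, universe)), use.names = FALSE)
  sj <- rep(seq_along(sets), lengths(sets))
  membership <- Matrix::sparseMatrix(
    i = gi, j = sj, dims = c(length(universe), length(sets)),
    dimnames = list(universe, names(sets)))
  inv_df <- data.frame(gene = unlist(sets, use.names = FALSE),
                       set = rep(names(sets), lengths(sets)),
                       stringsAsFactors = FALSE)
  inverse <- split(inv_df$set, inv_df$gene)
  structure(list(universe = universe, sets = sets, inverse = inverse,
                 membership = membership,
                 set_sizes = setNames(lengths(sets), names(sets))),
            class = "geneset_annotation")
}

#' @export
print.geneset_annotation <- function(x, ...) {
  cat(sprintf("<geneset_annotation> %d genesets over %d genes (sizes %d-%d)\n",
              length(x$sets), length(x$universe),
              min(x$set_sizes), max(x$set_sizes)))
  invisible(x)
}

#' Read genesets from a GMT file
#'
#' Standard GMT: one geneset per line, tab-separated fields
#' `id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to the GMT file.
#' @param universe Optional explicit gene universe (default: union of
#'   members).
#' @return A [geneset_annotation()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line(s) with fewer than 3 fields in ", path, ": line(s) ",
         paste(which(keep)[nf < 3], collapse = ", "))
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate geneset id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- ids
  geneset_annotation(sets, universe = universe)
}

#' Write a geneset annotation to a GMT file
#' @param annotation A [geneset_annotation()].
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to the set id).
#' @export
write_gmt <- function(annotation, path, descriptions = NULL) {
  ids <- names(annotation$sets)
  desc <- if (is.null(descriptions)) ids else descriptions[ids]
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], desc[i], annotation$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome layout and gene models
#'
#' @param path_sizes Two-column chrom.sizes table (chromosome, length), no
#'   header.
#' @param path_genes Delimited gene table with columns `gene_id`, `chr`,
#'   `start`, `end`, `biotype` and a header. Coordinates are taken as
#'   0-based half-open (BED-style) unless `one_based = TRUE`, in which case
#'   1-based inclusive coordinates are converted on read.
#' @param one_based Whether the gene table uses 1-based inclusive
#'   coordinates.
#' @param build_label Assembly label recorded in the layout.
#' @return A list with elements `layout` ([genome_layout()]) and `genes`
#'   (validated data.frame).
#' @export
read_genome <- function(path_sizes, path_genes, one_based = FALSE,
                        build_label = "custom") {
  sizes <- data.table::fread(path_sizes, header = FALSE, data.table = FALSE)
  if (ncol(sizes) < 2) stop("chrom.sizes must have two columns")
  layout <- genome_layout(sizes[[1]], sizes[[2]], build_label = build_label)
  genes <- data.table::fread(path_genes, header = TRUE, data.table = FALSE)
  names(genes) <- tolower(names(genes))
  if ("chrom" %in% names(genes) && !("chr" %in% names(genes))) {
    names(genes)[names(genes) == "chrom"] <- "chr"
  }
  if (one_based) {
    genes$start <- genes$start - 1
  }
  validate_genes(genes, layout)
  list(layout = layout, genes = genes)
}

#' Write a results table as locale-independent TSV
#'
#' @param rows A data.frame (or list of homogeneous records coercible to
#'   one).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results_table <- function(rows, path) {
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' Write JSON run metadata (config, seed, input digests)
#' @param config A [run_config()].
#' @param path Output JSON path.
#' @param inputs Named character vector of input file paths to digest.
#' @export
write_run_metadata <- function(config, path, inputs = character()) {
  meta <- list(config = unclass(config),
               package_version = as.character(utils::packageVersion("epioverlap")),
               inputs = if (length(inputs)) {
                 as.list(tools::md5sum(inputs))
               } else NULL)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
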