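#' Tile the genome into fixed-width regions
#'
#' Divides every chromosome into consecutive `width`-bp blocks; the last
#' block of each chromosome may be short. The blocks are disjoint and tile
#' each chromosome exactly.
#'
#' @param layout A [genome_layout()].
#' @param width Region width in bp (default 500 kb).
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
bin_genome <- function(layout, width = 5e5) {
  stopifnot(width > 0)
  parts <- lapply(seq_along(layout$chrom), function(i) {
    L <- layout$length[i]
    starts <- seq(0, L - 1, by = width)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + width, L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- cbind(region_id = sprintf("R%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Index of the region containing each (chrom, pos); NA where no region
# covers the position. Regions within a chromosome must be sorted, disjoint.
.region_index <- function(regions, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (cn in unique(chrom)) {
    rsub <- which(regions$chrom == cn)
    sel <- which(chrom == cn)
    if (!length(rsub)) next
    k <- findInterval(pos[sel], regions$start[rsub])
    ok <- k >= 1
    ok[ok] <- pos[sel][ok] < regions$end[rsub][k[ok]]
    idx[sel[ok]] <- rsub[k[ok]]
  }
  idx
}

#' Keep only regions containing at least one measured probe
#'
#' Mirrors the restriction of the region analysis to blocks covered by the
#' methylation array: a region with no measured CpG probe cannot be
#' identified by an EWAS and is removed. Order is preserved.
#'
#' @param regions Regions from [bin_genome()].
#' @param probes data.frame of probe positions (`chr`, `pos`).
#' @return The subset of `regions` containing at least one probe, with a
#'   `contains_probe` column set.
#' @export
filter_regions <- function(regions, probes) {
  idx <- .region_index(regions, probes$chr, probes$pos)
  keep <- sort(unique(idx[!is.na(idx)]))
  out <- regions[keep, , drop = FALSE]
  out$contains_probe <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Resolve the region-analysis p-value threshold
#'
#' The region threshold is a lenient 1e-5, or the maximum p-value the EWAS
#' reports if that is lower.
#'
#' @param ewas_max_p Maximum reported EWAS p-value.
#' @param lenient The lenient default threshold.
#' @return The resolved threshold.
#' @export
resolve_region_threshold <- function(ewas_max_p, lenient = 1e-5) {
  out <- min(lenient, ewas_max_p)
  message(sprintf("region threshold resolved to %g (lenient %g, max EWAS p %g)",
                  out, lenient, ewas_max_p))
  out
}

#' Tally regions by GWAS/EWAS co-occurrence
#'
#' Assigns each region to exactly one of four categories -- neither,
#' GWAS-only, EWAS-only, or both -- according to whether one or more GWAS
#' and/or EWAS sites below the region threshold fall in it.
#'
#' @param regions Filtered regions ([filter_regions()]).
#' @param gwas,ewas [study_hits()] objects (or data.frames of sites with
#'   `chr`, `pos`, `p`).
#' @param region_p Optional threshold re-applied to both site lists (see
#'   [resolve_region_threshold()]); `NULL` uses the sites as supplied.
#' @return An object of class `region_tally`: `counts` (named vector over
#'   the four categories) and `regions` (per-region category).
#' @export
tally_regions <- function(regions, gwas, ewas, region_p = NULL) {
  gs <- if (inherits(gwas, "study_hits")) gwas$sites else gwas
  es <- if (inherits(ewas, "study_hits")) ewas$sites else ewas
  if (!is.null(region_p)) {
    gs <- gs[gs$p < region_p, , drop = FALSE]
    es <- es[es$p < region_p, , drop = FALSE]
  }
  for (df in list(gs, es)) {
    bad <- setdiff(unique(df$chr), unique(regions$chrom))
    if (length(bad)) {
      stop("site(s) on chromosome(s) absent from regions: ",
           paste(bad, collapse = ", "))
    }
  }
  g_idx <- .region_index(regions, gs$chr, gs$pos)
  e_idx <- .region_index(regions, es$chr, es$pos)
  has_g <- seq_len(nrow(regions)) %in% g_idx
  has_e <- seq_len(nrow(regions)) %in% e_idx
  category <- ifelse(has_g & has_e, "both",
              ifelse(has_g, "gwas_only",
              ifelse(has_e, "ewas_only", "neither")))
  counts <- c(neither = sum(category == "neither"),
              gwas_only = sum(category == "gwas_only"),
              ewas_only = sum(category == "ewas_only"),
              both = sum(category == "both"))
  stopifnot(sum(counts) == nrow(regions))
  structure(list(counts = counts,
                 regions = cbind(regions,
                                 category = category,
                                 stringsAsFactors = FALSE)),
            class = "region_tally")
}

#' @export
print.region_tally <- function(x, ...) {
  cat("<region_tally>\n")
  print(x$counts)
  invisible(x)
}

#' Can the largest GWAS effect in a region predict an EWAS hit there?
#'
#' Scores each region by the largest absolute GWAS effect estimate among its
#' GWAS sites and labels it by whether any EWAS hit falls in it; reports the
#' AUC of the score for the label. Regions with no effect-bearing GWAS site
#' are dropped (and counted).
#'
#' @param regions Filtered regions.
#' @param gwas_sites data.frame of GWAS sites with `chr`, `pos`, `effect`.
#' @param ewas A [study_hits()] (or site data.frame) for the EWAS.
#' @return A list: `auc` (with 95% CI, via [rank_auc()]), `n_regions`,
#'   `n_dropped`.
#' @export
region_effect_auc <- function(regions, gwas_sites, ewas) {
  es <- if (inherits(ewas, "study_hits")) ewas$sites else ewas
  gs <- gwas_sites[!is.na(gwas_sites$effect), , drop = FALSE]
  g_idx <- .region_index(regions, gs$chr, gs$pos)
  keep <- !is.na(g_idx)
  score_by_region <- tapply(abs(gs$effect[keep]), g_idx[keep], max)
  region_ids <- as.integer(names(score_by_region))
  e_idx <- .region_index(regions, es$chr, es$pos)
  labels <- as.integer(region_ids %in% e_idx)
  n_dropped <- nrow(regions) - length(region_ids)
  if (n_dropped > 0) {
    message(n_dropped, " region(s) without a GWAS effect estimate dropped")
  }
  if (length(unique(labels)) < 2) {
    stop("AUC undefined: all retained regions have the same EWAS label")
  }
  auc <- rank_auc(as.numeric(score_by_region), labels)
  list(auc = auc, n_regions = length(region_ids), n_dropped = n_dropped)
}

#' Map sites to genes by position (nearest gene, many-to-many)
#'
#' A site inside one or more gene bodies maps to all of those genes;
#' otherwise it maps to the gene(s) at minimum distance from the site to the
#' nearer gene edge on the same chromosome (equidistant genes on both sides
#' all map). Mapping never crosses chromosomes; sites on chromosomes bearing
#' no genes are left unmapped with a warning.
#'
#' @param sites data.frame with `site_id`, `chr`, `pos`.
#' @param genes Gene table (`gene_id`, `chr`, `start`, `end`).
#' @param chunk Sites processed per vectorised block (memory/speed
#'   trade-off).
#' @return A list: `genes` (character vector of mapped gene ids), `map`
#'   (data.frame site_id, gene_id, distance; distance 0 means the site lies
#'   within the gene body), `unmapped` (site ids with no gene on their
#'   chromosome).
#' @export
map_sites_to_genes <- function(sites, genes, chunk = 1024L) {
  maps <- list()
  unmapped <- character()
  for (cn in unique(sites$chr)) {
    s <- sites[sites$chr == cn, , drop = FALSE]
    g <- genes[genes$chr == cn, , drop = FALSE]
    if (!nrow(g)) {
      unmapped <- c(unmapped, s$site_id)
      next
    }
    m <- nrow(g)
    for (lo in seq(1, nrow(s), by = chunk)) {
      hi <- min(lo + chunk - 1L, nrow(s))
      q <- s$pos[lo:hi]
      n <- length(q)
      # distance from site q to gene [start, end): 0 inside, else gap to
      # the nearer edge (last base is end - 1)
      D <- pmax(outer(g$start, q, `-`), outer(-(g$end - 1), q, `+`), 0)
      dmin <- apply(D, 2L, min)
      w <- which(D == rep(dmin, each = m))
      gi <- ((w - 1L) %% m) + 1L
      si <- ((w - 1L) %/% m) + 1L
      maps[[length(maps) + 1L]] <- data.frame(
        site_id = s$site_id[lo:hi][si],
        gene_id = g$gene_id[gi],
        distance = dmin[si],
        stringsAsFactors = FALSE)
    }
  }
  if (length(unmapped)) {
    warning(length(unmapped), " site(s) on chromosomes without genes left unmapped")
  }
  map <- if (length(maps)) do.call(rbind, maps) else {
    data.frame(site_id = character(), gene_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  }
  list(genes = unique(map$gene_id), map = map, unmapped = unmapped)
}
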