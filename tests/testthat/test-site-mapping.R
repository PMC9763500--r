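test_that("genome binning tiles each chromosome exactly", {
  lay <- genome_layout(c("chr1", "chr2"), c(1e6, 1.2e6))
  r <- bin_genome(lay, 5e5)
  expect_equal(sum(r$chrom == "chr1"), 2)
  expect_equal(sum(r$chrom == "chr2"), 3)
  expect_equal(r$end[nrow(r)] - r$start[nrow(r)], 2e5)
  # tiling invariant: per-chromosome lengths sum to the chromosome length,
  # blocks are disjoint and consecutive
  for (cn in lay$chrom) {
    rc <- r[r$chrom == cn, ]
    expect_equal(sum(rc$end - rc$start),
                 lay$length[match(cn, lay$chrom)])
    expect_true(all(rc$start[-1] == rc$end[-nrow(rc)]))
  }
})

test_that("region counts match brute-force tiling over a 22-chromosome layout", {
  set.seed(7)
  lens <- sort(round(runif(22, 4e5, 8e6)), decreasing = TRUE)
  lay <- genome_layout(paste0("chr", 1:22), lens)
  width <- 5e5
  r <- bin_genome(lay, width)
  expect_equal(nrow(r), sum(ceiling(lens / width)))
  # brute-force per-chromosome tiling oracle
  for (i in c(1, 10, 22)) {
    starts <- seq(0, lens[i] - 1, by = width)
    rc <- r[r$chrom == lay$chrom[i], ]
    expect_equal(rc$start, starts)
    expect_equal(rc$end, pmin(starts + width, lens[i]))
  }
})

test_that("probe filtering keeps exactly the regions holding a probe", {
  lay <- genome_layout("chr1", 2e6)
  r <- bin_genome(lay, 5e5)  # 4 regions
  expect_equal(nrow(filter_regions(r, data.frame(chr = character(),
                                                 pos = numeric()))), 0)
  one_each <- data.frame(chr = "chr1", pos = c(1, 6e5, 1.1e6, 1.9e6))
  expect_equal(nrow(filter_regions(r, one_each)), 4)
  # random probes: equals an O(n*m) membership scan
  set.seed(3)
  probes <- data.frame(chr = "chr1", pos = floor(runif(15, 0, 2e6)))
  kept <- filter_regions(r, probes)
  manual <- vapply(seq_len(nrow(r)), function(i) {
    any(probes$pos >= r$start[i] & probes$pos < r$end[i])
  }, logical(1))
  expect_equal(kept$region_id, r$region_id[manual])
})

test_that("region tallies partition the regions into the four categories", {
  lay <- genome_layout("chr1", 2e6)
  r <- bin_genome(lay, 5e5)
  r$contains_probe <- TRUE
  empty <- data.frame(site_id = character(), chr = character(),
                      pos = numeric(), p = numeric())
  t0 <- tally_regions(r, empty, empty)
  expect_equal(unname(t0$counts["neither"]), 4)
  expect_equal(sum(t0$counts), 4)

  g <- data.frame(site_id = "rs1", chr = "chr1", pos = 1e5, p = 1e-9)
  e <- data.frame(site_id = "cg1", chr = "chr1", pos = 2e5, p = 1e-9)
  t1 <- tally_regions(r, g, e)
  expect_equal(unname(t1$counts["both"]), 1)
  expect_equal(unname(t1$counts["neither"]), 3)

  # random hits equal a brute-force interval-membership oracle
  set.seed(11)
  g <- data.frame(site_id = paste0("rs", 1:20), chr = "chr1",
                  pos = floor(runif(20, 0, 2e6)), p = runif(20, 0, 1e-6))
  e <- data.frame(site_id = paste0("cg", 1:20), chr = "chr1",
                  pos = floor(runif(20, 0, 2e6)), p = runif(20, 0, 1e-6))
  tt <- tally_regions(r, g, e, region_p = 1e-6)
  for (i in seq_len(nrow(r))) {
    in_g <- any(g$p < 1e-6 & g$pos >= r$start[i] & g$pos < r$end[i])
    in_e <- any(e$p < 1e-6 & e$pos >= r$start[i] & e$pos < r$end[i])
    want <- if (in_g && in_e) "both" else if (in_g) "gwas_only"
            else if (in_e) "ewas_only" else "neither"
    expect_equal(tt$regions$category[i], want)
  }
  expect_equal(sum(tt$counts), nrow(r))
  expect_error(tally_regions(r, data.frame(site_id = "x", chr = "chrZ",
                                           pos = 1, p = 1e-9), e),
               "absent from regions")
})

test_that("the region threshold resolves to the lower of lenient and max EWAS p", {
  expect_equal(suppressMessages(resolve_region_threshold(0.9)), 1e-5)
  expect_equal(suppressMessages(resolve_region_threshold(1e-6)), 1e-6)
})

test_that("sites map to containing genes, and to all tied nearest genes", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chr = "chr1",
                      start = c(1000, 8000, 20001),
                      end = c(10000, 12000, 21000),
                      biotype = "protein_coding")
  inside <- data.frame(site_id = "s1", chr = "chr1", pos = 5000)
  m <- map_sites_to_genes(inside, genes)
  expect_equal(m$genes, "gA")
  expect_equal(m$map$distance, 0)
  # inside two overlapping genes -> both
  both <- data.frame(site_id = "s2", chr = "chr1", pos = 9000)
  expect_setequal(map_sites_to_genes(both, genes)$genes, c("gA", "gB"))
  # exactly equidistant between gB's last base (11999) and gC's start
  tie <- data.frame(site_id = "s3", chr = "chr1", pos = 16000)
  mt <- map_sites_to_genes(tie, genes)
  expect_setequal(mt$genes, c("gB", "gC"))
  expect_equal(unique(mt$map$distance), 4001)
  # a chromosome without genes leaves the site unmapped, with a warning
  lost <- data.frame(site_id = "s4", chr = "chr9", pos = 1)
  expect_warning(m4 <- map_sites_to_genes(lost, genes), "unmapped")
  expect_equal(m4$unmapped, "s4")
  expect_length(m4$genes, 0)
})

test_that("random mappings equal the all-pairs distance-minimisation oracle", {
  set.seed(19)
  w <- tiny_world(seed = 19, n_genes = 50)
  sites <- data.frame(site_id = sprintf("s%03d", 1:100),
                      chr = sample(w$layout$chrom, 100, replace = TRUE),
                      pos = floor(runif(100, 0, 5e6)))
  m <- map_sites_to_genes(sites, w$genes)
  o <- oracle_map(sites, w$genes)
  key <- function(df) sort(paste(df$site_id, df$gene_id, df$distance))
  expect_equal(key(m$map), key(o))
})

test_that("mapping agrees with a GenomicRanges nearest-gene computation", {
  skip_if_not_installed("GenomicRanges")
  set.seed(23)
  w <- tiny_world(seed = 23, n_genes = 60)
  sites <- data.frame(site_id = sprintf("s%03d", 1:80),
                      chr = sample(w$layout$chrom, 80, replace = TRUE),
                      pos = floor(runif(80, 0, 5e6)))
  m <- map_sites_to_genes(sites, w$genes)
  gr_genes <- GenomicRanges::GRanges(
    w$genes$chr, IRanges::IRanges(w$genes$start + 1, w$genes$end))
  gr_sites <- GenomicRanges::GRanges(
    sites$chr, IRanges::IRanges(sites$pos + 1, sites$pos + 1))
  hits <- GenomicRanges::nearest(gr_sites, gr_genes, select = "all")
  gr_map <- data.frame(site_id = sites$site_id[S4Vectors::queryHits(hits)],
                       gene_id = w$genes$gene_id[S4Vectors::subjectHits(hits)])
  key <- function(df) sort(paste(df$site_id, df$gene_id))
  expect_equal(key(m$map), key(gr_map))
})

test_that("mapped gene sets shrink monotonically as the threshold tightens", {
  w <- tiny_world(seed = 31, n_genes = 100)
  arch <- generate_architecture(w$genes, 30, 30, 0, seed = 1)
  st <- generate_study(arch, study_design("ewas", power = 0.9,
                                          panel_density = 20),
                       w$layout, w$genes, seed = 2)
  thresholds <- c(1e-3, 1e-5, 1e-7, 1e-12)
  sets <- lapply(thresholds, function(t) {
    map_sites_to_genes(st$sites[st$sites$p < t, ], w$genes)$genes
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("the region effect AUC behaves at its forced limits", {
  lay <- genome_layout("chr1", 3e6)
  r <- bin_genome(lay, 1e6)  # 3 regions
  gwas <- data.frame(site_id = paste0("rs", 1:3), chr = "chr1",
                     pos = c(1e5, 1.5e6, 2.5e6), p = 1e-9,
                     effect = c(3, 2, 1))
  ewas <- data.frame(site_id = "cg1", chr = "chr1", pos = 2e5, p = 1e-9)
  res <- suppressWarnings(region_effect_auc(r, gwas, ewas))
  expect_equal(res$auc$auc, 1)
  # labels independent of scores at larger n: AUC near 1/2
  set.seed(5)
  lay2 <- genome_layout("chr1", 4e8)
  r2 <- bin_genome(lay2, 5e5)
  gwas2 <- data.frame(site_id = paste0("rs", seq_len(nrow(r2))), chr = "chr1",
                      pos = r2$start + 100, p = 1e-9,
                      effect = rnorm(nrow(r2)))
  lab <- sample(c(TRUE, FALSE), nrow(r2), replace = TRUE)
  ewas2 <- data.frame(site_id = paste0("cg", seq_len(sum(lab))), chr = "chr1",
                      pos = r2$start[lab] + 200, p = 1e-9)
  res2 <- region_effect_auc(r2, gwas2, ewas2)
  expect_lt(abs(res2$auc$auc - 0.5), 0.06)
  # all labels identical -> undefined AUC
  expect_error(region_effect_auc(r, gwas,
                                 data.frame(site_id = character(),
                                            chr = character(),
                                            pos = numeric(), p = numeric())),
               "AUC undefined")
})
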