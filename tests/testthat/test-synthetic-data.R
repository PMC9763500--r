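test_that("synthetic genomes have the requested shape and are deterministic", {
  w <- generate_genome(2, 1e7, 200, c(1e3, 5e4), seed = 1)
  expect_equal(nrow(w$genes), 200)
  expect_s3_class(w$layout, "genome_layout")
  w2 <- generate_genome(2, 1e7, 200, c(1e3, 5e4), seed = 1)
  expect_identical(w, w2)
  w0 <- generate_genome(2, 1e7, 0, c(1e3, 5e4), seed = 1)
  expect_equal(nrow(w0$genes), 0)
  expect_equal(length(w0$layout$chrom), 2)
  expect_error(generate_genome(1, 1e4, 50, c(1e3, 2e3), seed = 1),
               "infeasible packing")
})

test_that("gene coordinates respect the layout and genes never overlap", {
  for (seed in 1:5) {
    w <- generate_genome(3, 2e6, 80, c(1e3, 3e4), seed = seed)
    len <- setNames(w$layout$length, w$layout$chrom)
    expect_true(all(w$genes$start >= 0))
    expect_true(all(w$genes$end <= len[w$genes$chr]))
    expect_true(all(w$genes$start < w$genes$end))
    for (cn in unique(w$genes$chr)) {
      g <- w$genes[w$genes$chr == cn, ]
      g <- g[order(g$start), ]
      if (nrow(g) > 1) {
        expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
      }
    }
  }
})

test_that("geneset sizes respect bounds and the broad/narrow split", {
  w <- generate_genome(2, 1e7, 200, c(1e3, 2e4), seed = 3)
  ann <- generate_genesets(w$genes, 100, c(5, 150), broad_fraction = 0.4,
                           seed = 2)
  expect_true(all(ann$set_sizes >= 5 & ann$set_sizes <= 150))
  expect_equal(sum(ann$set_sizes > 100), 40)
  narrow <- generate_genesets(w$genes, 50, c(5, 150), broad_fraction = 0,
                              seed = 2)
  expect_equal(sum(narrow$set_sizes > 100), 0)
  expect_identical(generate_genesets(w$genes, 30, c(5, 150), 0.4, seed = 9),
                   generate_genesets(w$genes, 30, c(5, 150), 0.4, seed = 9))
  expect_error(generate_genesets(w$genes[1:20, ], 10, c(5, 150), 0, seed = 1),
               "exceeds universe")
})

test_that("trait architectures realise the requested overlap exactly", {
  w <- generate_genome(2, 2e7, 1000, c(1e3, 1e4), seed = 4)
  a0 <- generate_architecture(w$genes, 100, 100, 0, seed = 1)
  expect_length(intersect(a0$causal_genes, a0$associated_genes), 0)
  expect_length(a0$causal_genes, 100)
  expect_length(a0$associated_genes, 100)
  a1 <- generate_architecture(w$genes, 100, 100, 1, seed = 1)
  expect_setequal(a1$causal_genes, a1$associated_genes)
  ah <- generate_architecture(w$genes, 100, 100, 0.5, seed = 1)
  expect_length(intersect(ah$causal_genes, ah$associated_genes), 50)
  # overlap proportion recoverable from the emitted sets for varied p
  for (p in c(0, 0.13, 0.5, 0.77, 1)) {
    a <- generate_architecture(w$genes, 200, 150, p, seed = 7)
    expect_equal(length(intersect(a$causal_genes, a$associated_genes)),
                 round(p * 150))
  }
  expect_error(generate_architecture(w$genes[1:50, ], 40, 40, 0, seed = 1),
               "infeasible")
})

test_that("at power 1 with no background, mapping recovers exactly the signal genes", {
  w <- generate_genome(3, 5e6, 150, c(2e3, 2e4), seed = 11)
  arch <- generate_architecture(w$genes, 40, 40, 0.5, seed = 2)
  des <- study_design("ewas", power = 1, n_sites_per_gene = 2,
                      panel_density = 0)
  st <- generate_study(arch, des, w$layout, w$genes, seed = 3)
  hits <- st$sites[st$sites$p < des$threshold, ]
  mapped <- map_sites_to_genes(hits, w$genes)
  expect_setequal(mapped$genes, arch$associated_genes)
  expect_setequal(st$detected_genes, arch$associated_genes)
})

test_that("detected-gene counts follow the binomial law of the study power", {
  w <- generate_genome(4, 2e7, 400, c(2e3, 1e4), seed = 21)
  arch <- generate_architecture(w$genes, 200, 200, 0, seed = 2)
  des <- study_design("gwas", power = 0.8, n_sites_per_gene = 1,
                      panel_density = 0)
  st <- generate_study(arch, des, w$layout, w$genes, seed = 5)
  # central 99% binomial(200, 0.8) interval computed from the binomial law
  bounds <- qbinom(c(0.005, 0.995), 200, 0.8)
  expect_gte(length(st$detected_genes), bounds[1])
  expect_lte(length(st$detected_genes), bounds[2])
  # at power 0 no gene is detected
  st0 <- generate_study(arch, study_design("gwas", power = 0,
                                           n_sites_per_gene = 1,
                                           panel_density = 0),
                        w$layout, w$genes, seed = 5)
  expect_length(st0$detected_genes, 0)
})

test_that("emitted study coordinates always respect the genome layout", {
  for (seed in 1:4) {
    w <- generate_genome(2, 3e6, 60, c(2e3, 1e4), seed = seed)
    arch <- generate_architecture(w$genes, 20, 20, 0.5, seed = seed)
    st <- generate_study(arch, study_design("ewas", power = 0.5,
                                            panel_density = 5),
                         w$layout, w$genes, seed = seed)
    len <- setNames(w$layout$length, w$layout$chrom)
    expect_true(all(st$sites$pos >= 0))
    expect_true(all(st$sites$pos < len[st$sites$chr]))
    expect_true(all(st$sites$p > 0 & st$sites$p <= 1))
  }
})

test_that("a simulated bundle round-trips through the file formats", {
  dir <- withr::local_tempdir()
  b <- suppressMessages(simulate_trait_bundle(
    dir, n_genes = 200, n_sets = 30, n_causal = 40, n_associated = 40,
    overlap_proportion = 0.5, seed = 13))
  gen <- read_genome(b$paths$chrom_sizes, b$paths$genes)
  expect_equal(gen$genes$gene_id, b$genes$gene_id)
  expect_equal(gen$layout$length, b$layout$length)
  ann <- read_gmt(b$paths$gmt, universe = b$annotation$universe)
  expect_equal(lapply(ann$sets, sort), lapply(b$annotation$sets, sort))
  truth <- jsonlite::read_json(b$paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$causal_genes, b$architecture$causal_genes)
  hits <- suppressMessages(read_summary_stats(b$paths$ewas, "ewas"))
  expect_true(all(hits$sites$p < 1e-7))
})
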