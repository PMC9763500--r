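test_that("summary-statistics reading is a pure threshold filter", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(site_id = paste0("cg", 1:5), chr = "chr1",
                   pos = c(100, 200, 300, 400, 500),
                   p = c(1e-9, 0.5, 1e-8, 0.2, 1e-3))
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- suppressMessages(read_summary_stats(tf, "ewas"))
  expect_s3_class(hits, "study_hits")
  expect_equal(nrow(hits$sites), 2)
  expect_setequal(hits$sites$site_id, c("cg1", "cg3"))
  expect_true(all(hits$sites$p < 1e-7))
  # retained rows are a subset of the input
  expect_true(all(hits$sites$site_id %in% df$site_id))
})

test_that("an empty table yields zero hits without error", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("site_id\tchr\tpos\tp", tf)
  hits <- suppressMessages(read_summary_stats(tf, "gwas"))
  expect_equal(nrow(hits$sites), 0)
})

test_that("unparseable rows and missing columns are reported by location", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site_id\tchr\tpos\tp",
               "cg1\tchr1\t100\t1e-9",
               "cg2\tchr1\t200\tNA",
               "cg3\tchr1\t300\tnot_a_number"), tf)
  expect_error(read_summary_stats(tf, "ewas"), "line\\(s\\): 3, 4")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site_id\tchr\tpos", "cg1\tchr1\t100"), tf2)
  expect_error(read_summary_stats(tf2, "ewas"), "missing required column.*p")
})

test_that("GMT reading builds the exact transpose and is idempotent", {
  tf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tB\tC"), tf)
  ann <- read_gmt(tf)
  expect_setequal(ann$universe, c("A", "B", "C"))
  expect_setequal(ann$inverse[["B"]], c("S1", "S2"))
  expect_equal(ann$inverse[["A"]], "S1")
  # inverse is the exact transpose of sets
  for (g in ann$universe) {
    member_of <- names(ann$sets)[vapply(ann$sets, function(s) g %in% s, logical(1))]
    expect_setequal(ann$inverse[[g]] %||% character(), member_of)
  }
  expect_identical(ann, read_gmt(tf))

  tf2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("GS1\tdesc\tG1", tf2)
  expect_equal(read_gmt(tf2)$sets, list(GS1 = "G1"))

  tf3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), tf3)
  expect_error(read_gmt(tf3), "duplicate geneset")
  tf4 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "S2\tonly_two_fields"), tf4)
  expect_error(read_gmt(tf4), "fewer than 3 fields.*2")
})

test_that("geneset annotation transpose equality holds after any construction path", {
  w <- tiny_world(seed = 5, n_genes = 100, n_sets = 15)
  ann <- w$annotation
  M <- as.matrix(ann$membership)
  for (s in names(ann$sets)) {
    expect_setequal(rownames(M)[M[, s]], ann$sets[[s]])
  }
  # round trip through GMT preserves the annotation
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, tf)
  ann2 <- read_gmt(tf, universe = ann$universe)
  expect_equal(lapply(ann2$sets, sort), lapply(ann$sets, sort))
  expect_identical(ann2$universe, ann$universe)
})

test_that("genome reading validates gene records against the layout", {
  sizes <- withr::local_tempfile(fileext = ".sizes")
  writeLines("chr1\t1000000", sizes)
  gf <- withr::local_tempfile(fileext = ".tsv")
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chr = "chr1",
                      start = c(0, 5000, 9000), end = c(100, 6000, 9500),
                      biotype = "protein_coding")
  write.table(genes, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  gen <- read_genome(sizes, gf)
  expect_equal(nrow(gen$genes), 3)
  expect_equal(genome_size(gen$layout), 1e6)

  bad <- genes; bad$end[2] <- 2e6
  write.table(bad, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genome(sizes, gf), "outside chromosome bounds.*g2")

  bad <- genes; bad$gene_id[2] <- "g1"
  write.table(bad, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genome(sizes, gf), "duplicate gene_id")

  bad <- genes; bad$start[3] <- bad$end[3]
  write.table(bad, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genome(sizes, gf), "start >= end.*g3")

  bad <- genes; bad$chr[1] <- "chrX"
  write.table(bad, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genome(sizes, gf), "absent from layout.*g1")
})

test_that("results tables round-trip value-identically", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(trait = "bmi", n_ewas_genes = 232L, n_gwas_genes = 3228L,
                   gene_overlap = 23L, obs_or = 2.039, exp_overlap = 3.04,
                   p_diff = 5.2e-2)
  write_results_table(df, tf)
  back <- read_results_table(tf)
  expect_equal(back, df)
  expect_identical(names(back), names(df))
  # empty rows give a header-only file
  write_results_table(df[0, ], tf)
  expect_equal(nrow(read_results_table(tf)), 0)
  expect_identical(names(read_results_table(tf)), names(df))
})

test_that("study_hits enforces its invariants", {
  s <- data.frame(site_id = "cg1", chr = "chr1", pos = 10, p = 0.5)
  expect_error(study_hits(s, study_type = "ewas"), "p < threshold")
  s$p <- 0
  expect_error(study_hits(s, study_type = "ewas"), "\\(0, 1\\]")
})
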