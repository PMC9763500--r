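test_that("the cross-product odds ratio honours the zero and infinity conventions", {
  expect_equal(fisher_or(contingency_table(0, 10, 10, 80))$odds_ratio, 0)
  expect_equal(fisher_or(contingency_table(5, 5, 5, 85))$odds_ratio, 17)
  expect_equal(fisher_or(contingency_table(3, 0, 4, 10))$odds_ratio, Inf)
  expect_equal(fisher_or(contingency_table(2, 3, 4, 0))$odds_ratio, 0)
  expect_error(fisher_or(contingency_table(0, 0, 5, 5)), "empty")
  expect_error(contingency_table(-1, 0, 0, 0), "non-negative")
})

test_that("Fisher p-values equal hypergeometric enumeration over fixed margins", {
  expect_equal(fisher_or(contingency_table(3, 2, 2, 3))$fisher_p,
               oracle_fisher_p(3, 2, 2, 3), tolerance = 1e-10)
  set.seed(1)
  for (i in 1:100) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    cc <- sample(0:8, 1); d <- sample(0:8, 1)
    if (a + b == 0) b <- 1
    expect_equal(fisher_or(contingency_table(a, b, cc, d))$fisher_p,
                 oracle_fisher_p(a, b, cc, d), tolerance = 1e-8,
                 label = sprintf("table (%d,%d,%d,%d)", a, b, cc, d))
  }
})

test_that("Fisher p is invariant to swapping the two lists", {
  set.seed(2)
  for (i in 1:25) {
    t1 <- c(sample(0:10, 1), sample(1:10, 2, replace = TRUE), sample(0:10, 1))
    r1 <- fisher_or(contingency_table(t1[1], t1[2], t1[3], t1[4]))
    r2 <- fisher_or(contingency_table(t1[1], t1[3], t1[2], t1[4]))
    expect_equal(r1$fisher_p, r2$fisher_p, tolerance = 1e-12)
  }
})

test_that("gene overlap builds the 2x2 table by set arithmetic", {
  u <- paste0("g", 1:100)
  same <- gene_overlap(u[1:10], u[1:10], u)
  expect_equal(same$odds_ratio, Inf)
  disjoint <- gene_overlap(u[1:10], u[11:20], u)
  expect_equal(disjoint$odds_ratio, 0)
  expect_equal(disjoint$table$a, 0)
  expect_error(gene_overlap(c(u[1], "missing"), u[1:3], u), "outside universe")
  # random sets over a 500-gene universe equal brute-force set arithmetic
  u <- paste0("g", 1:500)
  set.seed(3)
  for (i in 1:20) {
    e <- sample(u, sample(5:60, 1))
    g <- sample(u, sample(5:60, 1))
    r <- gene_overlap(e, g, u)
    expect_equal(r$table$a, length(intersect(e, g)))
    expect_equal(r$table$b, length(setdiff(e, g)))
    expect_equal(r$table$c, length(setdiff(g, e)))
    expect_equal(r$table$d, 500 - length(union(e, g)))
  }
})

test_that("enrichment scores equal brute-force 2x2 construction per geneset", {
  w <- tiny_world(seed = 8, n_genes = 200, n_sets = 20)
  ann <- w$annotation
  set.seed(8)
  hits <- sample(ann$universe, 30)
  prof <- enrichment_profile(hits, ann)
  n <- length(ann$universe)
  for (s in names(ann$sets)) {
    S <- ann$sets[[s]]
    a <- length(intersect(hits, S))
    b <- length(setdiff(hits, S))
    cc <- length(setdiff(S, hits))
    d <- n - length(union(hits, S))
    want <- if (a == 0) 0 else if (b == 0 || cc == 0) Inf else a * d / (b * cc)
    expect_equal(unname(prof$scores[s]), want, label = s)
  }
  # limits: hits equal to a set -> Inf; hits disjoint from a set -> 0
  sm <- names(which.min(ann$set_sizes))
  p2 <- enrichment_profile(ann$sets[[sm]], ann)
  expect_equal(unname(p2$scores[sm]), Inf)
  off <- setdiff(ann$universe, ann$sets[[sm]])[1:10]
  p3 <- enrichment_profile(off, ann)
  expect_equal(unname(p3$scores[sm]), 0)
  expect_error(enrichment_profile(character(), ann), "empty")
})

test_that("geneset overlap counts identified sets by membership", {
  w <- tiny_world(seed = 9, n_genes = 200, n_sets = 25)
  ann <- w$annotation
  set.seed(9)
  for (i in 1:10) {
    ha <- sample(ann$universe, 15)
    hb <- sample(ann$universe, 15)
    r <- geneset_overlap(ha, hb, ann)
    ia <- vapply(ann$sets, function(s) any(ha %in% s), logical(1))
    ib <- vapply(ann$sets, function(s) any(hb %in% s), logical(1))
    expect_equal(r$table$a, sum(ia & ib))
    expect_equal(r$table$b, sum(ia & !ib))
    expect_equal(r$table$c, sum(!ia & ib))
    expect_equal(r$table$d, sum(!ia & !ib))
  }
})

test_that("enrichment correlation is Spearman on score ranks", {
  mk <- function(scores, ids = sprintf("S%02d", seq_along(scores))) {
    structure(list(study = "x", scores = setNames(scores, ids),
                   hit_genes = "g"), class = "enrichment_profile")
  }
  p1 <- mk(c(0, 1, 2, 5, Inf))
  expect_equal(enrichment_correlation(p1, p1), 1)
  p_rev <- mk(rev(c(0, 1, 2, 5, Inf)))
  expect_equal(enrichment_correlation(p1, p_rev), -1)
  # random profiles equal rank-then-Pearson by hand
  set.seed(4)
  for (i in 1:10) {
    s1 <- sample(c(rexp(46), 0, 0, Inf, Inf))
    s2 <- sample(c(rexp(46), 0, 0, Inf, Inf))
    q1 <- mk(s1); q2 <- mk(s2)
    expect_equal(enrichment_correlation(q1, q2),
                 cor(rank(s1), rank(s2)), tolerance = 1e-12)
  }
  # monotone-transform invariance for strictly positive profiles
  s <- rexp(30) + 0.1
  t <- rexp(30) + 0.1
  expect_identical(enrichment_correlation(mk(s), mk(t)),
                   enrichment_correlation(mk(log(s)), mk(log(t))))
  expect_error(enrichment_correlation(mk(1:2), mk(2:1)), "at least 3")
  expect_error(enrichment_correlation(mk(rep(1, 5)), mk(rexp(5))),
               "zero variance")
  expect_error(enrichment_correlation(mk(rexp(5)),
                                      mk(rexp(4), sprintf("T%02d", 1:4))),
               "different geneset domains")
})

test_that("the z-test against a null matches the normal CDF", {
  nd <- null_distribution(c(1, 2, 3, 4, 5))
  expect_equal(z_test_vs_null(3, nd), 1)
  expect_equal(z_test_vs_null(nd$mean + 1.959964 * nd$sd, nd), 0.05,
               tolerance = 1e-6)
  set.seed(6)
  draws <- rnorm(200, 2, 0.7)
  nd2 <- null_distribution(draws)
  for (obs in c(-1, 0.5, 2, 3.3)) {
    expect_equal(z_test_vs_null(obs, nd2),
                 2 * pnorm(-abs(obs - mean(draws)) / sd(draws)),
                 tolerance = 1e-12)
  }
  expect_error(z_test_vs_null(1, null_distribution(rep(2, 10))),
               "degenerate")
})

test_that("BH q-values equal the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # property: equals the brute-force step-up on random subsets of a p-grid
  grid <- c(0.001, 0.008, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
  set.seed(10)
  for (i in 1:50) {
    p <- sample(grid, sample(2:9, 1), replace = TRUE)
    expect_equal(bh_fdr(p), oracle_bh(p), label = paste(p, collapse = ","))
  }
})

test_that("rank AUC equals pairwise comparison counting", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), ci = FALSE)$auc, 1)
  expect_equal(rank_auc(rep(1, 10), rep(c(0, 1), 5), ci = FALSE)$auc, 0.5)
  expect_equal(rank_auc(c(3, 2, 1), c(1, 0, 0), ci = FALSE)$auc, 1)
  set.seed(12)
  for (i in 1:100) {
    n <- sample(6:14, 1)
    scores <- sample(1:6, n, replace = TRUE) + ifelse(runif(n) < 0.3, 0.5, 0)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    a <- rank_auc(scores, labels, ci = FALSE)$auc
    expect_equal(a, oracle_auc(scores, labels))
    # negation antisymmetry
    expect_equal(rank_auc(-scores, labels, ci = FALSE)$auc, 1 - a)
  }
  expect_error(rank_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("the DeLong interval brackets the point estimate and matches pROC", {
  set.seed(13)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c(1, 0), each = 40)
  r <- rank_auc(scores, labels)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  roc <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                   quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  # infinite scores participate via their ranks
  r2 <- rank_auc(c(Inf, scores), c(1, labels))
  expect_true(is.finite(r2$auc) && is.finite(r2$ci[1]))
})
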