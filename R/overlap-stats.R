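#' A 2x2 contingency table over a gene (or geneset) universe
#'
#' Cell conventions used throughout: `a` = in both lists, `b` = first list
#' only, `c` = second list only, `d` = remainder of the universe; the four
#' cells sum to the universe size.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  structure(as.list(cells), class = "contingency_table")
}

#' Cross-product odds ratio and Fisher's exact test for a 2x2 table
#'
#' The reported odds ratio is the sample cross-product `(a*d)/(b*c)`, with
#' the conventions OR = 0 when `a = 0` and OR = +Inf when a complement cell
#' is empty (`b` or `c` zero with `a > 0`) -- no continuity correction. The
#' p-value is the conventional two-sided exact hypergeometric test
#' (minimum-likelihood tail definition, as implemented by
#' [stats::fisher.test()]); the conditional-MLE odds ratio is additionally
#' recorded for comparison.
#'
#' @param table A [contingency_table()].
#' @return An object of class `overlap_result`: `table`, `odds_ratio`,
#'   `fisher_p`, `cmle_or`.
#' @export
fisher_or <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (a + b < 1) stop("first list is empty (a + b = 0)")
  or <- if (a == 0) 0 else if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2))
  structure(list(table = table, odds_ratio = or, fisher_p = ft$p.value,
                 cmle_or = unname(ft$estimate)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> a=%d b=%d c=%d d=%d  OR=%s  p=%.3g\n",
              x$table$a, x$table$b, x$table$c, x$table$d,
              format(x$odds_ratio, digits = 4), x$fisher_p))
  invisible(x)
}

#' Overlap between two gene lists over a universe
#'
#' The gene-overlap odds ratio: the odds of a gene being identified by both
#' studies over the odds of it being identified by the first but not the
#' second, computed from the 2x2 table of the two lists over the declared
#' gene universe.
#'
#' @param ewas_genes,gwas_genes Character vectors of gene ids (the first and
#'   second list).
#' @param universe Character vector: the gene universe both lists live in.
#' @return An `overlap_result` (see [fisher_or()]).
#' @export
gene_overlap <- function(ewas_genes, gwas_genes, universe) {
  ewas_genes <- unique(as.character(ewas_genes))
  gwas_genes <- unique(as.character(gwas_genes))
  universe <- unique(as.character(universe))
  out <- setdiff(c(ewas_genes, gwas_genes), universe)
  if (length(out)) {
    stop("gene(s) outside universe: ", paste(head(out, 5), collapse = ", "))
  }
  a <- length(intersect(ewas_genes, gwas_genes))
  b <- length(ewas_genes) - a
  cc <- length(gwas_genes) - a
  d <- length(universe) - a - b - cc
  fisher_or(contingency_table(a, b, cc, d))
}

# Geneset hit counts for a hit-gene list: named vector of |hits ∩ S| per
# geneset, via the sparse membership matrix.
.set_hit_counts <- function(hit_idx, annotation) {
  M <- annotation$membership
  if (length(hit_idx) == 1L) {
    as.numeric(M[hit_idx, ])
  } else {
    Matrix::colSums(M[hit_idx, , drop = FALSE])
  }
}

# Vectorised cross-product OR with the 0/Inf conventions.
.or_convention <- function(a, b, cc, d) {
  ifelse(a == 0, 0, ifelse(b == 0 | cc == 0, Inf, (a * d) / (b * cc)))
}

#' Geneset enrichment odds-ratio profile for a gene list
#'
#' For each geneset S, the enrichment score is the odds of a hit gene being
#' annotated to S over the odds of a hit gene not being annotated to S:
#' the cross-product OR of the 2x2 table (hits-in-S, hits-not-in-S,
#' S-not-hit, remainder of universe). Genesets sharing no gene with the hit
#' list score exactly zero, and scores of +Inf can occur; both are expected
#' and preserved -- no pseudo-count is applied by default (downstream
#' comparison is rank-based).
#'
#' @param hit_genes Character vector of hit gene ids, a subset of the
#'   annotation universe; must be non-empty.
#' @param annotation A [geneset_annotation()].
#' @param study Study label carried in the profile.
#' @param pseudo_count Optional Haldane-Anscombe continuity correction added
#'   to every cell (default 0 = none).
#' @return An object of class `enrichment_profile`: named `scores` over all
#'   genesets, `hit_genes`, `study`.
#' @export
enrichment_profile <- function(hit_genes, annotation, study = "",
                               pseudo_count = 0) {
  hit_genes <- unique(as.character(hit_genes))
  if (length(hit_genes) == 0) stop("hit gene list is empty")
  idx <- match(hit_genes, annotation$universe)
  if (anyNA(idx)) {
    stop("hit gene(s) outside annotation universe: ",
         paste(head(hit_genes[is.na(idx)], 5), collapse = ", "))
  }
  n <- length(annotation$universe)
  nh <- length(idx)
  a <- .set_hit_counts(idx, annotation)
  b <- nh - a
  cc <- annotation$set_sizes - a
  d <- n - nh - cc
  scores <- if (pseudo_count > 0) {
    ((a + pseudo_count) * (d + pseudo_count)) /
      ((b + pseudo_count) * (cc + pseudo_count))
  } else {
    .or_convention(a, b, cc, d)
  }
  structure(list(study = study,
                 scores = setNames(as.numeric(scores), names(annotation$sets)),
                 hit_genes = hit_genes),
            class = "enrichment_profile")
}

#' Direct overlap of identified genesets between two studies
#'
#' A geneset is "identified" by a study iff at least one of the study's hit
#' genes is a member. The two identified-geneset lists are compared with the
#' same 2x2 odds-ratio/Fisher machinery as gene overlap, over the universe
#' of all genesets in the annotation.
#'
#' @param hits_a,hits_b Hit gene lists (or [enrichment_profile()] objects,
#'   whose hit genes are used).
#' @param annotation A [geneset_annotation()].
#' @return An `overlap_result` (see [fisher_or()]).
#' @export
geneset_overlap <- function(hits_a, hits_b, annotation) {
  ga <- if (inherits(hits_a, "enrichment_profile")) hits_a$hit_genes else hits_a
  gb <- if (inherits(hits_b, "enrichment_profile")) hits_b$hit_genes else hits_b
  ia <- match(unique(ga), annotation$universe)
  ib <- match(unique(gb), annotation$universe)
  if (anyNA(ia) || anyNA(ib)) stop("hit gene(s) outside annotation universe")
  ident_a <- .set_hit_counts(ia, annotation) > 0
  ident_b <- .set_hit_counts(ib, annotation) > 0
  a <- sum(ident_a & ident_b)
  b <- sum(ident_a & !ident_b)
  cc <- sum(!ident_a & ident_b)
  d <- sum(!ident_a & !ident_b)
  fisher_or(contingency_table(a, b, cc, d))
}

#' Spearman correlation between two enrichment profiles
#'
#' Rank correlation of the (log) enrichment scores of two profiles over the
#' same genesets. Because log is strictly monotone, ranks of log scores
#' equal ranks of raw scores, so zeros and +Inf participate naturally
#' through their (tied minimal / maximal) ranks; average ranks are used for
#' ties.
#'
#' @param p1,p2 [enrichment_profile()] objects over identical geneset
#'   domains.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
enrichment_correlation <- function(p1, p2) {
  s1 <- p1$scores
  if (!setequal(names(p1$scores), names(p2$scores))) {
    stop("profiles cover different geneset domains")
  }
  s2 <- p2$scores[names(s1)]
  if (length(s1) < 3) stop("need at least 3 genesets for a correlation")
  if (anyNA(s1) || anyNA(s2)) stop("profiles contain undefined scores")
  r1 <- rank(s1)
  r2 <- rank(s2)
  if (sd(r1) == 0 || sd(r2) == 0) {
    stop("correlation undefined: zero variance in enrichment scores")
  }
  cor(r1, r2)
}

#' An empirical null distribution of a statistic
#'
#' @param draws Numeric vector of resampled statistic values; draws that
#'   failed to evaluate may be NA and are excluded from the moments (their
#'   count is recorded).
#' @param statistic_name Label of the statistic.
#' @return An object of class `null_distribution` with `draws`, `mean`,
#'   `sd`, `n`, `n_dropped`.
#' @export
null_distribution <- function(draws, statistic_name = "statistic") {
  ok <- draws[!is.na(draws)]
  structure(list(statistic_name = statistic_name, draws = draws,
                 mean = mean(ok), sd = sd(ok), n = length(ok),
                 n_dropped = sum(is.na(draws))),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: n=%d mean=%.4g sd=%.4g%s\n",
              x$statistic_name, x$n, x$mean, x$sd,
              if (x$n_dropped) sprintf(" (%d dropped)", x$n_dropped) else ""))
  invisible(x)
}

#' Two-sided z-test of an observed statistic against a resampled null
#'
#' `p = 2 * Phi(-|observed - mean| / sd)` with the null's empirical mean and
#' standard deviation.
#'
#' @param observed Observed statistic.
#' @param null A [null_distribution()].
#' @return Two-sided p-value.
#' @export
z_test_vs_null <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is.finite(null$sd) || null$sd == 0) {
    stop("degenerate null distribution (sd = 0 or non-finite)")
  }
  if (!is.finite(null$mean)) stop("non-finite null mean")
  2 * pnorm(-abs(observed - null$mean) / null$sd)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment, order-preserving with the input.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Rank-based AUC with DeLong confidence interval
#'
#' AUC as the rank statistic `P(score1 > score0) + 0.5 * P(tie)`. The
#' confidence interval uses the DeLong variance estimator (computed on
#' ranks; the estimator is invariant to strictly monotone transforms, so
#' infinite scores are handled through their ranks).
#'
#' @param scores Numeric scores (may contain `Inf`).
#' @param labels 0/1 class labels; both classes must be present.
#' @param ci Compute the DeLong CI (needs >= 2 observations per class).
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `auc`, `ci` (length-2, NA if unavailable),
#'   `conf_level`.
#' @export
rank_auc <- function(scores, labels, ci = TRUE, conf_level = 0.95) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ci_out <- c(NA_real_, NA_real_)
  if (ci) {
    if (n1 < 2 || n0 < 2) {
      warning("confidence interval degenerate with fewer than 2 observations per class")
    } else {
      roc <- pROC::roc(response = labels, predictor = r,
                       levels = c(0L, 1L), direction = "<", quiet = TRUE)
      # pROC warns that a CI at AUC == 1 is degenerate; that is fine here
      ci_out <- suppressWarnings(
        as.numeric(pROC::ci.auc(roc, method = "delong",
                                conf.level = conf_level))[c(1, 3)])
    }
  }
  list(auc = auc, ci = ci_out, conf_level = conf_level)
}

# Bare AUC for hot loops (no checks, no CI).
.auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
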