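#' Pairwise enrichment-score correlations across studies
#'
#' Computes the Spearman correlation of enrichment profiles
#' ([enrichment_correlation()]) for every unordered pair of studies,
#' returning a symmetric matrix with unit diagonal.
#'
#' @param profiles Named list of [enrichment_profile()] objects on a common
#'   geneset domain (at least 2).
#' @param types Optional character vector of study types (`"gwas"` /
#'   `"ewas"`) parallel to `profiles`, carried as an attribute for grouped
#'   tests.
#' @return A symmetric correlation matrix of class `correlation_matrix` with
#'   attribute `types`.
#' @export
pairwise_correlations <- function(profiles, types = NULL) {
  n <- length(profiles)
  if (n < 2) stop("need at least 2 profiles")
  labs <- names(profiles) %||% paste0("study", seq_len(n))
  dom <- names(profiles[[1]]$scores)
  for (p in profiles) {
    if (!setequal(names(p$scores), dom)) {
      stop("profiles cover different geneset domains")
    }
  }
  m <- diag(1, n)
  dimnames(m) <- list(labs, labs)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- enrichment_correlation(profiles[[i]], profiles[[j]])
    }
  }
  if (!is.null(types)) {
    stopifnot(length(types) == n, all(types %in% c("gwas", "ewas")))
    attr(m, "types") <- types
  }
  class(m) <- c("correlation_matrix", class(m))
  m
}

#' Test each study pair's correlation against the grand mean
#'
#' For each unordered pair, a one-sided z-test of whether its correlation
#' exceeds the grand mean of all pairwise correlations, using the empirical
#' standard deviation of the pairwise correlations as the scale;
#' Benjamini-Hochberg FDR across all pairs. Pairs are grouped by the study
#' types at their ends (gwas-gwas, gwas-ewas, ewas-ewas) when types are
#' available.
#'
#' @param m A [pairwise_correlations()] matrix.
#' @param types Study types per study; defaults to the matrix's `types`
#'   attribute.
#' @return data.frame: `study1`, `study2`, `correlation`, `group`, `z_p`,
#'   `fdr_q`; attributes `grand_mean` and `sd`.
#' @export
group_mean_tests <- function(m, types = NULL) {
  types <- types %||% attr(m, "types")
  labs <- rownames(m)
  n <- nrow(m)
  ut <- upper.tri(m)
  r <- m[ut]
  grand <- mean(r)
  s <- sd(r)
  if (!is.finite(s) || s == 0) {
    stop("degenerate pairwise-correlation spread (sd = 0)")
  }
  idx <- which(ut, arr.ind = TRUE)
  group <- if (!is.null(types)) {
    g <- cbind(types[idx[, "row"]], types[idx[, "col"]])
    apply(g, 1, function(x) paste(sort(x), collapse = "-"))
  } else rep(NA_character_, length(r))
  z_p <- pnorm((r - grand) / s, lower.tail = FALSE)
  out <- data.frame(study1 = labs[idx[, "row"]], study2 = labs[idx[, "col"]],
                    correlation = r, group = group, z_p = z_p,
                    fdr_q = bh_fdr(z_p), stringsAsFactors = FALSE)
  attr(out, "grand_mean") <- grand
  attr(out, "sd") <- s
  out
}
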