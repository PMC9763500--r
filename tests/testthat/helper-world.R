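`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic worlds shared across tests. Built in code at test time;
# sizes chosen so the whole suite runs in minutes.

tiny_world <- function(seed = 42, n_genes = 300, n_sets = 40,
                       n_chromosomes = 3, chrom_length = 5e6) {
  w <- generate_genome(n_chromosomes, chrom_length, n_genes,
                       gene_length_range = c(2e3, 2e4), seed = seed)
  hi <- min(120, n_genes)
  ann <- generate_genesets(w$genes, n_sets, size_range = c(5, hi),
                           broad_fraction = if (hi > 100) 0.2 else 0,
                           seed = seed + 1)
  list(layout = w$layout, genes = w$genes, annotation = ann)
}

# Brute-force site -> nearest-gene mapping: plain double loop over all
# site/gene pairs, minimising distance-to-nearer-edge per chromosome.
oracle_map <- function(sites, genes) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    g <- genes[genes$chr == sites$chr[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- numeric(nrow(g))
    for (j in seq_len(nrow(g))) {
      q <- sites$pos[i]
      d[j] <- if (q >= g$start[j] && q < g$end[j]) 0 else {
        min(abs(g$start[j] - q), abs(q - (g$end[j] - 1)))
      }
    }
    best <- which(d == min(d))
    out[[length(out) + 1L]] <- data.frame(site_id = sites$site_id[i],
                                          gene_id = g$gene_id[best],
                                          distance = d[best],
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# O(n^2) pairwise AUC oracle: P(score1 > score0) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Step-up BH by the definition: q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j,
# computed via cumulative minimum from the largest p down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins, minimum-likelihood tail definition.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # size of first list
  k <- a + c          # size of second list
  n <- a + b + c + d
  support <- max(0, m + k - n):min(m, k)
  probs <- dhyper(support, k, n - k, m)
  sum(probs[probs <= dhyper(a, k, n - k, m) * (1 + 1e-7)])
}
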