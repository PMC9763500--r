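#' An architecture-simulation scenario
#'
#' One cell of the architecture grid. Given `n_kgg` known GWAS genes and
#' `n_keg` known EWAS genes (`n_ktg = n_kgg + n_keg`), a candidate
#' architecture has equal causal and associated pools of size
#' `n_ktg * multiplier` (so the total simulated gene count is
#' `2 * n_ktg * multiplier`), with a configurable overlap proportion between
#' the pools.
#'
#' @param n_kgg,n_keg Counts of known GWAS and EWAS genes.
#' @param multiplier Pool-size multiplier (the grid uses 1, 2, 3, 5, 10,
#'   20).
#' @param overlap_proportion Overlap between causal and associated pools in
#'   `[0, 1]` (the grid uses 0, 0.01, 0.1, 0.5, 1); 0 means the only
#'   overlap is that already present between the known gene lists, 1 means
#'   the maximum overlap feasible given them.
#' @param reps Simulation replicates (default 1000).
#' @return An object of class `arch_scenario`.
#' @export
arch_scenario <- function(n_kgg, n_keg, multiplier, overlap_proportion,
                          reps = 1000L) {
  stopifnot(n_kgg >= 1, n_keg >= 1, multiplier >= 1,
            overlap_proportion >= 0, overlap_proportion <= 1, reps >= 1)
  n_ktg <- n_kgg + n_keg
  structure(list(n_kgg = n_kgg, n_keg = n_keg, n_ktg = n_ktg,
                 multiplier = multiplier,
                 overlap_proportion = overlap_proportion,
                 pool_size = n_ktg * multiplier,
                 total_genes = 2 * n_ktg * multiplier,
                 reps = as.integer(reps)),
            class = "arch_scenario")
}

#' Build candidate causal and associated pools around the known genes
#'
#' The known GWAS genes are placed in the causal pool and the known EWAS
#' genes in the associated pool; both pools are padded to
#' `n_ktg * multiplier` with novel genes drawn from the universe outside the
#' known lists. The pools' intersection is
#' `|kgg ∩ keg| + round(overlap_proportion * max_extra)`, where `max_extra =
#' min(pool_size - |kgg|, pool_size - |keg|)` is the largest overlap the
#' novel genes can contribute: at 0 the only overlap is the known one, at 1
#' every novel gene of the smaller complement is shared (when
#' `|kgg| <= |keg|` this makes the associated-only genes exactly the known
#' EWAS genes not identified by GWAS).
#'
#' @param kgg,keg Known GWAS / EWAS gene-id vectors.
#' @param scenario An [arch_scenario()].
#' @param universe Gene universe to draw novel genes from.
#' @param seed Integer seed.
#' @return List with `causal` and `associated` gene-id vectors, plus the
#'   realised `overlap` count as attribute.
#' @export
build_pools <- function(kgg, keg, scenario, universe, seed = 1L) {
  stopifnot(inherits(scenario, "arch_scenario"))
  kgg <- unique(as.character(kgg))
  keg <- unique(as.character(keg))
  out <- setdiff(c(kgg, keg), universe)
  if (length(out)) {
    stop("known gene(s) outside universe: ", paste(head(out, 5), collapse = ", "))
  }
  S <- scenario$pool_size
  if (S < length(kgg)) {
    stop("infeasible: pool size ", S, " smaller than the ", length(kgg),
         " known GWAS genes")
  }
  if (S < length(keg)) {
    stop("infeasible: pool size ", S, " smaller than the ", length(keg),
         " known EWAS genes")
  }
  n_cnovel <- S - length(kgg)
  n_anovel <- S - length(keg)
  max_extra <- min(n_cnovel, n_anovel)
  extra <- round(scenario$overlap_proportion * max_extra)
  need <- n_cnovel + n_anovel - extra
  novel_universe <- setdiff(universe, union(kgg, keg))
  if (need > length(novel_universe)) {
    stop("infeasible: scenario needs ", need,
         " novel genes but the universe only has ", length(novel_universe),
         " outside the known lists")
  }
  nov <- with_seed(seed, sample(novel_universe, need))
  shared <- nov[seq_len(extra)]
  c_only <- nov[extra + seq_len(n_cnovel - extra)]
  a_only <- nov[extra + (n_cnovel - extra) + seq_len(n_anovel - extra)]
  pools <- list(causal = c(kgg, shared, c_only),
                associated = c(keg, shared, a_only))
  attr(pools, "overlap") <- length(intersect(pools$causal, pools$associated))
  pools
}

#' Simulate one architecture scenario and test it against the observed
#' correlation
#'
#' Builds the scenario's pools, then draws `reps` replicate study pairs --
#' `n_kgg` genes from the causal pool as the simulated GWAS and `n_keg` from
#' the associated pool as the simulated EWAS -- and records the Spearman
#' correlation of their geneset enrichment profiles. The observed
#' (empirical) correlation is scored against the simulated distribution with
#' a two-sided z-test: a small p is evidence against this architecture
#' generating the observed data.
#'
#' @param scenario An [arch_scenario()].
#' @param kgg,keg Known GWAS / EWAS gene-id vectors.
#' @param annotation A [geneset_annotation()].
#' @param empirical_rho Observed enrichment-score correlation.
#' @param seed Integer seed.
#' @return An object of class `arch_result`: scenario parameters, the
#'   simulated correlations, their summary, and `z_p`.
#' @export
run_arch_scenario <- function(scenario, kgg, keg, annotation, empirical_rho,
                              seed = 1L) {
  pools <- build_pools(kgg, keg, scenario, annotation$universe,
                       seed = child_seed(seed, "pools"))
  causal_idx <- match(pools$causal, annotation$universe)
  assoc_idx <- match(pools$associated, annotation$universe)
  reps <- scenario$reps
  gw_idx <- vector("list", reps)
  ew_idx <- vector("list", reps)
  for (i in seq_len(reps)) {
    with_seed(child_seed(seed, "arch_draw", i), {
      gw_idx[[i]] <- sample(causal_idx, scenario$n_kgg)
      ew_idx[[i]] <- sample(assoc_idx, scenario$n_keg)
    })
  }
  sims <- .batch_metrics(gw_idx, ew_idx, annotation, "rho_p")$rho_p
  ok <- sims[!is.na(sims)]
  if (length(ok) < 2 || sd(ok) == 0) {
    stop("degenerate simulated correlation distribution")
  }
  nd <- null_distribution(sims, "enrichment_correlation")
  structure(list(scenario = scenario,
                 simulated = sims,
                 sim_mean = nd$mean, sim_sd = nd$sd,
                 sim_median = stats::median(ok),
                 sim_iqr = unname(stats::quantile(ok, c(0.25, 0.75))),
                 empirical_rho = empirical_rho,
                 z_p = z_test_vs_null(empirical_rho, nd)),
            class = "arch_result")
}

#' Run the full architecture grid with FDR control
#'
#' Crosses the pool-size multipliers with the overlap proportions, runs each
#' scenario via [run_arch_scenario()], and applies Benjamini-Hochberg FDR
#' across all scenario z-test p-values (pool across traits by concatenating
#' grids before adjustment, or use this per trait). Scenarios that are
#' infeasible for the given known lists fail loudly: they are reported with
#' their error message and excluded from the FDR adjustment, with a warning.
#'
#' @param kgg,keg Known GWAS / EWAS gene-id vectors.
#' @param annotation A [geneset_annotation()].
#' @param empirical_rho Observed enrichment-score correlation.
#' @param multipliers,overlap_proportions Grid axes (defaults: the standard
#'   grid).
#' @param reps Replicates per scenario.
#' @param seed Integer master seed.
#' @param fdr_threshold Evidence-against threshold (default 0.05).
#' @return data.frame: one row per grid cell with simulation summaries,
#'   `z_p`, `fdr_q` and `rejected`; failed cells carry the error in
#'   `error`.
#' @export
run_arch_grid <- function(kgg, keg, annotation, empirical_rho,
                          multipliers = c(1, 2, 3, 5, 10, 20),
                          overlap_proportions = c(0, 0.01, 0.1, 0.5, 1),
                          reps = 1000L, seed = 1L, fdr_threshold = 0.05) {
  grid <- expand.grid(multiplier = multipliers,
                      overlap_proportion = overlap_proportions,
                      KEEP.OUT.ATTRS = FALSE)
  n_kgg <- length(unique(kgg))
  n_keg <- length(unique(keg))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sc <- arch_scenario(n_kgg, n_keg, grid$multiplier[g],
                        grid$overlap_proportion[g], reps = reps)
    res <- tryCatch(
      run_arch_scenario(sc, kgg, keg, annotation, empirical_rho,
                        seed = child_seed(seed, "arch_scenario", g)),
      error = function(e) e)
    rows[[g]] <- if (inherits(res, "error")) {
      data.frame(multiplier = grid$multiplier[g],
                 overlap_proportion = grid$overlap_proportion[g],
                 pool_size = sc$pool_size, total_genes = sc$total_genes,
                 sim_mean = NA_real_, sim_sd = NA_real_,
                 sim_median = NA_real_, sim_q25 = NA_real_,
                 sim_q75 = NA_real_, empirical_rho = empirical_rho,
                 z_p = NA_real_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(multiplier = grid$multiplier[g],
                 overlap_proportion = grid$overlap_proportion[g],
                 pool_size = sc$pool_size, total_genes = sc$total_genes,
                 sim_mean = res$sim_mean, sim_sd = res$sim_sd,
                 sim_median = res$sim_median, sim_q25 = res$sim_iqr[1],
                 sim_q75 = res$sim_iqr[2], empirical_rho = empirical_rho,
                 z_p = res$z_p, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(!is.na(out$error))) {
    warning(sum(!is.na(out$error)), " scenario(s) failed: ",
            paste(unique(out$error[!is.na(out$error)]), collapse = "; "))
  }
  out$fdr_q <- NA_real_
  ok <- !is.na(out$z_p)
  out$fdr_q[ok] <- bh_fdr(out$z_p[ok])
  out$rejected <- !is.na(out$fdr_q) & out$fdr_q < fdr_threshold
  out
}
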