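#' A power-simulation scenario
#'
#' One cell of the power grid: how many associated genes exist to be found
#' (`n_assoc_detected`, the "Assoc genes" axis), what fraction of them the
#' EWAS detects (`ewas_power` -- study sample size is operationalised purely
#' as detected-gene count), and what proportion of the detected EWAS genes
#' are causal (`prop_causal_ewas`). GWAS genes are always drawn from the
#' causal pool.
#'
#' @param n_assoc_detected Number of associated genes the trait has to
#'   detect.
#' @param ewas_power Fraction of those the EWAS detects, in `[0, 1]`; the
#'   EWAS list size is `round(ewas_power * n_assoc_detected)`.
#' @param prop_causal_ewas Proportion of the detected EWAS genes drawn from
#'   the causal pool, in `[0, 1]`.
#' @param n_gwas_genes GWAS list size (default: `n_assoc_detected`).
#' @param annotation_id Label of the annotation the scenario is scored with.
#' @param iterations Replicates per scenario (default 1000).
#' @return An object of class `power_scenario`.
#' @export
power_scenario <- function(n_assoc_detected, ewas_power, prop_causal_ewas,
                           n_gwas_genes = n_assoc_detected,
                           annotation_id = "default", iterations = 1000L) {
  stopifnot(n_assoc_detected >= 1, ewas_power >= 0, ewas_power <= 1,
            prop_causal_ewas >= 0, prop_causal_ewas <= 1, n_gwas_genes >= 1,
            iterations >= 1)
  n_ewas <- round(ewas_power * n_assoc_detected)
  structure(list(n_assoc_detected = n_assoc_detected, ewas_power = ewas_power,
                 prop_causal_ewas = prop_causal_ewas,
                 n_gwas_genes = n_gwas_genes,
                 n_ewas_detected = n_ewas,
                 n_causal_in_ewas = round(prop_causal_ewas * n_ewas),
                 annotation_id = annotation_id,
                 iterations = as.integer(iterations)),
            class = "power_scenario")
}

# Sample one replicate's gene index lists. Sampling order (GWAS, then
# EWAS-causal, then EWAS-associated) is fixed so the batch and single-draw
# paths agree for the same seed.
.draw_indices <- function(scenario, causal_idx, assoc_idx, seed) {
  n_c <- scenario$n_causal_in_ewas
  n_a <- scenario$n_ewas_detected - n_c
  if (scenario$n_gwas_genes > length(causal_idx)) {
    stop("GWAS sample exceeds causal pool")
  }
  if (n_c > length(causal_idx) || n_a > length(assoc_idx)) {
    stop("EWAS sample exceeds its pools")
  }
  with_seed(seed, {
    gw <- sample(causal_idx, scenario$n_gwas_genes)
    ew <- c(sample(causal_idx, n_c), sample(assoc_idx, n_a))
  })
  list(gw = gw, ew = unique(ew))
}

#' Draw one power-simulation replicate and compute the three metrics
#'
#' GWAS genes are a simple random sample from the causal pool; the EWAS list
#' combines `round(prop_causal_ewas * n_ewas)` causal-pool genes with the
#' remainder from the associated pool (without replacement within each
#' pool). The three overlap metrics are computed over the annotation
#' universe: gene-overlap OR (`or_g`), geneset-overlap OR (`or_p`), and the
#' Spearman correlation of enrichment scores (`rho_p`).
#'
#' @param scenario A [power_scenario()].
#' @param pools List with `causal` and `associated` gene-id vectors (e.g. a
#'   [generate_architecture()] result renamed, or [power_pools()]).
#' @param annotation A [geneset_annotation()].
#' @param seed Integer seed.
#' @return A list: `gwas_genes`, `ewas_genes`, `or_g`, `or_p`, `rho_p`.
#' @export
draw_scenario <- function(scenario, pools, annotation, seed = 1L) {
  stopifnot(inherits(scenario, "power_scenario"))
  causal_idx <- match(pools$causal, annotation$universe)
  assoc_idx <- match(pools$associated, annotation$universe)
  if (anyNA(causal_idx) || anyNA(assoc_idx)) {
    stop("pool gene(s) outside annotation universe")
  }
  d <- .draw_indices(scenario, causal_idx, assoc_idx, seed)
  gw <- annotation$universe[d$gw]
  ew <- annotation$universe[d$ew]
  or_g <- gene_overlap(ew, gw, annotation$universe)$odds_ratio
  or_p <- geneset_overlap(ew, gw, annotation)$odds_ratio
  rho_p <- tryCatch(
    enrichment_correlation(enrichment_profile(ew, annotation),
                           enrichment_profile(gw, annotation)),
    error = function(e) NA_real_)
  list(gwas_genes = gw, ewas_genes = ew,
       or_g = or_g, or_p = or_p, rho_p = rho_p)
}

#' Default causal/associated pools for the power simulation
#'
#' Disjoint pools (overlap between GWAS and EWAS draws is introduced only
#' through `prop_causal_ewas`) of 1000 causal and 1000 associated genes over
#' the universe, scaled down proportionally if the universe is smaller than
#' the default 20,000 genes.
#'
#' @param universe Character vector of gene ids.
#' @param n_causal,n_assoc Pool sizes.
#' @param seed Integer seed.
#' @return List with `causal` and `associated` gene-id vectors.
#' @export
power_pools <- function(universe, n_causal = 1000L, n_assoc = 1000L,
                        seed = 1L) {
  if (n_causal + n_assoc > length(universe)) {
    stop("pools exceed universe size")
  }
  with_seed(seed, {
    drawn <- sample(universe, n_causal + n_assoc)
  })
  list(causal = drawn[seq_len(n_causal)],
       associated = drawn[n_causal + seq_len(n_assoc)])
}

#' Default power-simulation grid
#'
#' Crossing of detected-gene counts, EWAS power levels and causal
#' proportions; every non-null cell has its matched `prop_causal_ewas = 0`
#' twin, as [run_power_grid()] requires.
#'
#' @param n_assoc_detected,ewas_power,prop_causal_ewas Grid axes.
#' @return data.frame grid.
#' @export
default_power_grid <- function(n_assoc_detected = c(50, 100, 500),
                               ewas_power = c(0.2, 0.5, 1),
                               prop_causal_ewas = c(0, 0.05, 1)) {
  if (!0 %in% prop_causal_ewas) {
    stop("grid must include prop_causal_ewas = 0 (the null scenario)")
  }
  expand.grid(n_assoc_detected = n_assoc_detected, ewas_power = ewas_power,
              prop_causal_ewas = prop_causal_ewas, KEEP.OUT.ATTRS = FALSE)
}

#' Run the power grid and score scenario discriminability by AUC
#'
#' For every grid cell with `prop_causal_ewas > 0`, the metric values of its
#' `reps` replicates are pooled with those of the matched
#' `prop_causal_ewas = 0` cell (same detected-gene count and power), and the
#' AUC of metric value for the non-null/null label is computed with a DeLong
#' 95% CI. High AUC means the metric can tell a partly-causal EWAS from one
#' sampling random associated genes.
#'
#' @param grid data.frame with columns `n_assoc_detected`, `ewas_power`,
#'   `prop_causal_ewas` (see [default_power_grid()]).
#' @param pools List with `causal`/`associated` gene-id pools.
#' @param annotation A [geneset_annotation()].
#' @param reps Replicates per scenario.
#' @param seed Integer master seed.
#' @param metrics Metrics to score.
#' @return data.frame: one row per non-null scenario x metric with `auc`,
#'   `ci_lo`, `ci_hi`, plus the per-scenario draws as attribute `"draws"`.
#' @export
run_power_grid <- function(grid, pools, annotation, reps = 1000L, seed = 1L,
                           metrics = c("or_g", "or_p", "rho_p")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  grid <- as.data.frame(grid)
  key <- function(g) paste(g$n_assoc_detected, g$ewas_power, sep = "|")
  nonnull <- grid[grid$prop_causal_ewas > 0, , drop = FALSE]
  nulls <- grid[grid$prop_causal_ewas == 0, , drop = FALSE]
  missing_twin <- setdiff(unique(key(nonnull)), unique(key(nulls)))
  if (length(missing_twin)) {
    stop("non-null scenario(s) without a matched prop_causal_ewas = 0 twin: ",
         paste(missing_twin, collapse = "; "))
  }
  if (reps < 2) warning("AUC confidence intervals degenerate with reps < 2")
  causal_idx <- match(pools$causal, annotation$universe)
  assoc_idx <- match(pools$associated, annotation$universe)
  draws <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sc <- power_scenario(grid$n_assoc_detected[g], grid$ewas_power[g],
                         grid$prop_causal_ewas[g], iterations = reps)
    gw_idx <- vector("list", reps)
    ew_idx <- vector("list", reps)
    for (i in seq_len(reps)) {
      d <- .draw_indices(sc, causal_idx, assoc_idx,
                         child_seed(seed, "power_draw", g, i))
      gw_idx[[i]] <- d$gw
      ew_idx[[i]] <- d$ew
    }
    draws[[g]] <- .batch_metrics(gw_idx, ew_idx, annotation, metrics)
  }
  rows <- list()
  for (g in which(grid$prop_causal_ewas > 0)) {
    twin <- which(grid$prop_causal_ewas == 0 & key(grid) == key(grid[g, ]))[1]
    for (m in metrics) {
      scores <- c(draws[[g]][[m]], draws[[twin]][[m]])
      labels <- rep(c(1L, 0L), c(reps, reps))
      ok <- !is.na(scores)
      auc <- rank_auc(scores[ok], labels[ok], ci = reps >= 2)
      rows[[length(rows) + 1L]] <- data.frame(
        n_assoc_detected = grid$n_assoc_detected[g],
        ewas_power = grid$ewas_power[g],
        prop_causal_ewas = grid$prop_causal_ewas[g],
        metric = m, auc = auc$auc,
        ci_lo = auc$ci[1], ci_hi = auc$ci[2],
        reps = reps, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "draws") <- setNames(draws, key2 <- paste(key(grid), grid$prop_causal_ewas, sep = "|"))
  out
}

#' Compare power across annotation methods
#'
#' Given [run_power_grid()] results computed with different annotations over
#' identical scenario grids, reports per-scenario AUC differences against
#' the first (reference) annotation, with CIs propagated from the DeLong
#' standard errors, ranked by mean AUC.
#'
#' @param results Named list of [run_power_grid()] outputs.
#' @return data.frame of per-annotation mean AUCs (ranked) with per-scenario
#'   deltas vs the reference as attribute `"deltas"`.
#' @export
compare_annotations <- function(results) {
  if (length(results) < 1) stop("no results supplied")
  keycols <- c("n_assoc_detected", "ewas_power", "prop_causal_ewas", "metric")
  ref <- results[[1]]
  for (r in results) {
    if (!identical(r[keycols], ref[keycols])) {
      stop("annotation results cover different scenario grids")
    }
  }
  summary <- data.frame(
    annotation = names(results),
    mean_auc = vapply(results, function(r) mean(r$auc), numeric(1)),
    stringsAsFactors = FALSE)
  summary <- summary[order(-summary$mean_auc), , drop = FALSE]
  rownames(summary) <- NULL
  se <- function(r) (r$ci_hi - r$ci_lo) / (2 * qnorm(0.975))
  deltas <- lapply(results[-1], function(r) {
    cbind(ref[keycols],
          delta_auc = r$auc - ref$auc,
          delta_se = sqrt(se(r)^2 + se(ref)^2))
  })
  attr(summary, "deltas") <- deltas
  summary
}
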