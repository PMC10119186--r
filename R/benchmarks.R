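## Self-benchmark studies: fixed compositions of the pipeline run on
## generated cohorts. They encode the package's validation conditions in one
## place so the test suite and any reproduction script exercise identical
## designs.

#' Null-calibration study: the full pipeline on an effect-free cohort
#'
#' Simulates a cohort with `risk_carrier_or = 1` (no gene carries risk),
#' applies the six-rule filter, collapses genes, computes 10 genotype
#' principal components from the common markers, runs the SKAT-O scan (with
#' the residual-bootstrap tail correction), and summarises calibration:
#' empirical type-I error at 0.05 and 0.01 and the genomic inflation factor.
#'
#' @param n_genes Number of genes simulated (default 2500, yielding upwards
#'   of 2,000 testable gene blocks).
#' @param seed Integer seed.
#' @param resample Bootstrap draws per gene (passed to [skat_o_scan()]).
#' @return List: `results` (scan data.frame), `p` (non-NA p-values),
#'   `type1_05`, `type1_01`, `lambda`, `n_genes_tested`.
#' @export
null_calibration_study <- function(n_genes = 2500, seed = 1,
                                   resample = 10000) {
  spec <- sim_spec(n_genes = n_genes, risk_carrier_or = 1, seed = seed)
  st <- simulate_study(spec)
  filt <- high_impact_filter(st$ann, st$gene_metrics, st$blacklist,
                             cohort_af = col_af(st$G_rare))
  col <- collapse_by_gene(st$G_rare, filt$qualifying, st$variant_gene)
  pcs <- pca_project(st$common$G, k = 10)$scores
  res <- skat_o_scan(col$blocks, st$phen$y, pcs, resample = resample,
                     seed = seed)
  p <- res$p_skato[!is.na(res$p_skato)]
  list(results = res, p = p,
       type1_05 = mean(p < 0.05), type1_01 = mean(p < 0.01),
       lambda = inflation_check(p), n_genes_tested = length(p))
}

#' Power study: recovery of spiked risk genes in the top ranks
#'
#' For each seed, simulates a cohort under the default spiked-alternative
#' conditions (5 risk genes, aggregate carrier odds ratio 3, per-gene
#' carrier frequency 10%, 1,500/1,500 target cohort), runs the pipeline and
#' records whether every risk gene ranks inside the top `top_frac` of
#' SKAT-O p-values. The scan runs without the bootstrap correction: spiked
#' genes sit many orders of magnitude below the bootstrap switch point, so
#' their ranks are unaffected and the asymptotic scan is much faster.
#'
#' @param seeds Integer vector of seeds (one study per seed).
#' @param n_genes Genes per study (default 1000).
#' @param top_frac Rank fraction defining success (default 0.01).
#' @return List: `per_seed` (logical), `fraction` (mean success),
#'   `ranks` (list of the risk genes' ranks per seed).
#' @export
power_recovery_study <- function(seeds, n_genes = 1000, top_frac = 0.01) {
  per_seed <- logical(length(seeds))
  ranks <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    spec <- sim_spec(n_genes = n_genes, seed = seeds[i])
    st <- simulate_study(spec)
    filt <- high_impact_filter(st$ann, st$gene_metrics, st$blacklist,
                               cohort_af = col_af(st$G_rare))
    col <- collapse_by_gene(st$G_rare, filt$qualifying, st$variant_gene)
    pcs <- pca_project(st$common$G, k = 10)$scores
    res <- skat_o_scan(col$blocks, st$phen$y, pcs, resample = 0)
    res <- res[!is.na(res$p_skato), ]
    n_top <- ceiling(top_frac * nrow(res))
    rk <- rank(res$p_skato, ties.method = "min")
    names(rk) <- res$gene
    rg <- intersect(spec$risk_genes, res$gene)
    ranks[[i]] <- rk[rg]
    per_seed[i] <- length(rg) == length(spec$risk_genes) &&
      all(rk[rg] <= n_top)
  }
  list(per_seed = per_seed, fraction = mean(per_seed), ranks = ranks)
}

#' Population-transfer benchmark for the rare-variant risk score
#'
#' Quantifies, on one seed, how much classification performance is lost
#' when the summary statistics backing the risk score come from a diverged
#' population instead of the target population. A target-population cohort
#' is split in half; "matched" summary statistics are estimated on the
#' training half. A second cohort is generated at the same variants under
#' diverged rare-allele frequencies - a fraction of the target's qualifying
#' variants is private (absent in the other population) and the rest are
#' log-normally jittered - with the same risk genes, and "mismatched"
#' summary statistics are estimated there. Both are shrunk over the
#' standard prior-fraction grid with the training half as LD reference,
#' scored on the held-out evaluation half, and classified by random forest.
#'
#' The architecture is polygenic (default 30 risk genes of 300): a
#' polygenic score is the instrument under test, and its transferability is
#' only measurable on a trait to which many genes contribute - under an
#' oligogenic spike both scores sit at the noise floor and the contrast
#' drowns.
#'
#' @param seed Integer seed.
#' @param n_genes Genes simulated (default 300 keeps the benchmark quick
#'   while leaving hundreds of qualifying variants).
#' @param n_risk Number of risk genes (default 30, a polygenic
#'   architecture).
#' @param private_frac Fraction of qualifying variants private to the
#'   target population (default 0.5; rare variants are predominantly
#'   population-private between long-separated populations).
#' @param jitter_sd Log-normal SD of the frequency divergence applied to
#'   shared variants (default 0.5).
#' @param folds,trees Random-forest cross-validation settings.
#' @return List: `auc_matched`, `auc_mismatched`, `n_variants`.
#' @export
prs_transfer_benchmark <- function(seed, n_genes = 300, n_risk = 30,
                                   private_frac = 0.5, jitter_sd = 0.5,
                                   folds = 5, trees = 300) {
  spec <- sim_spec(n_genes = n_genes,
                   risk_genes = sprintf("G%04d", seq_len(n_risk)),
                   n_markers_common = 200, seed = seed)
  st <- simulate_study(spec)
  qual <- intersect(st$qualifying_true, colnames(st$G_rare))
  G <- st$G_rare[, qual, drop = FALSE]
  y <- st$phen$y
  n <- nrow(G)

  half <- seq_len(floor(n / 2))
  train <- half
  eval_ <- setdiff(seq_len(n), half)

  summ_match <- simulate_summary_stats(G[train, , drop = FALSE], y[train])

  # diverged population at the same variants
  set.seed(child_seed(seed, "mismatch_pop"))
  maf_a <- col_af(G)
  private <- runif(length(qual)) < private_frac
  maf_b <- maf_a * exp(rnorm(length(qual), 0, jitter_sd))
  maf_b[private] <- 0
  maf_b <- clip(maf_b, 0, 0.05)
  nb <- length(train)
  Gb <- matrix(rbinom(nb * length(qual), 2L, rep(maf_b, each = nb)), nb,
               dimnames = list(sprintf("B%05d", seq_len(nb)), qual))
  phb <- spike_phenotypes(Gb, qual, st$variant_gene, spec$risk_genes,
                          spec$risk_carrier_or, spec$prevalence,
                          child_seed(seed, "mismatch_phen"))
  summ_mis <- simulate_summary_stats(Gb, phb$y)

  ld_ref <- G[train, , drop = FALSE]
  run_auc <- function(summ) {
    eff <- shrink_effects(summ, ld_ref, h2 = 0.2, iters = 100, burn = 30,
                          window = 25, seed = child_seed(seed, "gibbs"))
    sc <- score_individuals(G[eval_, , drop = FALSE], eff)
    classify(sc, y[eval_], folds = folds, seed = child_seed(seed, "cv"),
             trees = trees)$auc_mean
  }
  list(auc_matched = run_auc(summ_match),
       auc_mismatched = run_auc(summ_mis),
       n_variants = length(qual))
}
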