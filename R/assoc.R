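#' Collapse qualifying variants into per-gene blocks and carrier vectors
#'
#' Builds, for each gene with at least one qualifying variant, the sub-matrix
#' of dosages and a per-sample carrier flag (at least one alternate allele at
#' any qualifying variant of the gene). Variants whose cohort MAF exceeds
#' `cohort_maf_max` are excluded from the block (the conservative guard
#' against reference-frequency/cohort-frequency disagreement). Genes left
#' with zero qualifying variants are omitted and counted.
#'
#' @param G Samples x variants dosage matrix with variant-id column names.
#' @param qualifying_ids Qualifying variant ids.
#' @param variant_gene Named character vector mapping variant id to gene.
#' @param cohort_maf_max Cohort-MAF guard applied inside the block.
#' @return List with `blocks` (named list of dosage sub-matrices),
#'   `carriers` (samples x genes 0/1 matrix) and `n_omitted` (genes with no
#'   usable variant).
#' @export
collapse_by_gene <- function(G, qualifying_ids, variant_gene,
                             cohort_maf_max = 0.01) {
  ids <- intersect(qualifying_ids, colnames(G))
  maf <- col_maf(G[, ids, drop = FALSE])
  ids <- ids[!is.na(maf) & maf <= cohort_maf_max]
  genes <- unique(variant_gene[ids])
  blocks <- list()
  for (g in genes) {
    vid <- ids[variant_gene[ids] == g]
    if (length(vid) == 0) next
    blocks[[g]] <- G[, vid, drop = FALSE]
  }
  n_total_genes <- length(unique(variant_gene[intersect(qualifying_ids,
                                                        names(variant_gene))]))
  carriers <- vapply(blocks, function(B) {
    as.integer(rowSums(B, na.rm = TRUE) >= 1)
  }, integer(nrow(G)))
  if (is.null(dim(carriers))) carriers <- matrix(carriers, nrow = nrow(G))
  dimnames(carriers) <- list(rownames(G), names(blocks))
  list(blocks = blocks, carriers = carriers,
       n_omitted = n_total_genes - length(blocks))
}

#' Carrier-collapsing burden test (2 x 2 chi-squared)
#'
#' Cross-tabulates carrier status against case status and reports the odds
#' ratio and a 1-degree-of-freedom chi-squared test without continuity
#' correction. A zero cell triggers the Haldane-Anscombe 0.5 correction for
#' the odds ratio (flagged); an all-carrier or no-carrier table is flagged
#' degenerate with no p-value.
#'
#' @param carriers 0/1 carrier indicator vector.
#' @param phenotype 0/1 phenotype vector (both classes required).
#' @param continuity Apply the Yates continuity correction (default FALSE).
#' @return List of class `burden_result`: `or`, `chi2`, `p`, `table`,
#'   `carrier_freq_case`, `carrier_freq_control`, `haldane`, `degenerate`.
#' @export
carrier_burden_test <- function(carriers, phenotype, continuity = FALSE) {
  stopifnot(length(carriers) == length(phenotype),
            all(carriers %in% c(0, 1)), all(phenotype %in% c(0, 1)))
  if (length(unique(phenotype)) < 2) stop("both phenotype classes required")
  a <- sum(carriers == 1 & phenotype == 1) # case carriers
  b <- sum(carriers == 0 & phenotype == 1)
  c_ <- sum(carriers == 1 & phenotype == 0)
  d <- sum(carriers == 0 & phenotype == 0)
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(c("carrier", "non_carrier"),
                                c("case", "control")))
  degenerate <- (a + c_ == 0) || (b + d == 0)
  if (degenerate) {
    return(structure(list(or = NA_real_, chi2 = NA_real_, p = NA_real_,
                          table = tab, haldane = FALSE, degenerate = TRUE),
                     class = "burden_result"))
  }
  haldane <- any(tab == 0)
  if (haldane) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  cs <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  structure(list(
    or = or, chi2 = unname(cs$statistic), p = cs$p.value, table = tab,
    carrier_freq_case = a / (a + b), carrier_freq_control = c_ / (c_ + d),
    haldane = haldane, degenerate = FALSE
  ), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Carrier burden test: degenerate table (all or no carriers)\n")
    return(invisible(x))
  }
  cat(sprintf("Carrier burden test: OR = %.2f, chi2 = %.2f, p = %.3g\n",
              x$or, x$chi2, x$p))
  cat(sprintf("  carrier frequency: cases %.2f%%, controls %.2f%%\n",
              100 * x$carrier_freq_case, 100 * x$carrier_freq_control))
  invisible(x)
}

#' Per-variant logistic regression
#'
#' Maximum-likelihood logistic fit of the phenotype on a single dosage with
#' covariates; reports the Wald test. Non-convergence, quasi-complete
#' separation (fitted probabilities at the boundary) and collinearity
#' (aliased coefficients) are flagged; monomorphic dosages are skipped with
#' a notice.
#'
#' @param dosage Numeric dosage vector.
#' @param y 0/1 phenotype.
#' @param X Optional covariate matrix.
#' @return List: `beta`, `se`, `or`, `p`, `converged`, `separated`,
#'   `collinear`, `skipped`.
#' @export
variant_logistic <- function(dosage, y, X = NULL) {
  if (stats::var(dosage, na.rm = TRUE) == 0) {
    message("monomorphic dosage; skipped")
    return(list(beta = NA_real_, se = NA_real_, or = NA_real_, p = NA_real_,
                converged = NA, separated = NA, collinear = NA, skipped = TRUE))
  }
  df <- data.frame(y = y, g = dosage)
  if (!is.null(X)) {
    X <- as.matrix(X)
    colnames(X) <- paste0("c", seq_len(ncol(X)))
    df <- cbind(df, X)
  }
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  co <- summary(fit)$coefficients
  collinear <- any(is.na(stats::coef(fit)))
  separated <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (!"g" %in% rownames(co)) {
    return(list(beta = NA_real_, se = NA_real_, or = NA_real_, p = NA_real_,
                converged = fit$converged, separated = separated,
                collinear = TRUE, skipped = FALSE))
  }
  list(beta = co["g", 1], se = co["g", 2], or = exp(co["g", 1]),
       p = co["g", 4], converged = fit$converged, separated = separated,
       collinear = collinear, skipped = FALSE)
}

#' Genomic inflation factor from a set of p-values
#'
#' `lambda_GC`: the median of the observed 1-df chi-square quantiles divided
#' by the null median `qchisq(0.5, 1)`. Supports both neutral-model checks
#' (e.g. synonymous-only collapsing) and controls-vs-controls splits - the
#' caller supplies whichever p-value set the check requires.
#'
#' @param p Numeric vector of p-values (>= 100 recommended).
#' @return `lambda_GC` (1 indicates calibrated tests).
#' @export
inflation_check <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) warning("fewer than 100 p-values; lambda is unstable")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_genes Number of tests (>= 1).
#' @param alpha Family-wise error rate.
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}

#' Run SKAT-O across all gene blocks
#'
#' Convenience scanner: fits the null model once and applies [skat_o_test()]
#' to every block.
#'
#' @param blocks Named list of per-gene dosage matrices (from
#'   [collapse_by_gene()]).
#' @param y 0/1 phenotype.
#' @param X Optional covariate matrix.
#' @param rho_grid Mixing grid passed to [skat_o_test()].
#' @param method Tail-probability method passed to [skat_o_test()].
#' @param resample,resample_below Residual-bootstrap control passed to
#'   [skat_o_test()]; the default applies the bootstrap correction, which is
#'   what a calibration-sensitive scan should use. Set `resample = 0` for
#'   speed when only the extreme tail ranks matter.
#' @param seed Seed for the bootstrap draws (ignored when `resample = 0`).
#' @return data.frame: `gene`, `n_variants`, `p_skat`, `p_burden`,
#'   `p_skato`, `rho_opt`.
#' @export
skat_o_scan <- function(blocks, y, X = NULL,
                        rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                        method = c("saddlepoint", "liu", "imhof"),
                        resample = 10000, resample_below = 2e-3,
                        seed = 1) {
  method <- match.arg(method)
  nm <- skat_null_model(y, X)
  if (resample > 0) set.seed(seed)
  rows <- lapply(names(blocks), function(g) {
    r <- skat_o_test(blocks[[g]], nm, rho_grid = rho_grid, method = method,
                     resample = resample, resample_below = resample_below)
    data.frame(gene = g, n_variants = r$n_variants,
               p_skat = r$p_skat, p_burden = r$p_burden,
               p_skato = r$p_skato, rho_opt = r$rho_opt %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-level phenome-wide association scan
#'
#' For every phenotype code with at least `min_cases` cases, draws
#' `ratio * n_cases` controls without replacement from the control pool
#' (after removing individuals overlapping the cases), and runs
#' [skat_o_test()] on the gene block with the first two principal components
#' as covariates. Phenotypes whose pool is too small are skipped and logged.
#'
#' @param G_gene Samples x variants dosage matrix for the gene (row names are
#'   sample ids).
#' @param pheno_table Long-format data.frame with columns `sample_id`,
#'   `code`: one row per diagnosis.
#' @param control_pool Character vector of sample ids eligible as controls.
#' @param pcs Samples x components matrix of principal components (row names
#'   are sample ids); the first two columns are used.
#' @param ratio Control:case ratio (default 10).
#' @param min_cases Minimum case count per phenotype (default 100).
#' @param seed Integer seed for the control draws.
#' @return data.frame: `code`, `n_cases`, `n_controls`, `p_skato`; skipped
#'   phenotypes are absent (reported via message).
#' @export
phewas_scan <- function(G_gene, pheno_table, control_pool, pcs,
                        ratio = 10, min_cases = 100, seed = 1) {
  stopifnot(all(c("sample_id", "code") %in% names(pheno_table)))
  set.seed(seed)
  codes <- unique(pheno_table$code)
  rows <- list()
  for (code in codes) {
    cases <- unique(pheno_table$sample_id[pheno_table$code == code])
    cases <- intersect(cases, rownames(G_gene))
    if (length(cases) < min_cases) next
    pool <- setdiff(intersect(control_pool, rownames(G_gene)), cases)
    n_ctrl <- ratio * length(cases)
    if (length(pool) < n_ctrl) {
      message(sprintf("phenotype %s skipped: control pool too small", code))
      next
    }
    ctrls <- sample(pool, n_ctrl)
    ids <- c(cases, ctrls)
    y <- as.integer(ids %in% cases)
    X <- pcs[ids, 1:2, drop = FALSE]
    nm <- skat_null_model(y, X)
    r <- skat_o_test(G_gene[ids, , drop = FALSE], nm)
    rows[[code]] <- data.frame(code = code, n_cases = length(cases),
                               n_controls = n_ctrl, p_skato = r$p_skato,
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(code = character(), n_cases = integer(),
                      n_controls = integer(), p_skato = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
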