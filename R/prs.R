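#' Harmonize summary statistics against a variant table
#'
#' Removes strand-ambiguous variants (A/T and C/G), flips the sign of the
#' effect when the stated effect allele is the reference allele (so all
#' effects are expressed on the alternate-allele dosage scale), and drops
#' variants whose effect allele matches neither allele.
#'
#' @param summary `gwas_summary` data.frame (`variant_id`, `effect_allele`,
#'   `beta`, `se`, `n`).
#' @param variants data.frame with columns `variant_id`, `ref`, `alt`.
#' @return The harmonized summary data.frame with attributes `n_ambiguous`,
#'   `n_flipped`, `n_dropped`.
#' @export
harmonize_summary <- function(summary, variants) {
  idx <- match(summary$variant_id, variants$variant_id)
  keep <- !is.na(idx)
  s <- summary[keep, , drop = FALSE]
  v <- variants[idx[keep], , drop = FALSE]
  pair <- paste0(pmin(v$ref, v$alt), pmax(v$ref, v$alt))
  ambiguous <- pair %in% c("AT", "CG")
  s <- s[!ambiguous, , drop = FALSE]
  v <- v[!ambiguous, , drop = FALSE]
  flip <- s$effect_allele == v$ref
  match_alt <- s$effect_allele == v$alt
  drop <- !flip & !match_alt
  s$beta[flip] <- -s$beta[flip]
  s$effect_allele[flip] <- v$alt[flip]
  out <- s[!drop, , drop = FALSE]
  attr(out, "n_ambiguous") <- sum(ambiguous)
  attr(out, "n_flipped") <- sum(flip & !drop)
  attr(out, "n_dropped") <- sum(drop) + sum(!keep)
  out
}

## crude heritability estimate from summary chi-squares:
## E[chi2] = 1 + n h2 / M under an infinitesimal model, so
## h2_hat = M (mean(chi2) - 1) / mean(n), floored at a small positive value.
#' @rdname shrink_effects
#' @export
estimate_h2_summary <- function(summary) {
  z2 <- (summary$beta / summary$se)^2
  z2 <- z2[is.finite(z2)]
  max(length(z2) * (mean(z2) - 1) / mean(summary$n[is.finite(summary$se)]),
      1e-3)
}

#' Posterior mean effect sizes under a point-normal prior (LD-aware shrinkage)
#'
#' Shrinks marginal summary-statistic effects toward their posterior means
#' under a point-normal prior - each variant's effect is zero with
#' probability `1 - p_fraction` and Gaussian with variance
#' `h2 / (M * p_fraction)` otherwise - using Gibbs sampling over LD windows
#' estimated from a reference genotype panel. Effects are standardized
#' internally (`b = z / sqrt(n)`); the Rao-Blackwellized posterior mean is
#' averaged over post-burn-in sweeps and mapped back to the original scale.
#' With `p_fraction = 1` the infinitesimal closed form
#' `(R + M / (h2 n) I)^{-1} b` is used; without LD that reduces to
#' `beta * h2 n / (h2 n + M)` marker-wise.
#'
#' @param summary Harmonized `gwas_summary` data.frame.
#' @param ld_ref Reference dosage matrix (samples x variants, column names =
#'   variant ids) supplying LD; only variants present in both are used
#'   (unmatched ones are dropped and counted).
#' @param p_fraction Prior fraction(s) of non-zero effects; may be a vector
#'   (default the canonical grid `1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001`).
#' @param h2 Total heritability attributed to the variant set; when `NULL`,
#'   estimated crudely from the summary chi-squares (`estimate_h2_summary`).
#' @param iters,burn Gibbs sweeps and burn-in.
#' @param window LD window size in markers (consecutive blocks).
#' @param seed Integer seed.
#' @return Matrix (variants x length(p_fraction)) of posterior mean effects
#'   on the original allele scale, with `variant_id` rownames and attributes
#'   `n_unmatched`, `h2`.
#' @export
shrink_effects <- function(summary, ld_ref,
                           p_fraction = c(1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001),
                           h2 = NULL, iters = 200, burn = 50,
                           window = 50, seed = 1) {
  if (!is.null(h2) && h2 <= 0) stop("h2 must be positive")
  usable <- is.finite(summary$se) & summary$se > 0
  s <- summary[usable, , drop = FALSE]
  ids <- intersect(colnames(ld_ref), s$variant_id)
  n_unmatched <- nrow(summary) - length(ids)
  s <- s[match(ids, s$variant_id), , drop = FALSE]
  M <- length(ids)
  if (M == 0) stop("no variants matched between summary and reference")
  if (is.null(h2)) h2 <- estimate_h2_summary(s)

  z <- s$beta / s$se
  btilde <- z / sqrt(s$n)
  nvec <- s$n

  R_ref <- ld_ref[, ids, drop = FALSE]
  # impute missing to column mean for correlation
  cm <- colMeans(R_ref, na.rm = TRUE)
  for (j in which(colSums(is.na(R_ref)) > 0)) {
    R_ref[is.na(R_ref[, j]), j] <- cm[j]
  }

  starts <- seq(1, M, by = window)
  out <- matrix(0, M, length(p_fraction),
                dimnames = list(ids, as.character(p_fraction)))
  is_inf <- p_fraction == 1
  sparse_idx <- which(!is_inf)
  sig2 <- h2 / (M * p_fraction[sparse_idx])
  K <- length(sparse_idx)
  set.seed(seed)
  for (w in starts) {
    j_idx <- w:min(w + window - 1, M)
    mw <- length(j_idx)
    Rw <- if (mw > 1) {
      suppressWarnings(stats::cor(R_ref[, j_idx, drop = FALSE]))
    } else {
      matrix(1, 1, 1)
    }
    Rw[is.na(Rw)] <- 0
    diag(Rw) <- 1
    bw <- btilde[j_idx]
    nw <- nvec[j_idx]
    for (pi in which(is_inf)) {
      A <- Rw + diag(M / (h2 * nw), mw)
      out[j_idx, pi] <- solve(A, bw)
    }
    if (K > 0 && all(bw == 0)) {
      # symmetric prior, zero signal: the posterior mean is exactly zero
      out[j_idx, sparse_idx] <- 0
    } else if (K > 0) {
      # all sparse prior fractions run as parallel chains through one sweep
      Bc <- matrix(0, mw, K)
      acc <- matrix(0, mw, K)
      kept <- 0L
      lp1 <- log(p_fraction[sparse_idx])
      lp0 <- log1p(-p_fraction[sparse_idx])
      for (it in seq_len(iters)) {
        for (j in seq_len(mw)) {
          rj <- bw[j] - drop(Rw[j, ] %*% Bc) + Bc[j, ]
          pv <- 1 / (nw[j] + 1 / sig2)
          mu1 <- pv * nw[j] * rj
          l1 <- lp1 + stats::dnorm(rj, 0, sqrt(sig2 + 1 / nw[j]), log = TRUE)
          l0 <- lp0 + stats::dnorm(rj, 0, sqrt(1 / nw[j]), log = TRUE)
          pj <- 1 / (1 + exp(l0 - l1))
          on <- stats::runif(K) < pj
          Bc[j, ] <- ifelse(on, stats::rnorm(K, mu1, sqrt(pv)), 0)
          if (it > burn) acc[j, ] <- acc[j, ] + pj * mu1
        }
        if (it > burn) kept <- kept + 1L
      }
      out[j_idx, sparse_idx] <- acc / kept
    }
  }
  # back to the original allele scale: beta = btilde * se * sqrt(n)
  out <- out * (s$se * sqrt(s$n))
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "h2") <- h2
  out
}

#' Per-individual polygenic risk scores
#'
#' `PRS_i = sum_m dosage_im * effect_m`, with missing dosages imputed to
#' twice the allele frequency. When `effects` is a matrix (one column per
#' prior fraction) one score per column is returned.
#'
#' @param G Samples x variants dosage matrix aligned to the effect alleles.
#' @param effects Numeric vector or matrix of per-variant effects with
#'   variant-id names/rownames matching columns of `G`.
#' @return Matrix (samples x score columns) of scores.
#' @export
score_individuals <- function(G, effects) {
  if (is.null(dim(effects))) {
    effects <- matrix(effects, ncol = 1,
                      dimnames = list(names(effects), "score"))
  }
  ids <- intersect(colnames(G), rownames(effects))
  stopifnot(length(ids) > 0)
  Gs <- G[, ids, drop = FALSE]
  mu <- colMeans(Gs, na.rm = TRUE)
  for (j in which(colSums(is.na(Gs)) > 0)) {
    Gs[is.na(Gs[, j]), j] <- mu[j]
  }
  out <- Gs %*% effects[ids, , drop = FALSE]
  rownames(out) <- rownames(G)
  out
}

#' Random-forest classification of PRS profiles with cross-validated AUC
#'
#' Trains a random forest on the PRS feature columns with stratified,
#' seeded k-fold cross-validation and reports the out-of-fold AUC per fold
#' and its mean. Hyperparameters are fixed (`trees`, default mtry/depth) so
#' runs are comparable.
#'
#' @param profiles Samples x features matrix (e.g. 7 PRS columns).
#' @param labels 0/1 vector.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment and forests.
#' @param trees Number of trees per forest (default 500).
#' @return List: `auc_mean`, `auc_folds`, `oof` (out-of-fold probabilities),
#'   `fold` (fold assignment).
#' @export
classify <- function(profiles, labels, folds = 10, seed = 1, trees = 500) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (folds > min(n1, n0)) stop("folds exceed the smaller class size")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(0, 1)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  oof <- numeric(length(labels))
  aucs <- numeric(folds)
  yf <- factor(labels, levels = c(0, 1))
  for (f in seq_len(folds)) {
    tr <- fold != f
    rf <- randomForest::randomForest(profiles[tr, , drop = FALSE], yf[tr],
                                     ntree = trees)
    pr <- stats::predict(rf, profiles[!tr, , drop = FALSE], type = "prob")[, "1"]
    oof[!tr] <- pr
    aucs[f] <- as.numeric(pROC::auc(pROC::roc(
      response = labels[!tr], predictor = pr,
      levels = c(0, 1), direction = "<", quiet = TRUE)))
  }
  list(auc_mean = mean(aucs), auc_folds = aucs, oof = oof, fold = fold)
}

#' Integrated discrimination improvement between nested risk models
#'
#' `IDI = [mean(p_ext | case) - mean(p_ext | control)] -
#' [mean(p_base | case) - mean(p_base | control)]`.
#'
#' @param probs_base,probs_extended Predicted probabilities of the base and
#'   extended models, aligned to `labels`.
#' @param labels 0/1 vector; both classes must be present.
#' @return The IDI (a scalar).
#' @export
idi <- function(probs_base, probs_extended, labels) {
  stopifnot(length(probs_base) == length(labels),
            length(probs_extended) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  case <- labels == 1
  (mean(probs_extended[case]) - mean(probs_extended[!case])) -
    (mean(probs_base[case]) - mean(probs_base[!case]))
}
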