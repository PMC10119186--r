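#' Greedy sliding-window LD pruning of a genotype matrix
#'
#' Removes markers until, within every sliding window, no retained pair has
#' squared correlation above `r2_max`. Windows of `window` markers advance by
#' `step` markers along the input order (markers are assumed ordered by
#' genomic position); within a window, pairs are scanned left to right and the
#' right-hand member of an offending pair is dropped, so the result is
#' deterministic given the input order. Pairwise r-squared is computed on
#' dosages with pairwise-complete observations. Monomorphic markers (for
#' which r-squared is undefined) are excluded before pruning.
#'
#' @param G Samples x markers dosage matrix (NA = missing), markers ordered by
#'   position.
#' @param window Window size in markers.
#' @param step Step size in markers.
#' @param r2_max Maximum allowed pairwise r-squared.
#' @return Integer vector of retained marker column indices.
#' @export
ld_prune <- function(G, window = 50, step = 5, r2_max = 0.2) {
  stopifnot(window >= 2, step >= 1, r2_max >= 0)
  m <- ncol(G)
  v <- apply(G, 2, stats::var, na.rm = TRUE)
  keep <- !is.na(v) & v > 0
  for (s in seq(1, max(m - 1, 1), by = step)) {
    idx <- which(keep[s:min(s + window - 1, m)]) + s - 1
    if (length(idx) < 2) next
    sub <- G[, idx, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))^2
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || !keep[idx[b]]) next
        if (!is.na(r2[a, b]) && r2[a, b] > r2_max) keep[idx[b]] <- FALSE
      }
    }
  }
  which(keep)
}

#' Pre-mask markers on MAF, call rate and strand ambiguity
#'
#' Retains markers with minor allele frequency strictly above `maf_min` and
#' call rate strictly above `call_rate_min`; when `drop_ambiguous_strand` is
#' set and alleles are supplied, A/T and C/G markers (whose strand cannot be
#' resolved) are removed.
#'
#' @param G Samples x markers dosage matrix.
#' @param maf_min MAF threshold (strict `>`).
#' @param call_rate_min Call-rate threshold (strict `>`).
#' @param alleles Optional data.frame with columns `ref` and `alt`, one row
#'   per marker, required for the ambiguity test.
#' @param drop_ambiguous_strand Drop A/T and C/G markers.
#' @return Integer vector of retained marker column indices.
#' @export
premask_markers <- function(G, maf_min = 0.02, call_rate_min = 0.95,
                            alleles = NULL, drop_ambiguous_strand = !is.null(alleles)) {
  maf <- col_maf(G)
  call_rate <- colMeans(!is.na(G))
  keep <- !is.na(maf) & maf > maf_min & call_rate > call_rate_min
  if (drop_ambiguous_strand) {
    if (is.null(alleles)) stop("alleles required to test strand ambiguity")
    pair <- paste0(pmin(alleles$ref, alleles$alt), pmax(alleles$ref, alleles$alt))
    keep <- keep & !(pair %in% c("AT", "CG"))
  }
  which(keep)
}

#' Supervised two-population admixture-fraction estimation
#'
#' For each sample, estimates the fraction `q` of its ancestry attributable to
#' the reference population (popA) by maximising the binomial log-likelihood
#' `sum_m log Binom(g_m; 2, q pA_m + (1 - q) pB_m)` over `q` in `[0, 1]`, with
#' the two ancestral frequency vectors fixed by the reference panel
#' (a supervised, deterministic stand-in for unsupervised K = 2 structure
#' estimation). The 1-D optimisation uses [stats::optimize()] at tolerance
#' 1e-6; missing genotypes are skipped. Samples with fewer than
#' `min_markers` non-missing markers are flagged unreliable; when the panel is
#' uninformative (pA = pB everywhere) the likelihood is flat and `q = 0.5` is
#' returned with `flat = TRUE`.
#'
#' @param G Samples x markers dosage matrix restricted to the pruned,
#'   pre-masked marker set.
#' @param panel `ancestral_freqs` data.frame aligned to the columns of `G`
#'   (frequencies already clipped away from 0/1).
#' @param min_markers Minimum non-missing markers for a reliable estimate.
#' @return data.frame: `sample_id`, `q`, `loglik`, `n_markers`, `reliable`,
#'   `flat`.
#' @export
estimate_fractions <- function(G, panel, min_markers = 50) {
  stopifnot(ncol(G) == nrow(panel))
  pA <- clip(panel$freq_popA, 1e-4, 1 - 1e-4)
  pB <- clip(panel$freq_popB, 1e-4, 1 - 1e-4)
  flat_panel <- max(abs(pA - pB)) < 1e-12
  ids <- rownames(G) %||% sprintf("S%05d", seq_len(nrow(G)))
  res <- lapply(seq_len(nrow(G)), function(i) {
    g <- G[i, ]
    ok <- !is.na(g)
    nll <- function(q) {
      f <- q * pA[ok] + (1 - q) * pB[ok]
      -sum(g[ok] * log(f) + (2 - g[ok]) * log(1 - f))
    }
    if (flat_panel || !any(ok)) {
      q <- 0.5
      ll <- if (any(ok)) -nll(0.5) else NA_real_
      return(data.frame(sample_id = ids[i], q = q, loglik = ll,
                        n_markers = sum(ok), reliable = sum(ok) >= min_markers,
                        flat = TRUE, stringsAsFactors = FALSE))
    }
    opt <- stats::optimize(nll, interval = c(0, 1), tol = 1e-6)
    # the optimum can sit at a boundary; compare against endpoints explicitly
    cand <- c(opt$minimum, 0, 1)
    vals <- vapply(cand, nll, numeric(1))
    q <- cand[which.min(vals)]
    data.frame(sample_id = ids[i], q = q, loglik = -min(vals),
               n_markers = sum(ok), reliable = sum(ok) >= min_markers,
               flat = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Two-round minimum-reference-fraction population assignment
#'
#' Round 1 estimates admixture fractions for all candidates and the reference
#' samples against the supplied panel; the cutoff is the minimum fraction
#' observed in the reference samples and candidates with `q >= cutoff`
#' (boundary inclusive) are retained. Round 2 refines: the non-reference
#' ancestral frequencies are re-estimated from the candidates rejected so far
#' (sharpening the contrast, the analogue of re-running structure estimation
#' on the refined cohort), fractions are re-estimated for retained +
#' reference samples, and the updated minimum-reference cutoff is re-applied.
#' The observed cutoff of each round is recorded in the trace; once stable,
#' additional rounds change nothing.
#'
#' @param G Samples x markers dosage matrix (pruned/pre-masked markers).
#' @param panel `ancestral_freqs` aligned to the columns of `G`.
#' @param reference_ids Sample ids (row names of `G`) forming the reference
#'   panel; must be non-empty and present in `G`.
#' @param rounds Number of assignment rounds (default 2).
#' @param refine_other_panel Re-estimate popB frequencies from rejected
#'   candidates in rounds > 1 (default TRUE). With `FALSE` the panel is fixed
#'   and later rounds are idempotent.
#' @return List with `assigned` (character vector of assigned candidate ids,
#'   excluding the reference samples), `estimates` (final-round estimate
#'   data.frame) and `trace` (data.frame per round: `round`, `cutoff`,
#'   `n_candidates`, `n_removed`).
#' @export
assign_population <- function(G, panel, reference_ids, rounds = 2,
                              refine_other_panel = TRUE) {
  ids <- rownames(G)
  if (length(reference_ids) == 0) stop("reference_ids must be non-empty")
  if (!all(reference_ids %in% ids)) stop("reference_ids must be rows of G")
  candidates <- setdiff(ids, reference_ids)
  current <- candidates
  pan <- panel
  trace <- list()
  est <- NULL
  for (r in seq_len(rounds)) {
    if (r > 1 && refine_other_panel) {
      rejected <- setdiff(candidates, current)
      if (length(rejected) >= 5) {
        afB <- col_af(G[rejected, , drop = FALSE])
        pan$freq_popB <- clip(afB, 0.01, 0.99)
      }
    }
    use <- c(current, reference_ids)
    est <- estimate_fractions(G[use, , drop = FALSE], pan)
    cutoff <- min(est$q[est$sample_id %in% reference_ids])
    keep <- est$sample_id %in% reference_ids | est$q >= cutoff
    removed <- sum(!keep)
    est$assigned <- keep & !(est$sample_id %in% reference_ids)
    est$round <- r
    current <- est$sample_id[est$assigned]
    trace[[r]] <- data.frame(round = r, cutoff = cutoff,
                             n_candidates = length(use) - length(reference_ids),
                             n_removed = removed)
  }
  list(assigned = current, estimates = est, trace = do.call(rbind, trace))
}

#' Project samples onto genotype principal components
#'
#' Markers are mean-centred and scaled by `sqrt(2 p (1 - p))` (the binomial
#' standard deviation at the estimated allele frequency); missing genotypes
#' are imputed to the marker mean before scaling. The top `k` components are
#' returned with explained-variance fractions. The sign convention fixes the
#' largest-magnitude loading of each component to be positive so results are
#' reproducible across platforms.
#'
#' @param G Samples x markers dosage matrix.
#' @param k Number of components (default 10); truncated with a warning if it
#'   exceeds the matrix rank.
#' @return List with `scores` (samples x k), `loadings` (markers x k),
#'   `explained` (length-k fraction of variance), `d` (singular values).
#' @export
pca_project <- function(G, k = 10) {
  af <- col_af(G)
  sdv <- sqrt(2 * af * (1 - af))
  use <- !is.na(sdv) & sdv > 0
  X <- G[, use, drop = FALSE]
  mu <- 2 * af[use]
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- mu[j]
    X[, j] <- (xj - mu[j]) / sdv[use][j]
  }
  sv <- svd(X, nu = min(k, dim(X)), nv = min(k, dim(X)))
  pos <- sum(sv$d > max(sv$d) * 1e-8)
  if (k > pos) {
    warning(sprintf("k = %d exceeds rank %d; truncating", k, pos))
    k <- pos
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       explained = sv$d[seq_len(k)]^2 / sum(sv$d^2), d = sv$d)
}
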