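test_that("LD pruning removes exactly the window-local correlated markers", {
  set.seed(1)
  # independent markers: everything survives
  G <- matrix(rbinom(200 * 30, 2, 0.3), 200)
  expect_identical(ld_prune(G, window = 10, step = 2, r2_max = 0.2),
                   seq_len(30))

  # a duplicated column pair: exactly one of the two survives
  Gd <- cbind(G[, 1:5], G[, 3], G[, 6:10])
  kept <- ld_prune(Gd, window = 10, step = 2, r2_max = 0.2)
  expect_true(xor(3 %in% kept, 6 %in% kept))

  # monomorphic markers are excluded up front
  Gm <- cbind(G[, 1:4], 1L)
  expect_false(5 %in% ld_prune(Gm, window = 5, step = 1))
})

test_that("LD pruning satisfies the all-pairs window constraint (oracle check)", {
  set.seed(2)
  n <- 150; m <- 500
  # blocks of correlated markers: copy a base marker with noise
  G <- matrix(rbinom(n * m, 2, 0.4), n)
  for (b in seq(1, m - 4, by = 25)) {
    for (k in 1:3) {
      flip <- rbinom(n, 1, 0.1)
      G[, b + k] <- ifelse(flip == 1, rbinom(n, 2, 0.4), G[, b])
    }
  }
  window <- 50; step <- 5; r2max <- 0.2
  kept <- ld_prune(G, window, step, r2max)
  expect_gt(length(kept), 0)
  # brute force: within every window, no retained pair exceeds r2max
  for (s in seq(1, m - 1, by = step)) {
    idx <- intersect(kept, s:min(s + window - 1, m))
    if (length(idx) < 2) next
    r2 <- cor(G[, idx])^2
    expect_lt(max(r2[upper.tri(r2)]), r2max + 1e-12)
  }
  # pruning depends only on marker order and r2, not on sample labels
  expect_identical(ld_prune(G[sample(n), ], window, step, r2max), kept)
})

test_that("pre-masking applies strict MAF/call-rate rules and strand ambiguity", {
  # 6 hand-built markers: columns are (maf, call rate, alleles)
  n <- 200
  mk <- function(maf, cr) {
    g <- rbinom(n, 2, maf)
    g[seq_len(round((1 - cr) * n))] <- NA
    g
  }
  set.seed(3)
  G <- cbind(
    mk(0.30, 1.00), # pass
    mk(0.30, 0.90), # fail call rate
    mk(0.005, 1.00), # fail MAF
    mk(0.40, 1.00), # A/T ambiguous
    mk(0.25, 0.96), # pass
    mk(0.45, 1.00)  # C/G ambiguous
  )
  alleles <- data.frame(ref = c("A", "C", "G", "A", "T", "C"),
                        alt = c("C", "T", "A", "T", "G", "G"))
  kept <- premask_markers(G, alleles = alleles, drop_ambiguous_strand = TRUE)
  expect_identical(kept, c(1L, 5L))

  # boundary: MAF exactly at the threshold is removed (strict >)
  Gb <- matrix(c(rep(0L, 98), 1L, 1L), ncol = 1) # maf = 0.01
  expect_length(premask_markers(Gb, maf_min = 0.01), 0)
  expect_identical(premask_markers(Gb, maf_min = 0.0099), 1L)
})

test_that("supervised fraction estimation recovers pure and admixed ancestry", {
  panel <- simulate_reference_panels(5000, fst = 0.1, seed = 4)
  # pure popA samples: estimates close to 1
  coh <- simulate_cohort(panel, 30, q_dist = function(n) rep(1, n), seed = 4)
  est <- estimate_fractions(coh$G, panel)
  expect_true(all(est$q > 0.95))

  # flat panel: unidentifiable, q = 0.5 with flag
  flat <- panel
  flat$freq_popB <- flat$freq_popA
  estf <- estimate_fractions(coh$G[1:3, ], flat)
  expect_true(all(estf$flat))
  expect_true(all(estf$q == 0.5))

  # half-admixed samples at 10,000 markers: |q - 0.5| < 0.05 for >= 95%
  panel2 <- simulate_reference_panels(10000, fst = 0.1, seed = 5)
  coh2 <- simulate_cohort(panel2, 60, q_dist = function(n) rep(0.5, n), seed = 5)
  est2 <- estimate_fractions(coh2$G, panel2)
  expect_gte(mean(abs(est2$q - 0.5) < 0.05), 0.95)

  # too few markers: flagged unreliable
  est3 <- estimate_fractions(coh$G[1:2, 1:30], panel[1:30, ])
  expect_false(any(est3$reliable))
})

test_that("fraction estimates respond monotonically to genotype perturbations", {
  panel <- simulate_reference_panels(500, fst = 0.3, seed = 6)
  coh <- simulate_cohort(panel, 5, q_dist = function(n) rep(0.5, n), seed = 6)
  est0 <- estimate_fractions(coh$G, panel)
  # push one genotype toward the popA-major allele: q must not decrease
  j <- which.max(panel$freq_popA - panel$freq_popB)
  G2 <- coh$G
  G2[, j] <- pmin(G2[, j] + 1L, 2L)
  est1 <- estimate_fractions(G2, panel)
  expect_true(all(est1$q >= est0$q - 1e-6))
})

test_that("two-round cutoff assignment separates a 0.9/0.3 mixture", {
  panel <- simulate_reference_panels(5000, fst = 0.1, seed = 7)
  n_hi <- 120; n_lo <- 120; n_ref <- 36
  # reference panel spreads down to ~0.7, well under the 0.9 target cluster
  set.seed(7)
  qs <- c(rep(0.9, n_hi), rep(0.3, n_lo), runif(n_ref, 0.7, 1))
  coh <- simulate_cohort(panel, length(qs), q_dist = function(n) qs, seed = 7)
  ref_ids <- coh$samples$sample_id[(n_hi + n_lo + 1):length(qs)]
  res <- assign_population(coh$G, panel, ref_ids, rounds = 2)
  truth <- coh$samples$sample_id[1:n_hi]
  others <- coh$samples$sample_id[(n_hi + 1):(n_hi + n_lo)]
  sens <- mean(truth %in% res$assigned)
  spec <- mean(!(others %in% res$assigned))
  expect_gte(sens, 0.99)
  expect_gte(spec, 0.99)
  expect_equal(nrow(res$trace), 2)
  # a third round changes nothing once the assignment is stable
  res3 <- assign_population(coh$G, panel, ref_ids, rounds = 3)
  expect_setequal(res3$assigned, res$assigned)
})

test_that("assignment keeps boundary candidates and validates inputs", {
  panel <- simulate_reference_panels(800, fst = 0.4, seed = 8)
  # candidates are purer (q = 1) than every reference sample (q = 0.8):
  # the minimum-reference cutoff admits them all
  qs <- c(rep(1, 35), rep(0.8, 5))
  coh <- simulate_cohort(panel, 40, q_dist = function(n) qs, seed = 8)
  ref <- coh$samples$sample_id[36:40]
  res <- assign_population(coh$G, panel, ref, rounds = 1)
  expect_setequal(res$assigned, coh$samples$sample_id[1:35])
  expect_error(assign_population(coh$G, panel, character()), "non-empty")
})

test_that("PCA separates structured populations and respects duplicates", {
  panel <- simulate_reference_panels(1500, fst = 0.1, seed = 9)
  labs <- rep(c(1, 0), each = 60)
  coh <- simulate_cohort(panel, 120, q_dist = function(n) labs, seed = 9)
  pc <- pca_project(coh$G, k = 5)
  auc <- ajburden:::.auc_rank(labs, pc$scores[, 1])
  expect_gt(max(auc, 1 - auc), 0.99)
  expect_equal(sum(pc$explained <= 1), 5)

  # duplicated samples land on identical coordinates
  G2 <- rbind(coh$G, coh$G[1, , drop = FALSE])
  rownames(G2) <- c(rownames(coh$G), "dup")
  pc2 <- pca_project(G2, k = 3)
  expect_equal(unname(pc2$scores["dup", ]), unname(pc2$scores[1, ]),
               tolerance = 1e-8)

  # a single unstructured population shows no label separation
  panel0 <- simulate_reference_panels(800, fst = 0, seed = 10)
  coh0 <- simulate_cohort(panel0, 100, seed = 10)
  pc0 <- pca_project(coh0$G, k = 2)
  auc0 <- ajburden:::.auc_rank(rep(c(1, 0), 50), pc0$scores[, 1])
  expect_lt(abs(auc0 - 0.5), 0.2)

  # k beyond rank triggers truncation with a warning
  expect_warning(pca_project(coh$G[1:5, 1:20], k = 10), "rank")
})
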