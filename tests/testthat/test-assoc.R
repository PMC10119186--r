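test_that("gene collapsing produces correct blocks and carrier vectors", {
  G <- cbind(v1 = c(0L, 1L, 0L, 0L), v2 = c(0L, 0L, 2L, 0L),
             v3 = c(1L, 0L, 0L, 0L))
  rownames(G) <- paste0("S", 1:4)
  vg <- c(v1 = "GA", v2 = "GA", v3 = "GB")
  col <- collapse_by_gene(G, c("v1", "v2", "v3"), vg, cohort_maf_max = 0.5)
  expect_identical(unname(col$carriers[, "GA"]), c(0L, 1L, 1L, 0L))
  # a sample carrying in two genes counts once per gene
  G2 <- cbind(v1 = c(1L, 0L), v3 = c(1L, 0L))
  rownames(G2) <- paste0("S", 1:2)
  col2 <- collapse_by_gene(G2, c("v1", "v3"), vg, cohort_maf_max = 0.5)
  expect_identical(unname(col2$carriers[1, ]), c(1L, 1L))

  # cohort-MAF guard excludes common variants from the block
  set.seed(17)
  G3 <- cbind(rare = rbinom(400, 2, 0.004), common = rbinom(400, 2, 0.3))
  colnames(G3) <- c("r", "c")
  col3 <- collapse_by_gene(G3, c("r", "c"), c(r = "GX", c = "GX"))
  expect_identical(colnames(col3$blocks$GX), "r")

  # carrier counts equal brute-force row-wise any()
  st <- tiny_study(seed = 18)
  filt <- high_impact_filter(st$ann, st$gene_metrics, st$blacklist,
                             cohort_af = col_af(st$G_rare))
  col4 <- collapse_by_gene(st$G_rare, filt$qualifying, st$variant_gene)
  for (g in names(col4$blocks)[1:10]) {
    expect_identical(unname(col4$carriers[, g]),
                     as.integer(apply(col4$blocks[[g]] > 0, 1, any)))
  }
})

test_that("carrier burden test reproduces the printed carrier-set odds ratio", {
  # carrier counts reconstructed from the printed carrier frequencies
  n_case <- 1734; n_ctrl <- 2719
  a <- round(0.1574 * n_case) # 273
  c_ <- round(0.0926 * n_ctrl) # 252
  carriers <- c(rep(1, a), rep(0, n_case - a), rep(1, c_), rep(0, n_ctrl - c_))
  y <- c(rep(1, n_case), rep(0, n_ctrl))
  r <- carrier_burden_test(carriers, y)
  expect_equal(round(r$or, 2), 1.83)
  expect_lt(r$p, 1e-9)
  expect_equal(r$carrier_freq_case, a / n_case)
})

test_that("carrier burden test handles nulls, symmetry and degenerate margins", {
  # equal carrier frequencies: OR 1, chi2 0
  y <- rep(c(1, 0), each = 100)
  carr <- rep(c(1, 0, 1, 0), c(10, 90, 10, 90))
  r <- carrier_burden_test(carr, y)
  expect_equal(r$or, 1)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  # cross-check the 2x2 with the exact conditional distribution
  expect_gt(fisher.test(r$table)$p.value, 0.99)

  # label-swap symmetry: OR inverts
  carr2 <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  r2 <- carrier_burden_test(carr2, y)
  r2swap <- carrier_burden_test(carr2, 1 - y)
  expect_equal(r2$or, 1 / r2swap$or, tolerance = 1e-12)
  expect_equal(r2$chi2, r2swap$chi2, tolerance = 1e-12)

  # zero cell: Haldane correction flag
  r3 <- carrier_burden_test(rep(c(1, 0, 0, 0), c(5, 95, 0, 100)), y)
  expect_true(r3$haldane)
  # all carriers: degenerate
  r4 <- carrier_burden_test(rep(1, 200), y)
  expect_true(r4$degenerate)
  expect_true(is.na(r4$p))
})

test_that("SKAT-O statistics satisfy the rho-endpoint identities", {
  set.seed(19)
  n <- 500
  y <- rbinom(n, 1, 0.4)
  nm <- skat_null_model(y)
  maf <- c(0.01, 0.004, 0.02, 0.008)
  G <- sapply(maf, function(p) rbinom(n, 2, p))
  r <- skat_o_test(G, nm)
  w <- dbeta(pmin(col_af(G), 1 - col_af(G)), 1, 25)
  S <- as.vector(crossprod(G * rep(w, each = n), y - nm$mu))
  expect_equal(unname(r$Q_rho["0"]), sum(S^2), tolerance = 1e-8)
  expect_equal(unname(r$Q_rho["1"]), sum(S)^2, tolerance = 1e-8)
  expect_equal(r$Q_skat, sum(S^2), tolerance = 1e-8)
  expect_equal(r$Q_burden, sum(S)^2, tolerance = 1e-8)

  # p is invariant to variant order and to sample order
  perm <- sample(ncol(G))
  expect_equal(skat_o_test(G[, perm], nm)$p_skato, r$p_skato, tolerance = 1e-9)
  sp <- sample(n)
  nm2 <- skat_null_model(y[sp])
  expect_equal(skat_o_test(G[sp, ], nm2)$p_skato, r$p_skato, tolerance = 1e-6)

  # single-variant block collapses to the score test
  g1 <- G[, 1, drop = FALSE]
  r1 <- skat_o_test(g1, nm)
  S1 <- sum(g1 * (y - nm$mu))
  V1 <- sum(g1^2 * nm$v) - (sum(g1 * nm$v))^2 / sum(nm$v)
  expect_equal(r1$p_skato, pchisq(S1^2 / V1, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(r1$p_skat, r1$p_burden)

  # the omnibus p never beats the best single-rho p
  expect_gte(r$p_skato, min(r$p_rho) * (1 - 1e-6))
})

test_that("SKAT-O p-values are null-calibrated and detect spiked genes", {
  set.seed(20)
  n <- 1500
  y <- rbinom(n, 1, 0.5)
  nm <- skat_null_model(y)
  ps <- replicate(400, {
    m <- sample(2:6, 1)
    maf <- exp(runif(m, log(5e-4), log(5e-3)))
    G <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n)
    skat_o_test(G, nm)$p_skato
  })
  t1 <- mean(ps < 0.05, na.rm = TRUE)
  expect_lt(abs(t1 - 0.05), 1.96 * sqrt(0.05 * 0.95 / 400) + 0.01)

  # a strong spiked gene is detected
  maf <- rep(0.01, 5)
  G <- sapply(maf, function(p) rbinom(n, 2, p))
  carrier <- rowSums(G) > 0
  y2 <- rbinom(n, 1, ifelse(carrier, 0.75, 0.45))
  r <- skat_o_test(G, skat_null_model(y2))
  expect_lt(r$p_skato, 1e-4)
})

test_that("per-variant logistic regression flags pathologies and finds real effects", {
  set.seed(21)
  n <- 2000
  g <- rbinom(n, 2, 0.05)
  y <- rbinom(n, 1, plogis(-0.2 + log(3) * g))
  r <- variant_logistic(g, y)
  expect_lt(r$p, 1e-4)
  expect_gt(r$or, 1.5)

  # dosage duplicated as covariate: collinearity flag
  r2 <- variant_logistic(g, y, X = cbind(g))
  expect_true(r2$collinear)
  # monomorphic: skipped
  expect_message(r3 <- variant_logistic(rep(1, n), y), "monomorphic")
  expect_true(r3$skipped)
  # null dosage: non-significant in distribution
  p_null <- replicate(50, {
    variant_logistic(rbinom(n, 2, 0.1), y)$p
  })
  expect_gt(mean(p_null > 0.05), 0.8)
})

test_that("inflation factor responds correctly to calibrated and inflated inputs", {
  set.seed(22)
  p <- runif(5000)
  expect_lt(abs(inflation_check(p) - 1), 0.05)
  expect_gt(inflation_check(p^2), 1)
  expect_warning(inflation_check(runif(50)), "unstable")
})

test_that("Bonferroni threshold reproduces the printed genome-wide cutoff", {
  th <- bonferroni_threshold(13268)
  # printed at three significant figures (truncated)
  expect_equal(trunc(th * 1e8) / 1e8, 3.76e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 0.0025)
})

test_that("phenome-wide scan enforces case-count, ratio and pool rules", {
  set.seed(23)
  n <- 4000
  ids <- sprintf("P%05d", 1:n)
  G <- matrix(rbinom(n * 4, 2, 0.01), n,
              dimnames = list(ids, paste0("v", 1:4)))
  pcs <- matrix(rnorm(n * 2), n, dimnames = list(ids, c("PC1", "PC2")))
  # phenotype A: 120 cases (kept); phenotype B: 99 cases (dropped)
  phe <- rbind(
    data.frame(sample_id = ids[1:120], code = "A"),
    data.frame(sample_id = ids[200:298], code = "B")
  )
  pool <- ids[1500:4000]
  res <- phewas_scan(G, phe, pool, pcs, seed = 5)
  expect_identical(res$code, "A")
  expect_equal(res$n_controls, 10 * res$n_cases)
  expect_true(res$p_skato > 0 && res$p_skato <= 1)
  # a pool that cannot supply 10x controls drops the phenotype
  expect_message(
    res2 <- phewas_scan(G, phe[phe$code == "A", ], ids[1500:1700], pcs),
    "too small")
  expect_equal(nrow(res2), 0)
})
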