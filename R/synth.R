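#' Simulation specification for a synthetic case-control exome cohort
#'
#' Bundles the study conditions under which the pipeline is exercised: cohort
#' size, marker counts, gene count, the designated risk genes with their
#' carrier-level effect, the admixture distribution, and the global seed. The
#' defaults are the conditions used throughout the package's own validation
#' suites: a balanced 1,500/1,500 cohort, 5 risk genes with aggregate carrier
#' odds ratio 3 and per-gene carrier frequency 10%, and two ancestral
#' populations at FST 0.1.
#'
#' @param n_cases Target number of cases (the realised count is binomial around
#'   the implied prevalence).
#' @param n_controls Target number of controls.
#' @param n_markers_common Number of common markers (used for ancestry, LD
#'   pruning, PCA).
#' @param n_genes Number of genes carrying rare variants.
#' @param variants_per_gene Rare variants simulated per gene.
#' @param risk_genes Character vector of risk gene ids; must be a subset of the
#'   generated genes `sprintf("G%04d", 1:n_genes)`.
#' @param risk_carrier_or Odds ratio (> 0) multiplying the odds of disease per
#'   risk gene in which a sample carries at least one qualifying allele;
#'   `1` yields a null cohort.
#' @param risk_carrier_freq Target carrier frequency, per risk gene, of its
#'   qualifying variant set.
#' @param fst Divergence between the two ancestral populations.
#' @param q_dist Function `function(n)` drawing `n` true admixture fractions
#'   (share attributed to the reference population). Default: everyone is an
#'   unadmixed member of the reference population.
#' @param missing_rate Fraction of genotype entries set missing.
#' @param prevalence Disease prevalence targeted by the logistic intercept;
#'   defaults to `n_cases / (n_cases + n_controls)`.
#' @param seed Integer global seed; expanded per stage via [child_seed()].
#' @return A list of class `sim_spec`.
#' @seealso [simulate_study()] which consumes the spec end to end.
#' @export
sim_spec <- function(n_cases = 1500, n_controls = 1500,
                     n_markers_common = 2000,
                     n_genes = 1000, variants_per_gene = 12,
                     risk_genes = sprintf("G%04d", 1:5),
                     risk_carrier_or = 3, risk_carrier_freq = 0.10,
                     fst = 0.1,
                     q_dist = function(n) rep(1, n),
                     missing_rate = 0.02,
                     prevalence = NULL,
                     seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_genes >= 1, variants_per_gene >= 1,
            n_markers_common >= 1, risk_carrier_or > 0, fst >= 0, fst < 1,
            missing_rate >= 0, missing_rate < 1)
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!all(risk_genes %in% genes)) {
    stop("risk_genes must be a subset of the generated gene ids G0001..")
  }
  spec <- list(
    n_cases = n_cases, n_controls = n_controls,
    n_samples = n_cases + n_controls,
    n_markers_common = n_markers_common,
    n_genes = n_genes, variants_per_gene = variants_per_gene,
    genes = genes, risk_genes = risk_genes,
    risk_carrier_or = risk_carrier_or, risk_carrier_freq = risk_carrier_freq,
    fst = fst, q_dist = q_dist, missing_rate = missing_rate,
    prevalence = prevalence %||% (n_cases / (n_cases + n_controls)),
    seed = seed
  )
  class(spec) <- "sim_spec"
  spec
}

#' Simulate two-population reference allele frequencies (Balding-Nichols)
#'
#' Draws an ancestral frequency per marker from Uniform(0.05, 0.95) and then
#' population-specific frequencies from the Balding-Nichols beta distribution
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)`; at `fst = 0` the two
#' populations share the ancestral frequency exactly. Frequencies are clipped
#' to `[0.01, 0.99]`. Each marker also gets a reference and alternate allele
#' (distinct bases drawn uniformly), so downstream strand-ambiguity rules can
#' be exercised.
#'
#' @param n_markers Number of markers (>= 1).
#' @param fst Divergence parameter in `[0, 1)`.
#' @param seed Integer seed.
#' @return A data.frame of class `ancestral_freqs` with columns `marker_id`,
#'   `ref`, `alt`, `freq_popA`, `freq_popB` and attribute `fst`.
#' @export
simulate_reference_panels <- function(n_markers, fst, seed) {
  if (!is.numeric(fst) || fst < 0 || fst >= 1) {
    stop("fst must lie in [0, 1)")
  }
  stopifnot(n_markers >= 1)
  set.seed(seed)
  p <- runif(n_markers, 0.05, 0.95)
  if (fst > 0) {
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    pA <- rbeta(n_markers, a, b)
    pB <- rbeta(n_markers, a, b)
  } else {
    pA <- p
    pB <- p
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_markers, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  out <- data.frame(
    marker_id = sprintf("m%06d", seq_len(n_markers)),
    ref = ref, alt = unname(alt),
    freq_popA = clip(pA, 0.01, 0.99),
    freq_popB = clip(pB, 0.01, 0.99),
    stringsAsFactors = FALSE
  )
  attr(out, "fst") <- fst
  class(out) <- c("ancestral_freqs", class(out))
  out
}

#' Simulate an admixed genotype cohort from a two-population panel
#'
#' Each sample receives a true admixture fraction `q` from `q_dist`; its
#' genotype at marker `m` is Binomial(2, q * pA_m + (1 - q) * pB_m). A
#' configurable fraction of entries is set missing completely at random.
#'
#' @param panel An `ancestral_freqs` data.frame from
#'   [simulate_reference_panels()].
#' @param n_samples Number of samples.
#' @param q_dist Function drawing true admixture fractions.
#' @param missing_rate Fraction of entries set missing.
#' @param seed Integer seed.
#' @param sample_prefix Prefix for generated sample ids.
#' @return List with `G` (samples x markers dosage matrix, NA = missing) and
#'   `samples` (data.frame `sample_id`, `q_true`, `pop_label`; label is
#'   `"popA"` when `q_true >= 0.5`).
#' @export
simulate_cohort <- function(panel, n_samples, q_dist = function(n) rep(1, n),
                            missing_rate = 0, seed = 1,
                            sample_prefix = "S") {
  stopifnot(inherits(panel, "ancestral_freqs"), n_samples >= 1,
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  q <- q_dist(n_samples)
  stopifnot(length(q) == n_samples, all(q >= 0 & q <= 1))
  m <- nrow(panel)
  f <- outer(q, panel$freq_popA) + outer(1 - q, panel$freq_popB)
  G <- matrix(rbinom(n_samples * m, 2L, as.vector(f)), nrow = n_samples)
  if (missing_rate > 0) {
    G[runif(length(G)) < missing_rate] <- NA_integer_
  }
  ids <- sprintf("%s%05d", sample_prefix, seq_len(n_samples))
  dimnames(G) <- list(ids, panel$marker_id)
  list(
    G = G,
    samples = data.frame(
      sample_id = ids, q_true = q,
      pop_label = ifelse(q >= 0.5, "popA", "popB"),
      stringsAsFactors = FALSE
    )
  )
}

## consequence categories retained by the high-impact filter
.whitelist_consequences <- c(
  "missense", "start_lost", "stop_lost", "stop_gained",
  "splice_acceptor", "splice_donor", "inframe_insertion", "inframe_deletion",
  "protein_altering", "start_retained", "stop_retained", "frameshift"
)

#' Consequence whitelist used by the high-impact filter
#'
#' @return Character vector of the retained consequence categories.
#' @export
whitelist_consequences <- function() .whitelist_consequences

#' Simulate a per-variant annotation table and per-gene metric table
#'
#' Generates the attributes the six-rule high-impact filter consumes:
#' consequence category (whitelisted classes, synonymous, and non-coding),
#' reference-population MAF (a configurable fraction missing, to exercise the
#' cohort-frequency fallback, and a configurable fraction deliberately drawn
#' above the 0.01 cutoff so the rule is exercised on both sides), CADD score,
#' per-gene mutation significance cutoff (MSC) and gene damage index (GDI)
#' with configurable missingness, and a blacklist flag. True cohort MAFs for
#' the rare variants are drawn log-uniform over `[1e-4, 5e-3]` so the
#' MAF < 0.01 rule sees both sides of the boundary.
#'
#' @param genes Character vector of gene ids.
#' @param variants_per_gene Variants simulated for each gene.
#' @param seed Integer seed.
#' @param p_consequence Named numeric vector of category probabilities over
#'   `c("missense", "other_whitelist", "synonymous", "noncoding")`.
#' @param p_ref_maf_missing Probability the reference MAF is missing.
#' @param p_common Probability a variant's true MAF is drawn common
#'   (Uniform(0.011, 0.05)) instead of rare, exercising the MAF rule.
#' @param p_blacklist Probability a variant is blacklisted.
#' @param p_msc_missing,p_gdi_missing Probability the per-gene MSC / GDI is
#'   missing.
#' @return List with `ann` (data.frame: `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, `true_maf`, `ref_maf`, `cadd`),
#'   `gene_metrics` (data.frame: `gene`, `msc_cadd`, `gdi`) and `blacklist`
#'   (character vector of blacklisted variant ids).
#' @export
simulate_annotations <- function(genes, variants_per_gene = 8, seed = 1,
                                 p_consequence = c(missense = 0.45,
                                                   other_whitelist = 0.15,
                                                   synonymous = 0.25,
                                                   noncoding = 0.15),
                                 p_ref_maf_missing = 0.2,
                                 p_common = 0.04,
                                 p_blacklist = 0.02,
                                 p_msc_missing = 0.10,
                                 p_gdi_missing = 0.05) {
  stopifnot(length(genes) >= 1, variants_per_gene >= 1)
  set.seed(seed)
  n <- length(genes) * variants_per_gene
  gene <- rep(genes, each = variants_per_gene)

  cat4 <- sample(names(p_consequence), n, replace = TRUE,
                 prob = p_consequence / sum(p_consequence))
  other <- setdiff(.whitelist_consequences, "missense")
  consequence <- ifelse(
    cat4 == "missense", "missense",
    ifelse(cat4 == "other_whitelist", sample(other, n, replace = TRUE),
           ifelse(cat4 == "synonymous", "synonymous", "intron"))
  )

  true_maf <- exp(runif(n, log(1e-4), log(5e-3)))
  common <- runif(n) < p_common
  true_maf[common] <- runif(sum(common), 0.011, 0.05)

  ref_maf <- true_maf * exp(rnorm(n, 0, 0.15))
  ref_maf <- clip(ref_maf, 0, 0.5)
  ref_maf[runif(n) < p_ref_maf_missing] <- NA_real_

  cadd <- clip(rnorm(n, 18, 6), 0, 60)

  msc <- clip(rnorm(length(genes), 15, 4), 0, 40)
  msc[runif(length(genes)) < p_msc_missing] <- NA_real_
  gdi <- exp(rnorm(length(genes), log(5), 0.7))
  gdi[runif(length(genes)) < p_gdi_missing] <- NA_real_

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  pos <- seq_len(n) * 100L

  ann <- data.frame(
    variant_id = sprintf("1:%d:%s:%s", pos, ref, unname(alt)),
    chrom = "1", pos = pos, ref = ref, alt = unname(alt),
    gene = gene, consequence = consequence,
    true_maf = true_maf, ref_maf = ref_maf, cadd = cadd,
    stringsAsFactors = FALSE
  )
  blacklist <- ann$variant_id[runif(n) < p_blacklist]
  list(
    ann = ann,
    gene_metrics = data.frame(gene = genes, msc_cadd = msc, gdi = gdi,
                              stringsAsFactors = FALSE),
    blacklist = blacklist
  )
}

#' Spike case/control phenotypes driven by qualifying risk-gene carriage
#'
#' Case probability follows a carrier-level (dominant) logistic model: the
#' intercept is solved so the expected prevalence matches the target, and each
#' risk gene in which a sample carries at least one qualifying alternate
#' allele multiplies its odds of disease by `risk_carrier_or`. With
#' `risk_carrier_or = 1` the cohort is null.
#'
#' @param G Samples x variants dosage matrix with variant-id column names.
#' @param qualifying_ids Variant ids that passed the high-impact filter.
#' @param variant_gene Named character vector mapping variant id to gene.
#' @param risk_genes Risk gene ids.
#' @param risk_carrier_or Per-risk-gene carrier odds ratio.
#' @param prevalence Target prevalence in (0, 1).
#' @param seed Integer seed.
#' @param per_allele If `TRUE`, odds scale per qualifying allele rather than
#'   per carried gene (additive coding); default is the dominant carrier model.
#' @return List with `y` (0/1 integer vector), `intercept`, `carriers`
#'   (samples x risk-genes carrier indicator matrix) and `degenerate` (TRUE
#'   when every sample, or no sample, carries; the carrier odds ratio is then
#'   undefined).
#' @export
spike_phenotypes <- function(G, qualifying_ids, variant_gene, risk_genes,
                             risk_carrier_or = 3, prevalence = 0.5, seed = 1,
                             per_allele = FALSE) {
  stopifnot(prevalence > 0, prevalence < 1, risk_carrier_or > 0)
  if (risk_carrier_or != 1 && length(risk_genes) == 0) {
    stop("risk_genes must be non-empty for a non-null simulation")
  }
  set.seed(seed)
  n <- nrow(G)
  carriers <- matrix(0L, n, length(risk_genes),
                     dimnames = list(rownames(G), risk_genes))
  for (g in risk_genes) {
    vid <- intersect(qualifying_ids, names(variant_gene)[variant_gene == g])
    vid <- intersect(vid, colnames(G))
    if (length(vid) == 0) next
    sub <- G[, vid, drop = FALSE]
    if (per_allele) {
      carriers[, g] <- as.integer(rowSums(sub, na.rm = TRUE))
    } else {
      carriers[, g] <- as.integer(rowSums(sub, na.rm = TRUE) >= 1)
    }
  }
  burden <- rowSums(carriers)
  eta_gene <- log(risk_carrier_or) * burden
  b0 <- uniroot(function(b) mean(plogis(b + eta_gene)) - prevalence,
                interval = c(-30, 30), tol = 1e-10)$root
  y <- as.integer(runif(n) < plogis(b0 + eta_gene))
  degenerate <- length(risk_genes) > 0 &&
    (all(rowSums(carriers) >= 1) || all(rowSums(carriers) == 0))
  list(y = y, intercept = b0, carriers = carriers, degenerate = degenerate)
}

#' Simulate a gene-by-gene biological distance matrix with a proximate core
#'
#' Produces a symmetric, zero-diagonal, positive matrix in which pairs drawn
#' from within `core_set` have systematically shorter distances (mean
#' `core_mean`) than all other pairs (mean `background_mean`), emulating a
#' gene connectome in which disease genes are mutually proximate. Distances
#' are gamma-distributed with the stated means; `gap = background_mean -
#' core_mean` is the tunable contrast, and `core_mean == background_mean`
#' yields an exchangeable (null) matrix.
#'
#' @param genes Gene ids.
#' @param core_set Subset of `genes` forming the proximate core.
#' @param seed Integer seed.
#' @param core_mean,background_mean Mean pairwise distance within the core and
#'   elsewhere.
#' @param shape Gamma shape parameter (controls spread).
#' @return Symmetric numeric matrix with `genes` as dimnames.
#' @export
simulate_distance_matrix <- function(genes, core_set = character(), seed = 1,
                                     core_mean = 5, background_mean = 15,
                                     shape = 10) {
  stopifnot(all(core_set %in% genes), core_mean > 0, background_mean > 0)
  set.seed(seed)
  n <- length(genes)
  D <- matrix(0, n, n, dimnames = list(genes, genes))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  in_core <- genes[idx[, 1]] %in% core_set & genes[idx[, 2]] %in% core_set
  mu <- ifelse(in_core, core_mean, background_mean)
  d <- rgamma(nrow(idx), shape = shape, rate = shape / mu)
  D[idx] <- d
  D <- D + t(D)
  D
}

#' Single-variant summary statistics from a training split (score regression)
#'
#' Computes, for every variant, a score-based effect estimate, standard error
#' and sample size from the training genotypes and phenotypes: with centred
#' dosage g and phenotype y, `U = sum(g (y - ybar))`, `V = ybar (1 - ybar)
#' sum((g - gbar)^2)`, `beta = U / V`, `se = 1 / sqrt(V)`. Monomorphic
#' variants are recorded with effect zero and infinite SE and flagged;
#' variants whose dosage separates the phenotype perfectly (|correlation| = 1)
#' are flagged as `separated`.
#'
#' @param G_train Training dosage matrix (samples x variants, column names are
#'   variant ids); must be disjoint from any evaluation split.
#' @param y_train 0/1 phenotype vector.
#' @param effect_allele Optional character vector of effect alleles (defaults
#'   to the alt allele parsed from `chrom:pos:ref:alt` ids when possible).
#' @return data.frame of class `gwas_summary`: `variant_id`, `effect_allele`,
#'   `beta`, `se`, `n`, `monomorphic`, `separated`.
#' @export
simulate_summary_stats <- function(G_train, y_train, effect_allele = NULL) {
  stopifnot(nrow(G_train) == length(y_train), all(y_train %in% c(0, 1)))
  n_called <- colSums(!is.na(G_train))
  ybar <- mean(y_train)
  Gc <- scale(G_train, center = TRUE, scale = FALSE)
  Gc[is.na(Gc)] <- 0
  U <- as.vector(crossprod(Gc, y_train - ybar))
  V <- ybar * (1 - ybar) * colSums(Gc^2)
  mono <- V <= 0
  beta <- ifelse(mono, 0, U / V)
  se <- ifelse(mono, Inf, 1 / sqrt(V))
  # perfect separation: dosage and phenotype perfectly correlated
  sep <- rep(FALSE, ncol(G_train))
  poly <- which(!mono)
  if (length(poly)) {
    cc <- suppressWarnings(cor(G_train[, poly, drop = FALSE], y_train,
                               use = "pairwise.complete.obs"))
    sep[poly] <- !is.na(cc) & abs(cc) >= 1 - 1e-12
  }
  ids <- colnames(G_train) %||% sprintf("v%06d", seq_len(ncol(G_train)))
  if (is.null(effect_allele)) {
    parts <- strsplit(ids, ":", fixed = TRUE)
    effect_allele <- vapply(parts, function(p) if (length(p) == 4L) p[4] else "A",
                            character(1))
  }
  out <- data.frame(
    variant_id = ids, effect_allele = effect_allele,
    beta = beta, se = se, n = n_called,
    monomorphic = mono, separated = sep,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("gwas_summary", class(out))
  out
}

#' Generate a complete synthetic study from a simulation specification
#'
#' Runs every generator stage under per-stage child seeds derived from
#' `spec$seed`: the two-population reference panel and common-marker cohort;
#' per-gene rare variants whose annotations carry the filterable attributes;
#' calibration of risk-gene qualifying-variant frequencies so each risk gene's
#' carrier frequency hits `spec$risk_carrier_freq`; rare genotypes; and spiked
#' phenotypes. The qualifying set used for spiking is the six-rule filter
#' applied with the true simulated MAFs, so the association stage must rediscover
#' it from the emitted annotation tables.
#'
#' @param spec A [sim_spec()] object.
#' @return List with elements `panel`, `common` (list `G`, `samples`), `ann`,
#'   `gene_metrics`, `blacklist`, `G_rare` (samples x rare variants),
#'   `variant_gene` (named map), `qualifying_true` (variant ids), `phen`
#'   (output of [spike_phenotypes()]), and `spec`.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  panel <- simulate_reference_panels(spec$n_markers_common, spec$fst,
                                     child_seed(spec$seed, "panel"))
  common <- simulate_cohort(panel, spec$n_samples, spec$q_dist,
                            spec$missing_rate, child_seed(spec$seed, "cohort"))
  antab <- simulate_annotations(spec$genes, spec$variants_per_gene,
                                child_seed(spec$seed, "annotations"))
  ann <- antab$ann
  variant_gene <- setNames(ann$gene, ann$variant_id)

  # qualifying set under the true frequencies (the generator's ground truth)
  gene_metrics <- antab$gene_metrics
  blacklist <- antab$blacklist
  qual <- high_impact_filter(
    ann, gene_metrics, blacklist, cohort_af = ann$true_maf
  )$qualifying

  # a designated risk gene must actually carry its designed effect: ensure
  # each has at least 7 qualifying variants (rewriting the attributes of its
  # earliest non-qualifying variants), so the carrier-frequency target is
  # attainable under the per-variant rare-MAF cap below
  if (length(spec$risk_genes) > 0) {
    for (g in spec$risk_genes) {
      vg <- ann$variant_id[ann$gene == g]
      need <- 7 - length(intersect(qual, vg))
      if (need <= 0) next
      fix <- setdiff(vg, qual)
      fix <- fix[seq_len(min(need, length(fix)))]
      idx <- match(fix, ann$variant_id)
      msc <- gene_metrics$msc_cadd[gene_metrics$gene == g]
      ann$consequence[idx] <- "missense"
      ann$cadd[idx] <- max(c(msc, 15), na.rm = TRUE) + 5
      ann$true_maf[idx] <- pmin(ann$true_maf[idx], 5e-3)
      ann$ref_maf[idx] <- ann$true_maf[idx]
      gene_metrics$gdi[gene_metrics$gene == g] <-
        min(gene_metrics$gdi[gene_metrics$gene == g], 13, na.rm = TRUE)
      blacklist <- setdiff(blacklist, fix)
    }
    qual <- high_impact_filter(
      ann, gene_metrics, blacklist, cohort_af = ann$true_maf
    )$qualifying
  }

  # calibrate risk-gene qualifying MAFs to the target carrier frequency:
  # P(carrier) = 1 - prod_j (1 - maf_j)^2 over the gene's qualifying
  # variants. Each scaled MAF stays strictly below the rare-variant cap so
  # the association stage's cohort-MAF guard cannot strip designed risk
  # variants; a gene with too few qualifying variants saturates at the cap
  # and realizes the largest attainable carrier frequency instead.
  maf <- ann$true_maf
  names(maf) <- ann$variant_id
  maf_cap <- 0.008
  for (g in spec$risk_genes) {
    vid <- intersect(qual, ann$variant_id[ann$gene == g])
    if (length(vid) == 0) next
    target <- spec$risk_carrier_freq
    attainable <- 1 - prod((1 - rep(maf_cap, length(vid)))^2)
    if (attainable <= target) {
      maf[vid] <- maf_cap
    } else {
      f <- uniroot(function(s) {
        1 - prod((1 - clip(maf[vid] * exp(s), 0, maf_cap))^2) - target
      }, interval = c(-10, 10), tol = 1e-10)$root
      maf[vid] <- clip(maf[vid] * exp(f), 0, maf_cap)
    }
  }

  set.seed(child_seed(spec$seed, "rare_geno"))
  n <- spec$n_samples
  G_rare <- matrix(rbinom(n * nrow(ann), 2L, rep(maf, each = n)), nrow = n)
  dimnames(G_rare) <- list(common$samples$sample_id, ann$variant_id)

  phen <- spike_phenotypes(G_rare, qual, variant_gene, spec$risk_genes,
                           spec$risk_carrier_or, spec$prevalence,
                           child_seed(spec$seed, "phenotype"))
  list(panel = panel, common = common, ann = ann,
       gene_metrics = gene_metrics, blacklist = blacklist,
       G_rare = G_rare, variant_gene = variant_gene,
       qualifying_true = qual, phen = phen, spec = spec)
}
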