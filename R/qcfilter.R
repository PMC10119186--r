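#' Split multiallelic records into biallelic records
#'
#' Expands each record with a comma-separated ALT field into one record per
#' alternate allele. Genotype strings are recoded against each split allele
#' (the dosage counts occurrences of that allele index; other alternate
#' alleles count as reference), per-allele AD fields are redistributed to
#' `ref,alt_k`, and the ID is regenerated as `chrom:pos:ref:alt`. Records with
#' a malformed genotype field are skipped with a warning.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated alternates) and optionally `id`.
#' @param gt Character matrix (records x samples) of genotype strings like
#'   `"0/1"` or `"1|2"` (`"./."` for missing).
#' @param ad Optional character matrix of comma-separated per-allele depths
#'   aligned to `records`/`gt`.
#' @return List with `records` (biallelic data.frame, one row per output
#'   allele, ID normalised), `dosage` (output-records x samples integer
#'   matrix, NA for missing) and `ad` (redistributed depths, or NULL).
#' @export
split_multiallelic <- function(records, gt, ad = NULL) {
  stopifnot(nrow(records) == nrow(gt))
  out_rec <- list(); out_dos <- list(); out_ad <- list()
  for (i in seq_len(nrow(records))) {
    alts <- strsplit(records$alt[i], ",", fixed = TRUE)[[1]]
    g <- gt[i, ]
    toks <- strsplit(g, "[/|]")
    bad <- vapply(toks, function(t) {
      length(t) != 2L || !all(t %in% c(".", as.character(0:length(alts))))
    }, logical(1))
    if (any(bad)) {
      warning(sprintf("record %s:%s skipped: malformed genotype field",
                      records$chrom[i], records$pos[i]))
      next
    }
    for (k in seq_along(alts)) {
      dos <- vapply(toks, function(t) {
        if (any(t == ".")) return(NA_integer_)
        sum(t == as.character(k))
      }, integer(1))
      rec <- records[i, , drop = FALSE]
      rec$alt <- alts[k]
      rec$id <- sprintf("%s:%s:%s:%s", rec$chrom, rec$pos, rec$ref, alts[k])
      out_rec[[length(out_rec) + 1L]] <- rec
      out_dos[[length(out_dos) + 1L]] <- dos
      if (!is.null(ad)) {
        fields <- strsplit(ad[i, ], ",", fixed = TRUE)
        out_ad[[length(out_ad) + 1L]] <- vapply(fields, function(f) {
          if (length(f) >= k + 1L) paste(f[1], f[k + 1L], sep = ",") else NA_character_
        }, character(1))
      }
    }
  }
  recs <- do.call(rbind, out_rec)
  rownames(recs) <- NULL
  list(
    records = recs,
    dosage = do.call(rbind, out_dos),
    ad = if (is.null(ad)) NULL else do.call(rbind, out_ad)
  )
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Levene-Haldane exact test on genotype counts: conditional on the observed
#' allele counts, enumerates all heterozygote counts of matching parity,
#' computes their probabilities from log-factorials, and sums the
#' probabilities of configurations no more likely than the observed one
#' (two-sided).
#'
#' @param n_aa,n_ab,n_bb Counts of the three genotypes.
#' @return Exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na <- 2 * n_aa + n_ab # minor-or-not irrelevant; symmetric
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- lgamma(n + 1) - lgamma((na - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - na - hets) / 2 + 1) + hets * log(2) +
    lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  sum(p[p <= p[obs] * (1 + 1e-9)])
}

#' Variant-level quality control
#'
#' Removes variants failing any of: mean depth below `dp_min` or mean
#' genotype quality below `gq_min` (when per-genotype DP/GQ matrices are
#' supplied); no alternate-allele carrier with `DP >= dp_min` and
#' `GQ >= gq_min`; call rate below `call_rate_min`; Hardy-Weinberg exact-test
#' p below `hwe_p_min`, computed in controls (standard practice, so true risk
#' variants out of equilibrium in cases are not discarded); and differential
#' case/control missingness with Fisher exact p below `diff_miss_p_min`.
#' Sub-rules whose inputs are absent are skipped with a notice.
#'
#' @param G Samples x variants dosage matrix.
#' @param phenotype 0/1 vector (controls = 0) for the HWE and differential
#'   missingness rules.
#' @param dp,gq Optional samples x variants depth / quality matrices.
#' @param dp_min,gq_min,call_rate_min,hwe_p_min,diff_miss_p_min Thresholds.
#' @return List with `pass` (logical per variant), `report` (data.frame of
#'   per-rule failure counts) and `rules` (logical matrix, TRUE = failed).
#' @export
qc_variants <- function(G, phenotype, dp = NULL, gq = NULL,
                        dp_min = 10, gq_min = 20, call_rate_min = 0.95,
                        hwe_p_min = 1e-6, diff_miss_p_min = 1e-5) {
  m <- ncol(G)
  stopifnot(length(phenotype) == nrow(G))
  fail <- matrix(FALSE, m, 4,
                 dimnames = list(colnames(G),
                                 c("depth_quality", "call_rate", "hwe",
                                   "diff_missingness")))
  if (!is.null(dp) && !is.null(gq)) {
    mean_ok <- colMeans(dp, na.rm = TRUE) >= dp_min &
      colMeans(gq, na.rm = TRUE) >= gq_min
    carrier_ok <- vapply(seq_len(m), function(j) {
      alt <- !is.na(G[, j]) & G[, j] > 0
      any(alt & dp[, j] >= dp_min & gq[, j] >= gq_min, na.rm = TRUE) || !any(alt)
    }, logical(1))
    fail[, "depth_quality"] <- !(mean_ok & carrier_ok)
  } else {
    message("DP/GQ not supplied; depth/quality sub-rules skipped")
  }
  fail[, "call_rate"] <- colMeans(!is.na(G)) < call_rate_min
  ctrl <- phenotype == 0
  fail[, "hwe"] <- vapply(seq_len(m), function(j) {
    g <- G[ctrl, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(FALSE)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2)) < hwe_p_min
  }, logical(1))
  miss <- is.na(G)
  fail[, "diff_missingness"] <- vapply(seq_len(m), function(j) {
    tab <- matrix(c(sum(miss[ctrl, j]), sum(!miss[ctrl, j]),
                    sum(miss[!ctrl, j]), sum(!miss[!ctrl, j])), 2)
    if (all(tab[1, ] == 0)) return(FALSE)
    stats::fisher.test(tab)$p.value < diff_miss_p_min
  }, logical(1))
  list(pass = rowSums(fail) == 0 & rep(TRUE, m),
       report = data.frame(rule = colnames(fail), n_failed = colSums(fail)),
       rules = fail)
}

#' Per-sample quality-control metrics
#'
#' Computes, per sample: the heterozygous / homozygous-alternate genotype
#' ratio, the transition/transversion ratio over carried SNVs, the
#' insertion/deletion ratio over carried indels, and the missing-genotype
#' rate.
#'
#' @param G Samples x variants dosage matrix.
#' @param ref,alt Character vectors of alleles, one per variant.
#' @return data.frame: `sample_id`, `het_hom_ratio`, `titv_ratio`,
#'   `insdel_ratio`, `missing_rate`.
#' @export
sample_qc_metrics <- function(G, ref, alt) {
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1
  ti <- is_snv & paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
  tv <- is_snv & !ti
  ins <- !is_snv & nchar(alt) > nchar(ref)
  del <- !is_snv & nchar(alt) < nchar(ref)
  carried <- !is.na(G) & G > 0
  het <- !is.na(G) & G == 1
  hom <- !is.na(G) & G == 2
  data.frame(
    sample_id = rownames(G) %||% sprintf("S%05d", seq_len(nrow(G))),
    het_hom_ratio = rowSums(het) / pmax(rowSums(hom), 1e-12),
    titv_ratio = rowSums(carried[, ti, drop = FALSE]) /
      pmax(rowSums(carried[, tv, drop = FALSE]), 1e-12),
    insdel_ratio = rowSums(carried[, ins, drop = FALSE]) /
      pmax(rowSums(carried[, del, drop = FALSE]), 1e-12),
    missing_rate = rowMeans(is.na(G)),
    stringsAsFactors = FALSE
  )
}

#' Pairwise robust kinship coefficients (shared-heterozygosity estimator)
#'
#' For each sample pair, the within-pair robust kinship coefficient
#' `phi = (N_AaAa - 2 N_AAaa) / (N_Aa,i + N_Aa,j)`, where `N_AaAa` counts
#' jointly heterozygous markers, `N_AAaa` counts opposite homozygotes, and
#' `N_Aa,i` counts heterozygous markers of sample i over loci called in both.
#' A sample against itself gives 0.5; monozygotic duplicates approach 0.5,
#' parent-offspring pairs 0.25, and unrelated samples 0.
#'
#' @param G Samples x markers dosage matrix (>= 200 informative markers
#'   recommended).
#' @param min_joint Pairs with fewer jointly called markers are flagged.
#' @return List with `phi` (symmetric matrix), `n_joint` (jointly called
#'   marker counts) and `flagged` (logical matrix, TRUE where `n_joint <
#'   min_joint`).
#' @export
kinship <- function(G, min_joint = 50) {
  called <- !is.na(G)
  H <- called & G == 1
  A0 <- called & G == 0
  A2 <- called & G == 2
  storage.mode(H) <- "numeric"
  storage.mode(A0) <- "numeric"
  storage.mode(A2) <- "numeric"
  C <- called
  storage.mode(C) <- "numeric"
  het_het <- tcrossprod(H)
  opp_hom <- tcrossprod(A0, A2)
  opp_hom <- opp_hom + t(opp_hom)
  het_i <- tcrossprod(H, C) # het in i over loci called in j
  denom <- het_i + t(het_i)
  phi <- (het_het - 2 * opp_hom) / pmax(denom, 1e-12)
  n_joint <- tcrossprod(C)
  dimnames(phi) <- dimnames(n_joint) <- list(rownames(G), rownames(G))
  list(phi = phi, n_joint = n_joint, flagged = n_joint < min_joint)
}

#' Sample-level quality control
#'
#' Removes samples: falling outside `mad_k` median absolute deviations from
#' the median for any of the het/hom, Ti/Tv or ins/del ratios (a metric with
#' zero MAD is skipped, so degenerate spread never divides by zero; with
#' fewer than 10 samples the MAD rule is skipped entirely with a warning);
#' with missing-genotype rate above `miss_max`; or forming a pair with
#' kinship above `kin_max`, from which the member with the higher missing
#' rate is dropped (ties broken by later sample order).
#'
#' @param metrics data.frame from [sample_qc_metrics()].
#' @param kin Optional result of [kinship()] on the same samples.
#' @param mad_k MAD multiplier (default 4).
#' @param miss_max Maximum missing rate (default 0.03).
#' @param kin_max Kinship threshold above which a pair is resolved (default
#'   0.185).
#' @return List with `retained` (sample ids), `removed` (data.frame
#'   `sample_id`, `reason`).
#' @export
qc_samples <- function(metrics, kin = NULL, mad_k = 4, miss_max = 0.03,
                       kin_max = 0.185) {
  ids <- metrics$sample_id
  removed <- character(); reason <- character()
  drop_mad <- rep(FALSE, length(ids))
  if (length(ids) < 10) {
    warning("fewer than 10 samples; MAD outlier rule skipped (unstable)")
  } else {
    for (mname in c("het_hom_ratio", "titv_ratio", "insdel_ratio")) {
      x <- metrics[[mname]]
      md <- stats::median(x)
      mad <- stats::median(abs(x - md))
      if (mad == 0) next
      drop_mad <- drop_mad | abs(x - md) > mad_k * mad
    }
  }
  removed <- c(removed, ids[drop_mad])
  reason <- c(reason, rep("mad_outlier", sum(drop_mad)))
  drop_miss <- metrics$missing_rate > miss_max & !drop_mad
  removed <- c(removed, ids[drop_miss])
  reason <- c(reason, rep("missing_rate", sum(drop_miss)))
  kept <- setdiff(ids, removed)
  if (!is.null(kin)) {
    phi <- kin$phi[kept, kept, drop = FALSE]
    miss <- setNames(metrics$missing_rate, ids)
    repeat {
      ut <- which(upper.tri(phi) & phi > kin_max, arr.ind = TRUE)
      if (nrow(ut) == 0) break
      i <- rownames(phi)[ut[1, 1]]
      j <- colnames(phi)[ut[1, 2]]
      drop <- if (miss[i] > miss[j]) i else j
      removed <- c(removed, drop)
      reason <- c(reason, "kinship")
      kept <- setdiff(kept, drop)
      phi <- phi[kept, kept, drop = FALSE]
    }
  }
  list(retained = kept,
       removed = data.frame(sample_id = removed, reason = reason,
                            stringsAsFactors = FALSE))
}

#' Six-rule high-impact rare-variant filter
#'
#' Retains a variant if and only if all of the following hold: (a) its
#' consequence is in the high-impact whitelist (see
#' [whitelist_consequences()]); (b) its effective minor allele frequency -
#' the reference-population MAF when present, otherwise the cohort allele
#' frequency - is at most `maf_max` (boundary inclusive); (c) its CADD score
#' is at least its gene's mutation significance cutoff, or at least
#' `msc_fallback` when the gene has no MSC; (d) its gene's damage index is
#' strictly below `gdi_max` (a gene with no GDI passes); (e) it is not
#' blacklisted; and, when site-level depth and mapping-quality vectors are
#' supplied, (f) `DP > dp_min` and `MQ > mq_min`. Variants with no gene
#' assignment are excluded and counted separately. Per-rule attrition counts
#' are returned.
#'
#' @param ann Annotation data.frame with columns `variant_id`, `gene`,
#'   `consequence`, `ref_maf`, `cadd`.
#' @param gene_metrics data.frame with columns `gene`, `msc_cadd`, `gdi`.
#' @param blacklist Character vector of blacklisted variant ids.
#' @param cohort_af Numeric vector of cohort allele frequencies aligned to
#'   `ann` rows (the fallback when `ref_maf` is missing).
#' @param maf_max MAF cutoff (retain iff effective MAF `<= maf_max`).
#' @param gdi_max GDI cutoff (retain iff `gdi < gdi_max`; 13.34 is the
#'   generalised human-disease cutoff).
#' @param msc_fallback CADD threshold applied when the gene's MSC is missing.
#' @param dp,mq Optional site-level depth / mapping quality vectors.
#' @param dp_min,mq_min Site-quality thresholds (strict `>`).
#' @return List with `qualifying` (variant ids), `keep` (logical per row),
#'   `attrition` (data.frame `rule`, `n_failed`), `n_no_gene` (variants
#'   excluded for missing gene assignment) and `rules` (per-rule pass
#'   matrix).
#' @export
high_impact_filter <- function(ann, gene_metrics, blacklist, cohort_af,
                               maf_max = 0.01, gdi_max = 13.34,
                               msc_fallback = 15,
                               dp = NULL, mq = NULL, dp_min = 10, mq_min = 40) {
  stopifnot(length(cohort_af) == nrow(ann))
  has_gene <- !is.na(ann$gene) & ann$gene != ""
  gm <- gene_metrics[match(ann$gene, gene_metrics$gene), ]
  eff_maf <- ifelse(is.na(ann$ref_maf), pmin(cohort_af, 1 - cohort_af),
                    ann$ref_maf)
  pass <- cbind(
    consequence = ann$consequence %in% .whitelist_consequences,
    maf = !is.na(eff_maf) & eff_maf <= maf_max,
    msc = ifelse(is.na(gm$msc_cadd), ann$cadd >= msc_fallback,
                 ann$cadd >= gm$msc_cadd),
    gdi = is.na(gm$gdi) | gm$gdi < gdi_max,
    blacklist = !(ann$variant_id %in% blacklist)
  )
  if (!is.null(dp) && !is.null(mq)) {
    pass <- cbind(pass, site_quality = dp > dp_min & mq > mq_min)
  }
  keep <- has_gene & rowSums(!pass) == 0
  attrition <- data.frame(
    rule = c(colnames(pass), "no_gene"),
    n_failed = c(colSums(!pass[has_gene, , drop = FALSE]), sum(!has_gene))
  )
  list(qualifying = ann$variant_id[keep], keep = keep,
       attrition = attrition, n_no_gene = sum(!has_gene), rules = pass)
}
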