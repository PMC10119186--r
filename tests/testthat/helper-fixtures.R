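# Small in-code fixtures shared across test files.

# tiny deterministic cohort for cheap unit tests
tiny_study <- function(seed = 11, n_genes = 60, ...) {
  spec <- sim_spec(n_cases = 150, n_controls = 150, n_markers_common = 300,
                   n_genes = n_genes, seed = seed, ...)
  simulate_study(spec)
}

# independent brute-force implementation of the six filter rules, written
# against the rule statements (not the package code), used as the oracle
oracle_filter <- function(ann, gene_metrics, blacklist, cohort_af,
                          maf_max = 0.01, gdi_max = 13.34, msc_fallback = 15) {
  keep <- character()
  for (i in seq_len(nrow(ann))) {
    v <- ann[i, ]
    if (is.na(v$gene) || v$gene == "") next
    if (!(v$consequence %in% whitelist_consequences())) next
    af <- if (!is.na(v$ref_maf)) v$ref_maf else min(cohort_af[i], 1 - cohort_af[i])
    if (is.na(af) || af > maf_max) next
    g <- gene_metrics[gene_metrics$gene == v$gene, ]
    msc <- if (nrow(g) == 1) g$msc_cadd else NA
    gdi <- if (nrow(g) == 1) g$gdi else NA
    if (is.na(msc)) {
      if (v$cadd < msc_fallback) next
    } else if (v$cadd < msc) next
    if (!is.na(gdi) && gdi >= gdi_max) next
    if (v$variant_id %in% blacklist) next
    keep <- c(keep, v$variant_id)
  }
  keep
}

# Hudson-style FST ratio-of-means estimator on two population frequency
# vectors (frequencies known, no sampling correction needed)
hudson_fst <- function(p1, p2) {
  mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}
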