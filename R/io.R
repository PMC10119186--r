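## Plain-text interchange formats: tab-delimited tables for dosage matrices,
## annotations, gene metrics, blacklists, distance matrices and summary
## statistics, plus minimal VCF v4.2 support (reading via vcfR).

#' Write / read a dosage matrix as TSV
#'
#' Rows are samples, columns are variants; missing dosages are empty cells.
#'
#' @param G Samples x variants dosage matrix.
#' @param path File path.
#' @return `read_dosage_tsv` returns the dosage matrix.
#' @export
write_dosage_tsv <- function(G, path) {
  df <- data.frame(sample_id = rownames(G), G, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "")
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$sample_id
  storage.mode(G) <- "double"
  G
}

#' Write / read the per-variant annotation table
#'
#' @param ann Annotation data.frame.
#' @param path File path.
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, colClasses = c(chrom = "character"))
}

#' Write / read the per-gene metric table (MSC, GDI)
#'
#' @param gene_metrics data.frame with `gene`, `msc_cadd`, `gdi`.
#' @param path File path.
#' @export
write_gene_metrics_tsv <- function(gene_metrics, path) {
  utils::write.table(gene_metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' @rdname write_gene_metrics_tsv
#' @export
read_gene_metrics_tsv <- function(path) utils::read.delim(path)

#' Write / read a variant blacklist (one variant id per line)
#'
#' @param blacklist Character vector of variant ids.
#' @param path File path.
#' @export
write_blacklist <- function(blacklist, path) writeLines(blacklist, path)

#' @rdname write_blacklist
#' @export
read_blacklist <- function(path) readLines(path)

#' Write / read a square gene x gene distance matrix as TSV
#'
#' @param D Symmetric distance matrix with gene dimnames.
#' @param path File path.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(gene = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df$gene
  D
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns: `variant_id`, `effect_allele`, `beta`, `se`, `n` (and any flag
#' columns present).
#'
#' @param summary `gwas_summary` data.frame.
#' @param path File path.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  out <- utils::read.delim(path)
  class(out) <- c("gwas_summary", class(out))
  out
}

#' Read genotypes from a VCF file into a dosage matrix
#'
#' Parses a (biallelic) VCF with vcfR and returns alternate-allele dosages
#' plus the variant table; per-genotype DP and GQ matrices are extracted
#' when present.
#'
#' @param path VCF file path.
#' @return List: `G` (samples x variants dosage, NA = missing), `variants`
#'   (data.frame `variant_id`, `chrom`, `pos`, `ref`, `alt`), `dp`, `gq`
#'   (samples x variants or NULL).
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, 2, function(col) {
    toks <- strsplit(col, "[/|]")
    vapply(toks, function(t) {
      if (length(t) == 0 || any(is.na(t)) || any(t == ".")) return(NA_integer_)
      sum(t != "0")
    }, integer(1))
  })
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = sprintf("%s:%s:%s:%s", fix$CHROM, fix$POS, fix$REF, fix$ALT),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  G <- t(dos) # variants x samples -> samples x variants
  dimnames(G) <- list(colnames(gt), variants$variant_id)
  fmt <- strsplit(v@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
  grab <- function(el) {
    if (!el %in% fmt) return(NULL)
    m <- suppressWarnings(vcfR::extract.gt(v, element = el, as.numeric = TRUE))
    t(m)[colnames(gt), , drop = FALSE]
  }
  dp <- tryCatch(grab("DP"), error = function(e) NULL)
  gq <- tryCatch(grab("GQ"), error = function(e) NULL)
  if (!is.null(dp)) colnames(dp) <- variants$variant_id
  if (!is.null(gq)) colnames(gq) <- variants$variant_id
  list(G = G, variants = variants, dp = dp, gq = gq)
}

#' Write a dosage matrix as a minimal VCF v4.2
#'
#' Emits biallelic records with GT fields (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param G Samples x variants dosage matrix.
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `variant_id`) aligned to the columns of `G`.
#' @param path Output path.
#' @export
write_vcf_dosage <- function(G, variants, path) {
  stopifnot(ncol(G) == nrow(variants))
  ids <- variants$variant_id %||%
    sprintf("%s:%s:%s:%s", variants$chrom, variants$pos, variants$ref,
            variants$alt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
    writeLines(paste(c(variants$chrom[j], variants$pos[j], ids[j],
                       variants$ref[j], variants$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
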