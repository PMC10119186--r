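#' Consensus genes across pathway-method prioritized sets
#'
#' Genes present in every method's prioritized set, plus per-gene method-hit
#' counts for relaxed k-of-n consensus. An empty intersection is a valid
#' (logged) outcome.
#'
#' @param method_sets Named list (>= 2 methods) of character gene vectors.
#' @return List: `consensus` (genes in every set), `hits` (named integer
#'   vector of method counts per gene).
#' @export
intersect_methods <- function(method_sets) {
  stopifnot(length(method_sets) >= 2)
  all_genes <- unique(unlist(method_sets))
  hits <- vapply(all_genes, function(g) {
    sum(vapply(method_sets, function(s) g %in% s, logical(1)))
  }, integer(1))
  consensus <- Reduce(intersect, method_sets)
  if (length(consensus) == 0) message("empty consensus across methods")
  list(consensus = consensus, hits = sort(hits, decreasing = TRUE))
}

#' Biological-importance score from significant pathways and modules
#'
#' For each queried gene, sums over all significant pathways/modules that
#' contain the gene - across every method - the number of known disease
#' genes among that pathway's members. Method-specific significance cutoffs
#' are applied upstream (via the `significant` column or a per-method alpha
#' map). A gene absent from every pathway scores 0.
#'
#' @param genes Genes to score.
#' @param pathway_sets data.frame with columns `method`, `pathway_id`,
#'   `members` (list-column of character vectors, or `;`-separated strings),
#'   and either `significant` (logical) or `p` (combined with `alpha`).
#' @param known Known disease-gene set.
#' @param alpha Named per-method significance cutoffs used when
#'   `significant` is absent (e.g. `c(innatedb = 0.05, ipa = 0.01)`); a
#'   single unnamed value applies to all methods.
#' @return Named integer vector of scores.
#' @export
importance_score <- function(genes, pathway_sets, known, alpha = 0.05) {
  members <- pathway_sets$members
  if (!is.list(members)) members <- strsplit(members, ";", fixed = TRUE)
  if ("significant" %in% names(pathway_sets)) {
    sig <- pathway_sets$significant
  } else {
    if (!"p" %in% names(pathway_sets)) stop("need `significant` or `p` column")
    cut <- if (is.null(names(alpha))) {
      rep(alpha[1], nrow(pathway_sets))
    } else {
      unname(alpha[pathway_sets$method])
    }
    if (any(is.na(cut))) stop("missing alpha for some method")
    sig <- pathway_sets$p < cut
  }
  known_in <- vapply(members, function(m) length(intersect(m, known)),
                     integer(1))
  scores <- vapply(genes, function(g) {
    in_path <- vapply(members, function(m) g %in% m, logical(1))
    sum(known_in[sig & in_path])
  }, integer(1))
  setNames(as.integer(scores), genes)
}

#' Genes in the joint top fraction of two rankings
#'
#' Returns genes in the top `fraction` by importance score (descending) and
#' simultaneously in the top `fraction` by association p-value (ascending).
#' Rank ties at the boundary are resolved inclusively: every gene tied with
#' the boundary value is admitted.
#'
#' @param scores Named numeric vector of importance scores.
#' @param assoc_p Named numeric vector of association p-values over the same
#'   gene universe.
#' @param fraction Top fraction (default 0.10).
#' @return Character vector of genes in both top sets.
#' @export
joint_top_fraction <- function(scores, assoc_p, fraction = 0.10) {
  genes <- names(scores)
  stopifnot(setequal(genes, names(assoc_p)), fraction > 0, fraction <= 1)
  n_top <- ceiling(fraction * length(genes))
  s_cut <- sort(scores, decreasing = TRUE)[n_top]
  p_cut <- sort(assoc_p)[n_top]
  top_s <- genes[scores >= s_cut]
  top_p <- genes[assoc_p[genes] <= p_cut]
  intersect(top_s, top_p)
}
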