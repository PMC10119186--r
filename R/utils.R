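#' Derive a per-stage child seed from one global seed
#'
#' One global integer seed is expanded into independent per-stage seeds by a
#' deterministic polynomial hash of the stage label, so that fixing the global
#' seed fixes every emitted artifact while stages remain decoupled (adding a
#' stage never perturbs another stage's stream).
#'
#' The scheme is: `h <- seed`; then for each byte `b` of the UTF-8 stage label,
#' `h <- (h * 31 + b) mod (2^31 - 1)`. All arithmetic stays below 2^53 so the
#' double-precision computation is exact.
#'
#' @param seed Integer global seed (non-negative, below 2^31).
#' @param stage Character scalar naming the stage (e.g. `"panel"`, `"cohort"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "panel")
#' child_seed(1, "cohort")
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed < 2^31)
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.double(seed) %% m
  for (b in as.integer(charToRaw(stage))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

## clip numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Column-wise allele frequencies of a dosage matrix
#'
#' `col_af` returns the alternate-allele frequency per variant (NA-aware);
#' `col_maf` folds it to the minor allele frequency.
#'
#' @param G Samples x variants dosage matrix.
#' @return Numeric vector, one value per variant column.
#' @export
col_af <- function(G) colMeans(G, na.rm = TRUE) / 2

#' @rdname col_af
#' @export
col_maf <- function(G) {
  af <- col_af(G)
  pmin(af, 1 - af)
}

## Mann-Whitney AUC used only for quick internal diagnostics; user-facing AUCs
## go through pROC (see classify()).
.auc_rank <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
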