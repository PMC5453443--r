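# One-sided Fisher exact over-representation and multiple-testing control.
#
# The 2x2 table convention: k DE genes carrying the motif out of K DE genes,
# n background genes carrying it out of N background genes, with the DE genes
# contained in the background. Under the null the motif-carrier count among
# DE genes is hypergeometric(N, n, K) and the one-sided (greater) p-value is
# the upper tail P(X >= k).

validate_contingency <- function(k, K, n, N) {
  v <- c(k = k, K = K, n = n, N = N)
  if (any(is.na(v)) || any(v != round(v)) || any(v < 0)) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  if (K > N || n > N || k > K || k > n) {
    stop("invalid contingency table: need k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  invisible(v)
}

#' One-sided (greater) Fisher exact p-value for a 2x2 enrichment table
#'
#' @param k DE genes with the feature.
#' @param K Total DE genes.
#' @param n Background genes with the feature.
#' @param N Total background genes (background includes the DE genes).
#' @return `P(X >= k)` for `X ~ hypergeometric(N, n, K)`, computed on the
#'   upper tail in one call (no 1-minus-CDF cancellation).
#' @export
fisher_greater <- function(k, K, n, N) {
  validate_contingency(k, K, n, N)
  if (k == 0) return(1)
  phyper(k - 1, m = n, n = N - n, k = K, lower.tail = FALSE)
}

#' Bonferroni family-wise correction
#'
#' @param p_values Numeric vector of raw p-values in `[0,1]`.
#' @param m Family size; defaults to `length(p_values)` and may be larger
#'   (e.g. when only a subset of a tested family is being adjusted).
#' @return Adjusted p-values `min(1, m * p)`, in input order.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  assert_probability(p_values)
  if (m < length(p_values)) {
    stop("family size m must be >= number of p-values", call. = FALSE)
  }
  if (!length(p_values)) return(numeric(0))
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' @param p_values Numeric vector of raw p-values in `[0,1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p_values) {
  assert_probability(p_values)
  if (!length(p_values)) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

# Shared Fisher driver over a gene x feature presence matrix.
enrichment_rows <- function(presence, de_genes, background, contrast,
                            alpha, correction, family_size = NULL) {
  de_genes <- unique(de_genes)
  background <- unique(background)
  if (!all(de_genes %in% background)) {
    stop("de_genes must be a subset of the background universe",
         call. = FALSE)
  }
  if (!length(background)) stop("empty background universe", call. = FALSE)
  if (!length(de_genes)) {
    warning("empty DE gene list: no enrichment rows", call. = FALSE)
    return(data.frame(test_id = character(), contrast = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      method = character(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  bg <- presence[background, , drop = FALSE]
  K <- length(de_genes)
  N <- length(background)
  n <- colSums(bg)
  k <- colSums(bg[de_genes, , drop = FALSE])
  p_raw <- vapply(seq_along(n), function(j) {
    fisher_greater(k[j], K, n[j], N)
  }, numeric(1))
  m <- family_size %||% length(p_raw)
  p_adj <- if (correction == "bonferroni") bonferroni(p_raw, m) else
    bh_fdr(p_raw)
  out <- data.frame(test_id = colnames(presence), contrast = contrast,
                    k = as.integer(k), K = K, n = as.integer(n), N = N,
                    p_raw = p_raw, p_adj = p_adj, method = correction,
                    significant = p_adj <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_raw, out$test_id), , drop = FALSE]
}

#' Per-motif promoter enrichment among DE genes
#'
#' For each motif, builds the 2x2 table from gene-level presence restricted
#' to the background universe, applies the one-sided Fisher exact test, and
#' corrects across the motif family within the contrast (Bonferroni by
#' default). Genes whose promoters were empty stay in the background with
#' presence false: they were scanned and could not contribute hits.
#'
#' @param hits `motif_hits` object from [scan_promoters()].
#' @param de_genes Character vector of DE gene ids (subset of `background`).
#' @param background Character vector: the gene universe, typically all genes
#'   in the contrast's DE table. Defaults to all scanned genes.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param contrast Label attached to the rows.
#' @param family_size Bonferroni family size; defaults to the number of
#'   motifs tested.
#' @return data.frame of enrichment rows sorted by raw p (ties by motif id):
#'   `test_id`, `contrast`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `method`,
#'   `significant`.
#' @export
motif_enrichment <- function(hits, de_genes, background = hits$genes,
                             alpha = 0.05,
                             correction = c("bonferroni", "bh"),
                             contrast = "contrast", family_size = NULL) {
  correction <- match.arg(correction)
  if (!all(background %in% hits$genes)) {
    stop("background must be a subset of the scanned genes", call. = FALSE)
  }
  enrichment_rows(hits$presence, de_genes, background, contrast, alpha,
                  correction, family_size)
}
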