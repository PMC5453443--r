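# Strand-aware promoter extraction.
#
# GFF3 coordinates stay 1-based inclusive throughout the package; this module
# is the single place where upstream windows are computed from them, so there
# is exactly one conversion site.

#' Extract the upstream promoter of one gene
#'
#' For a `+` strand gene the promoter is the genomic window
#' `[start-length, start-1]` read left to right; for a `-` strand gene it is
#' the reverse complement of `[end+1, end+length]`. Either way the returned
#' sequence reads 5'->3' toward the gene. Windows are clipped at contig
#' boundaries and flagged `truncated`; a gene flush against the boundary
#' yields an empty, truncated promoter.
#'
#' @param gene One-row data.frame (or list) with `gene_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @param genome Named character vector, contig -> uppercase sequence.
#' @param length Window length in bp (default 1000).
#' @return One-row data.frame with columns `gene_id`, `sequence`,
#'   `requested_length`, `actual_length`, `truncated`, `contig`, `span_start`,
#'   `span_end`, `strand`. For an empty window `span_start > span_end` by
#'   convention (zero-width 1-based interval).
#' @export
extract_promoter <- function(gene, genome, length = 1000L) {
  if (!is.numeric(length) || length(length) != 1L || length <= 0) {
    stop("promoter length must be a positive integer", call. = FALSE)
  }
  length <- as.integer(length)
  contig <- as.character(gene$contig)
  if (!contig %in% names(genome)) {
    stop("contig ", contig, " (gene ", gene$gene_id, ") not in genome",
         call. = FALSE)
  }
  clen <- nchar(genome[[contig]])
  if (gene$start < 1L || gene$end > clen || gene$start > gene$end) {
    stop("gene ", gene$gene_id, " coordinates outside contig ", contig,
         call. = FALSE)
  }
  if (gene$strand == "+") {
    lo <- max(1L, gene$start - length)
    hi <- gene$start - 1L
  } else if (gene$strand == "-") {
    lo <- gene$end + 1L
    hi <- min(clen, gene$end + length)
  } else {
    stop("gene ", gene$gene_id, " strand must be + or -", call. = FALSE)
  }
  if (lo > hi) {                      # zero-width upstream window
    seq <- ""
  } else {
    seq <- substr(genome[[contig]], lo, hi)
    if (gene$strand == "-") seq <- revcomp_iupac(seq)
  }
  actual <- nchar(seq)
  data.frame(gene_id = as.character(gene$gene_id), sequence = seq,
             requested_length = length, actual_length = actual,
             truncated = actual < length, contig = contig,
             span_start = lo, span_end = hi,
             strand = as.character(gene$strand),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract promoters for a collection of genes
#'
#' @param genes data.frame of gene models ([read_gene_models()]).
#' @param genome Named character vector, contig -> sequence.
#' @param length Window length in bp (default 1000).
#' @param drop_truncated Drop promoters shorter than `length` instead of
#'   keeping them flagged (default keeps them).
#' @return List with `promoters` (one row per gene, ordered by `gene_id`) and
#'   `report` (counts of truncated and empty promoters).
#' @export
extract_promoters <- function(genes, genome, length = 1000L,
                              drop_truncated = FALSE) {
  if (nrow(genes) == 0L) {
    empty <- extract_promoter(
      list(gene_id = "x", contig = names(genome)[1], start = 1L, end = 1L,
           strand = "+"), genome, length)[0, ]
    return(list(promoters = empty, report = list(n_genes = 0L,
                n_truncated = 0L, n_empty = 0L)))
  }
  # vectorized variant of extract_promoter(), identical arithmetic
  if (!is.numeric(length) || length(length) != 1L || length <= 0) {
    stop("promoter length must be a positive integer", call. = FALSE)
  }
  length <- as.integer(length)
  bad_contig <- !genes$contig %in% names(genome)
  if (any(bad_contig)) {
    stop("contig ", genes$contig[which(bad_contig)[1]], " (gene ",
         genes$gene_id[which(bad_contig)[1]], ") not in genome",
         call. = FALSE)
  }
  clen <- nchar(genome)[genes$contig]
  bad_coord <- genes$start < 1L | genes$end > clen | genes$start > genes$end
  if (any(bad_coord)) {
    stop("gene ", genes$gene_id[which(bad_coord)[1]],
         " coordinates outside contig ",
         genes$contig[which(bad_coord)[1]], call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene ", genes$gene_id[which(!genes$strand %in%
                                        c("+", "-"))[1]],
         " strand must be + or -", call. = FALSE)
  }
  plus <- genes$strand == "+"
  lo <- ifelse(plus, pmax(1L, genes$start - length), genes$end + 1L)
  hi <- ifelse(plus, genes$start - 1L, pmin(clen, genes$end + length))
  seq <- ifelse(lo > hi, "", substr(rep(genome[genes$contig], 1L), lo, hi))
  minus_nonempty <- !plus & nzchar(seq)
  if (any(minus_nonempty)) {
    seq[minus_nonempty] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[minus_nonempty])))
  }
  out <- data.frame(gene_id = genes$gene_id, sequence = seq,
                    requested_length = length, actual_length = nchar(seq),
                    truncated = nchar(seq) < length, contig = genes$contig,
                    span_start = as.integer(lo), span_end = as.integer(hi),
                    strand = genes$strand, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  report <- list(n_genes = nrow(out),
                 n_truncated = sum(out$truncated),
                 n_empty = sum(out$actual_length == 0L))
  if (drop_truncated) out <- out[!out$truncated, , drop = FALSE]
  list(promoters = out, report = report)
}
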