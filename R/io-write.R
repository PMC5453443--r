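# Writers mirroring the readers; round-tripping any parsed collection through
# its writer and reader yields an identical collection.

#' Write a genome as FASTA
#' @param genome Named character vector (contig -> sequence).
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  seqs <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write gene models as GFF3
#' @param genes data.frame as returned by [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "promotif"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a motif library TSV
#' @param motifs data.frame as returned by [read_motif_library()].
#' @param path Output path.
#' @export
write_motif_library <- function(motifs, path) {
  write_tsv(motifs[, c("motif_id", "sequence", "category", "source")], path)
}

#' Write a per-contrast DE table TSV
#' @param de data.frame as returned by [read_de_table()].
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  out <- de[, c("feature_id", "log2fc", "pvalue", "fdr")]
  out$log2fc <- format_pval(out$log2fc)
  out$pvalue <- format_pval(out$pvalue)
  out$fdr <- format_pval(out$fdr)
  write_tsv(out, path)
}

#' Write an orthogroup table in the OrthoFinder dialect
#' @param orthomap Object from [read_orthogroups()].
#' @param path Output path.
#' @export
write_orthogroups <- function(orthomap, path) {
  species <- orthomap$species
  header <- paste(c("Orthogroup", species), collapse = "\t")
  rows <- vapply(names(orthomap$orthogroups), function(og) {
    cells <- vapply(species, function(sp) {
      paste(orthomap$orthogroups[[og]][[sp]], collapse = ", ")
    }, character(1))
    paste(c(og, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write gene-set tables as membership TSV
#' @param sets Named list of sets as returned by [read_gene_sets()].
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    data.frame(set_id = s$set_id, set_label = s$set_label,
               gene_id = s$members, stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}

#' Write promoters as FASTA
#'
#' One record per gene, header `gene_id contig:start-end(strand)
#' truncated=bool`.
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param path Output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  headers <- sprintf("%s %s:%d-%d(%s) truncated=%s",
                     promoters$gene_id, promoters$contig,
                     promoters$span_start, promoters$span_end,
                     promoters$strand, tolower(promoters$truncated))
  seqs <- Biostrings::BStringSet(promoters$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write a motif hit table as long-form TSV
#'
#' Columns: `gene_id`, `motif_id`, `occurrences_sense`,
#' `occurrences_antisense`, `present` — bit-exact integers.
#'
#' @param hits A `motif_hits` object from [scan_promoters()].
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  df <- data.frame(
    gene_id = rep(hits$genes, times = length(hits$motifs)),
    motif_id = rep(hits$motifs, each = length(hits$genes)),
    occurrences_sense = as.vector(hits$sense),
    occurrences_antisense = as.vector(hits$antisense),
    present = as.integer(as.vector(hits$presence)),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write enrichment rows as TSV
#'
#' Rows are already ordered by raw p ascending with ties broken by id;
#' p-values are serialised with 12 significant digits.
#'
#' @param rows data.frame from [motif_enrichment()] or [set_enrichment()].
#' @param path Output path.
#' @export
write_enrichment <- function(rows, path) {
  out <- rows
  out$p_raw <- format_pval(out$p_raw)
  out$p_adj <- format_pval(out$p_adj)
  out$significant <- as.integer(out$significant)
  write_tsv(out, path)
}

#' Write a wide motif-by-contrast significance matrix
#'
#' One row per test id, one 0/1 column per contrast (1 = significant after
#' correction at the stated alpha), mirroring per-condition black/white
#' significance grids.
#'
#' @param rows Combined enrichment rows across contrasts.
#' @param path Output path.
#' @export
write_significance_matrix <- function(rows, path) {
  ids <- sort(unique(rows$test_id))
  contrasts <- unique(rows$contrast)
  mat <- matrix(0L, nrow = length(ids), ncol = length(contrasts),
                dimnames = list(ids, contrasts))
  sig <- rows[rows$significant, , drop = FALSE]
  if (nrow(sig)) mat[cbind(sig$test_id, sig$contrast)] <- 1L
  df <- data.frame(test_id = ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
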