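# IUPAC degenerate motif matching over promoter sets.
#
# Match semantics: every (possibly overlapping) offset is counted; an N in the
# scanned sequence matches no motif letter, including motif letter N, so
# unknown bases never create hits. The C++ kernel in src/scan.cpp implements
# the inner loops; count_occurrences() is the scalar surface over it.

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements all 15 ambiguity codes (R<->Y, K<->M, B<->V, D<->H; S, W and N
#' are self-complementary) and reverses.
#'
#' @param seq IUPAC nucleotide string.
#' @return The reverse complement, uppercase.
#' @export
revcomp_iupac <- function(seq) {
  assert_scalar_string(seq, "sequence")
  seq <- toupper(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- IUPAC_COMPLEMENT[ch]
  if (anyNA(comp)) {
    stop("invalid IUPAC character: ",
         paste(unique(ch[is.na(comp)]), collapse = ", "), call. = FALSE)
  }
  paste(rev(comp), collapse = "")
}

#' Count motif occurrences in one sequence
#'
#' @param sequence Subject sequence over `A,C,G,T,N`.
#' @param motif IUPAC motif string (or a one-row motif record with a
#'   `sequence` field).
#' @param policy `"sense"`, `"antisense"` or `"both"`; `both` sums the sense
#'   count and the count of the motif's reverse complement on the same
#'   sequence.
#' @return Non-negative integer occurrence count.
#' @export
count_occurrences <- function(sequence, motif, policy = c("both", "sense",
                                                          "antisense")) {
  policy <- match.arg(policy)
  if (is.list(motif) || is.data.frame(motif)) motif <- motif$sequence[[1]]
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence must contain only A,C,G,T,N", call. = FALSE)
  }
  motif <- toupper(motif)
  if (!is_iupac(motif)) stop("invalid IUPAC motif: ", motif, call. = FALSE)
  n <- 0L
  if (policy %in% c("sense", "both")) {
    n <- n + .scan_count_cpp(sequence, motif)[1, 1]
  }
  if (policy %in% c("antisense", "both")) {
    n <- n + .scan_count_cpp(sequence, revcomp_iupac(motif))[1, 1]
  }
  n
}

#' Scan a promoter set against a motif library
#'
#' Builds the gene x motif occurrence and presence matrices. Presence is
#' derived as at least one occurrence on the scanned orientation(s); empty
#' promoters contribute all-zero rows.
#'
#' @param promoters data.frame from [extract_promoters()], or any data.frame
#'   with `gene_id` and `sequence` columns.
#' @param motifs Motif library data.frame ([read_motif_library()]).
#' @param policy Orientation policy as in [count_occurrences()]; default
#'   `both` (presence is the union over orientations).
#' @return A `motif_hits` object: list with `genes`, `motifs`, `sense`,
#'   `antisense` (integer matrices gene x motif), `occurrences` (the policy
#'   total), `presence` (logical) and `scan_policy`.
#' @export
scan_promoters <- function(promoters, motifs,
                           policy = c("both", "sense", "antisense")) {
  policy <- match.arg(policy)
  if (nrow(motifs) == 0L) stop("empty motif collection", call. = FALSE)
  if (anyDuplicated(promoters$gene_id)) {
    stop("duplicate gene_id among promoters", call. = FALSE)
  }
  seqs <- toupper(promoters$sequence)
  fwd <- toupper(motifs$sequence)
  if (!all(is_iupac(fwd))) stop("invalid IUPAC motif in library", call. = FALSE)
  rev <- vapply(fwd, revcomp_iupac, character(1), USE.NAMES = FALSE)
  dn <- list(promoters$gene_id, motifs$motif_id)

  sense <- .scan_count_cpp(seqs, fwd)
  antisense <- .scan_count_cpp(seqs, rev)
  dimnames(sense) <- dimnames(antisense) <- dn
  occ <- switch(policy,
                sense = sense,
                antisense = antisense,
                both = sense + antisense)
  structure(list(genes = promoters$gene_id, motifs = motifs$motif_id,
                 sense = sense, antisense = antisense,
                 occurrences = occ, presence = occ >= 1L,
                 scan_policy = policy),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat("motif_hits: ", length(x$genes), " genes x ", length(x$motifs),
      " motifs (policy = ", x$scan_policy, ")\n", sep = "")
  cat("  genes with >=1 hit: ", sum(rowSums(x$presence) > 0), "\n", sep = "")
  invisible(x)
}
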