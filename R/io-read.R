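#' Read a genome FASTA into a named vector of uppercase sequences
#'
#' Sequences are uppercased and any character outside `A,C,G,T,N` is replaced
#' by `N`; the number of replacements is reported via [message()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  x <- toupper(as.character(seqs))
  names(x) <- ids
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", x), function(m) sum(m > 0L),
                      integer(1)))
  if (n_bad > 0L) {
    x <- gsub("[^ACGTN]", "N", x)
    log_note(n_bad, " non-ACGTN character(s) replaced by N in ", path)
  }
  x
}

#' Read gene models from a GFF3 file
#'
#' Only `gene` feature rows are used; each must carry an `ID` attribute.
#' Coordinates are kept 1-based inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, ordered as in the file.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 (", path, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ids <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else
    as.character(gr$ID)
  if (any(is.na(ids) | !nzchar(ids))) {
    stop("gene feature without ID attribute in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (!all(strand %in% c("+", "-"))) {
    stop("gene with strand outside {+,-} in ", path, call. = FALSE)
  }
  data.frame(gene_id = ids,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a motif library TSV
#'
#' Expects columns `motif_id`, `sequence`, `category`, `source`. Sequences are
#' uppercased and validated against the 15-letter IUPAC alphabet.
#'
#' @param path Path to the TSV.
#' @return data.frame with one row per motif.
#' @export
read_motif_library <- function(path) {
  df <- read_tsv_checked(path, c("motif_id", "sequence", "category", "source"),
                         "motif library")
  df$motif_id <- as.character(df$motif_id)
  df$sequence <- toupper(as.character(df$sequence))
  df$category <- as.character(df$category)
  df$source <- as.character(df$source)
  bad <- which(!is_iupac(df$sequence))
  if (length(bad)) {
    stop("invalid IUPAC sequence in motif library row ", bad[1], " (",
         df$motif_id[bad[1]], ": ", df$sequence[bad[1]], ")", call. = FALSE)
  }
  if (anyDuplicated(df$motif_id)) {
    stop("duplicate motif_id: ",
         paste(unique(df$motif_id[duplicated(df$motif_id)]), collapse = ", "),
         call. = FALSE)
  }
  df[, c("motif_id", "sequence", "category", "source")]
}

#' Read a per-contrast differential-expression table
#'
#' Expects columns `feature_id`, `log2fc`, `pvalue`, `fdr` (extra columns are
#' ignored). Rows with missing `log2fc` or `fdr` are dropped with a reported
#' count.
#'
#' @param path Path to the TSV.
#' @param contrast Contrast label attached to every record.
#' @return data.frame with columns `feature_id`, `contrast`, `log2fc`,
#'   `pvalue`, `fdr`.
#' @export
read_de_table <- function(path, contrast) {
  assert_scalar_string(contrast, "contrast")
  df <- read_tsv_checked(path, c("feature_id", "log2fc", "pvalue", "fdr"),
                         "DE table")
  df$feature_id <- as.character(df$feature_id)
  df$log2fc <- as.numeric(df$log2fc)
  df$pvalue <- as.numeric(df$pvalue)
  df$fdr <- as.numeric(df$fdr)
  drop <- is.na(df$log2fc) | is.na(df$fdr)
  if (any(drop)) {
    log_note(sum(drop), " row(s) with missing log2fc/fdr dropped from ", path)
    df <- df[!drop, , drop = FALSE]
  }
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature_id in DE table ", path, ": ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]),
               collapse = ", "), call. = FALSE)
  }
  data.frame(feature_id = df$feature_id, contrast = contrast,
             log2fc = df$log2fc, pvalue = df$pvalue, fdr = df$fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an orthogroup table (OrthoFinder `Orthogroups.tsv` dialect)
#'
#' Header row is `Orthogroup` followed by one column per species; cells hold
#' comma+space separated gene lists, possibly empty. A gene repeated across
#' orthogroups within one species is kept in both, with a warning.
#'
#' @param path Path to the TSV.
#' @return A list with elements `species` (character vector of labels) and
#'   `orthogroups`: a named list, one entry per orthogroup, each a named list
#'   species -> character vector of gene ids.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty orthogroup table: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "Orthogroup" || length(header) < 2L) {
    stop("orthogroup table must start with 'Orthogroup' + species columns",
         call. = FALSE)
  }
  species <- header[-1]
  ncol_expect <- length(header)
  rows <- lapply(lines[-1], function(l) {
    # keep trailing empty cells
    cells <- strsplit(paste0(l, "\t\x01"), "\t", fixed = TRUE)[[1]]
    cells <- cells[-length(cells)]
    if (length(cells) != ncol_expect) {
      stop("orthogroup row with ", length(cells), " column(s), expected ",
           ncol_expect, ": ", substr(l, 1, 50), call. = FALSE)
    }
    cells
  })
  ogs <- lapply(rows, function(cells) {
    members <- lapply(cells[-1], function(cell) {
      genes <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
      genes[nzchar(genes)]
    })
    names(members) <- species
    members
  })
  names(ogs) <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(names(ogs))) {
    stop("duplicate orthogroup id in ", path, call. = FALSE)
  }
  for (sp in species) {
    all_genes <- unlist(lapply(ogs, `[[`, sp), use.names = FALSE)
    dup <- unique(all_genes[duplicated(all_genes)])
    if (length(dup)) {
      warning("species ", sp, ": ", length(dup),
              " gene id(s) appear in more than one orthogroup (kept in all)",
              call. = FALSE)
    }
  }
  structure(list(species = species, orthogroups = ogs),
            class = "orthomap")
}

#' Read gene-set membership tables (GO annotations, signature sets)
#'
#' Expects columns `set_id`, `set_label`, `gene_id`, one membership per row;
#' duplicate memberships within a set are deduplicated.
#'
#' @param path Path to the TSV.
#' @return A named list of sets; each element carries `set_id`, `set_label`
#'   and `members` (character vector).
#' @export
read_gene_sets <- function(path) {
  df <- read_tsv_checked(path, c("set_id", "set_label", "gene_id"),
                         "gene-set table")
  if (nrow(df) == 0L) stop("empty gene-set table: ", path, call. = FALSE)
  df$set_id <- as.character(df$set_id)
  df$set_label <- as.character(df$set_label)
  df$gene_id <- as.character(df$gene_id)
  gene_sets(df$set_id, df$set_label, df$gene_id)
}

#' Build a gene-set collection from parallel vectors
#'
#' @param set_id,set_label,gene_id Parallel character vectors (one membership
#'   per element); `set_label` must be constant within a `set_id`.
#' @return Named list of sets as in [read_gene_sets()].
#' @export
gene_sets <- function(set_id, set_label, gene_id) {
  split_idx <- split(seq_along(set_id), set_id)
  out <- lapply(split_idx, function(i) {
    list(set_id = set_id[i[1]],
         set_label = set_label[i[1]],
         members = unique(gene_id[i]))
  })
  # preserve first-appearance order
  out[unique(set_id)]
}

#' Read a wide supplementary-style DE table into long per-contrast records
#'
#' Convenience reader for supplementary tables laid out one row per feature
#' with per-contrast `log2fc`/`fdr` (and optionally `pvalue`) column pairs
#' named `<contrast>_log2fc`, `<contrast>_fdr`, `<contrast>_pvalue`.
#' Accepts TSV always and xlsx when the readxl package is installed.
#'
#' @param path Path to a TSV or xlsx file.
#' @param contrasts Character vector of contrast prefixes to extract.
#' @param id_col Name of the feature-id column (default `feature_id`).
#' @return Named list of per-contrast data.frames in [read_de_table()] layout.
#' @export
read_supplementary_de <- function(path, contrasts, id_col = "feature_id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!id_col %in% names(df)) {
    stop("id column '", id_col, "' not found in ", path, call. = FALSE)
  }
  out <- lapply(contrasts, function(ct) {
    lfc_col <- paste0(ct, "_log2fc")
    fdr_col <- paste0(ct, "_fdr")
    p_col <- paste0(ct, "_pvalue")
    for (cl in c(lfc_col, fdr_col)) {
      if (!cl %in% names(df)) {
        stop("column '", cl, "' not found in ", path, call. = FALSE)
      }
    }
    rec <- data.frame(
      feature_id = as.character(df[[id_col]]),
      contrast = ct,
      log2fc = as.numeric(df[[lfc_col]]),
      pvalue = if (p_col %in% names(df)) as.numeric(df[[p_col]]) else NA_real_,
      fdr = as.numeric(df[[fdr_col]]),
      stringsAsFactors = FALSE)
    drop <- is.na(rec$log2fc) | is.na(rec$fdr)
    if (any(drop)) {
      log_note(sum(drop), " row(s) with missing log2fc/fdr dropped for ", ct)
      rec <- rec[!drop, , drop = FALSE]
    }
    rec
  })
  names(out) <- contrasts
  out
}
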