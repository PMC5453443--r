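# IUPAC nucleotide ambiguity alphabet and shared validators.

#' The 15 IUPAC nucleotide codes and the bases each stands for
#' @keywords internal
#' @noRd
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

is_iupac <- function(x) {
  !is.na(x) & nzchar(x) &
    vapply(strsplit(toupper(x), "", fixed = TRUE),
           function(ch) all(ch %in% names(IUPAC_CODES)), logical(1))
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  invisible(x)
}

assert_probability <- function(p, what = "p-values") {
  if (length(p) && (any(is.na(p)) || any(p < 0) || any(p > 1))) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

# Counted-event logging: all parsers funnel soft events (sanitised characters,
# dropped rows) through here so callers can silence or capture them.
log_note <- function(...) {
  message("promotif: ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

iupac_masks <- function(x) {
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
           W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L,
           N = 15L)
  unname(bit[strsplit(toupper(x), "", fixed = TRUE)[[1]]])
}

# TRUE if some word matches both IUPAC patterns at an alignment where they
# overlap by >= min_overlap positions (either orientation of b): such a pair
# can share matches and is not statistically independent
iupac_cross_reactive <- function(a, b, min_overlap = 4L) {
  ma <- iupac_masks(a)
  for (bb in c(b, revcomp_iupac(b))) {
    mb <- iupac_masks(bb)
    for (s in seq(-(length(mb) - min_overlap),
                  length(ma) - min_overlap)) {
      ia <- seq(max(1L, 1L + s), min(length(ma), length(mb) + s))
      ib <- ia - s
      if (all(bitwAnd(ma[ia], mb[ib]) > 0L)) return(TRUE)
    }
  }
  FALSE
}

# p-values serialised with 12 significant digits for stable TSV round-trips
format_pval <- function(p) formatC(p, digits = 12, format = "g")

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
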