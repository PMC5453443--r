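# DE-list construction, orthogroup projection, set over-representation and
# motif co-occurrence.

#' Threshold a DE table into a gene list
#'
#' Membership uses the inclusive conventions |log2FC| >= cutoff and
#' FDR <= cutoff; `direction` restricts to up- or down-regulated genes.
#'
#' @param records DE records for a single contrast ([read_de_table()]).
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 1; a stricter
#'   list uses 4).
#' @param fdr_cutoff FDR cutoff (default 0.05).
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @return List with `contrast`, `direction`, `lfc_cutoff`, `fdr_cutoff` and
#'   `members` (character vector of gene ids).
#' @export
filter_de <- function(records, lfc_cutoff = 1, fdr_cutoff = 0.05,
                      direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (lfc_cutoff < 0) stop("lfc_cutoff must be >= 0", call. = FALSE)
  if (length(unique(records$contrast)) > 1L) {
    stop("filter_de expects records from a single contrast", call. = FALSE)
  }
  pass_fc <- switch(direction,
                    both = abs(records$log2fc) >= lfc_cutoff,
                    up = records$log2fc >= lfc_cutoff,
                    down = records$log2fc <= -lfc_cutoff)
  members <- records$feature_id[pass_fc & records$fdr <= fdr_cutoff]
  structure(list(contrast = records$contrast[1] %||% NA_character_,
                 direction = direction, lfc_cutoff = lfc_cutoff,
                 fdr_cutoff = fdr_cutoff, members = members),
            class = "de_gene_list")
}

#' Intersect DE gene lists across contrasts
#'
#' @param lists List of two or more [filter_de()] results (or plain character
#'   vectors).
#' @return Character vector of gene ids differentially expressed in all.
#' @export
intersect_de <- function(lists) {
  if (length(lists) < 2L) stop("need at least two DE lists", call. = FALSE)
  sets <- lapply(lists, function(l) if (is.character(l)) l else l$members)
  Reduce(intersect, sets)
}

#' Map genes to their putative orthologs through orthogroups
#'
#' One-to-many and many-to-many relations are kept: each source gene maps to
#' the union of target-species members of every orthogroup containing it.
#'
#' @param source_genes Character vector of source-species gene ids.
#' @param orthomap Object from [read_orthogroups()].
#' @param source_species,target_species Species labels from the table header.
#' @return Named list, source gene -> character vector of target gene ids
#'   (empty for genes in no orthogroup; their count is reported).
#' @export
map_orthologs <- function(source_genes, orthomap, source_species,
                          target_species) {
  for (sp in c(source_species, target_species)) {
    if (!sp %in% orthomap$species) {
      stop("unknown species label: ", sp, call. = FALSE)
    }
  }
  # invert: source gene -> orthogroup ids
  src_members <- lapply(orthomap$orthogroups, `[[`, source_species)
  gene2og <- split(rep(names(src_members), lengths(src_members)),
                   unlist(src_members, use.names = FALSE))
  out <- lapply(source_genes, function(g) {
    ogs <- gene2og[[g]]
    if (is.null(ogs)) return(character(0))
    sort(unique(unlist(lapply(orthomap$orthogroups[ogs], `[[`,
                              target_species), use.names = FALSE)))
  })
  names(out) <- source_genes
  n_unmapped <- sum(lengths(out) == 0L)
  if (n_unmapped > 0L) {
    log_note(n_unmapped, " of ", length(source_genes),
             " source gene(s) map to no ", target_species, " ortholog")
  }
  out
}

#' Project signature gene sets across species via orthogroups
#'
#' Each set's members are replaced by the union of their ortholog images in
#' the target species; labels (gene family, subcellular compartment) carry
#' through. Sets whose image is empty are dropped with a warning.
#'
#' @param sets Gene-set collection over source-species ids
#'   ([read_gene_sets()]).
#' @param orthomap Object from [read_orthogroups()].
#' @param source_species,target_species Species labels.
#' @return Projected gene-set collection over target-species ids.
#' @export
project_signature_sets <- function(sets, orthomap, source_species,
                                   target_species) {
  all_src <- unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE))
  images <- map_orthologs(all_src, orthomap, source_species, target_species)
  out <- lapply(sets, function(s) {
    proj <- sort(unique(unlist(images[s$members], use.names = FALSE)))
    list(set_id = s$set_id, set_label = s$set_label, members = proj)
  })
  empty <- vapply(out, function(s) length(s$members) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " set(s) dropped: no members map to ",
            target_species, " (", paste(names(out)[empty], collapse = ", "),
            ")", call. = FALSE)
  }
  out[!empty]
}

#' Gene-set over-representation among DE genes
#'
#' For each set, a one-sided Fisher exact test on the 2x2 table of set
#' membership (intersected with the background) versus DE status, corrected
#' across the set family (Benjamini-Hochberg by default, as used for GO and
#' signature-set testing).
#'
#' @param sets Gene-set collection ([read_gene_sets()] or
#'   [project_signature_sets()]).
#' @param de_genes Character vector of DE gene ids (subset of `background`).
#' @param background Character vector: the gene universe.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @param correction `"bh"` (default) or `"bonferroni"`.
#' @param contrast Label attached to the rows.
#' @return data.frame of enrichment rows as in [motif_enrichment()].
#' @export
set_enrichment <- function(sets, de_genes, background, alpha = 0.05,
                           correction = c("bh", "bonferroni"),
                           contrast = "contrast") {
  correction <- match.arg(correction)
  background <- unique(background)
  if (!length(background)) stop("empty background universe", call. = FALSE)
  presence <- vapply(sets, function(s) background %in% s$members,
                     logical(length(background)))
  presence <- matrix(presence, nrow = length(background),
                     dimnames = list(background,
                                     vapply(sets, `[[`, character(1),
                                            "set_id")))
  enrichment_rows(presence, de_genes, background, contrast, alpha,
                  correction)
}

#' Tabulate motif co-occurrence over a gene universe
#'
#' Reports, for each queried motif, how many universe genes carry it; for
#' each motif pair, how many carry both; and the full presence-pattern
#' breakdown (counts over all 2^q presence/absence patterns, which sum to the
#' universe size).
#'
#' @param hits `motif_hits` object from [scan_promoters()].
#' @param gene_universe Character vector, subset of the scanned genes (e.g.
#'   the HSP genes when counting circadian elements among them).
#' @param query_motifs Character vector of motif ids in the hit table.
#' @return List with `universe_size`, `single` (named counts per motif),
#'   `pairs` (data.frame motif_a, motif_b, both) and `patterns` (data.frame
#'   with one 0/1 column per motif plus `count`).
#' @export
cooccurrence <- function(hits, gene_universe, query_motifs) {
  missing_m <- setdiff(query_motifs, hits$motifs)
  if (length(missing_m)) {
    stop("unknown motif_id: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  missing_g <- setdiff(gene_universe, hits$genes)
  if (length(missing_g)) {
    stop("gene universe outside hit table: ",
         paste(utils::head(missing_g, 5), collapse = ", "), call. = FALSE)
  }
  pres <- hits$presence[gene_universe, query_motifs, drop = FALSE]
  single <- colSums(pres)
  pairs <- if (length(query_motifs) >= 2L) {
    combos <- utils::combn(query_motifs, 2L)
    data.frame(motif_a = combos[1, ], motif_b = combos[2, ],
               both = apply(combos, 2L, function(pr) {
                 sum(pres[, pr[1]] & pres[, pr[2]])
               }),
               stringsAsFactors = FALSE)
  } else {
    data.frame(motif_a = character(), motif_b = character(),
               both = integer(), stringsAsFactors = FALSE)
  }
  grid <- expand.grid(rep(list(c(0L, 1L)), length(query_motifs)))
  names(grid) <- query_motifs
  pattern_key <- function(m) apply(m, 1L, paste, collapse = "")
  obs <- if (nrow(pres)) pattern_key(pres * 1L) else character(0)
  grid$count <- as.integer(table(factor(obs, levels = pattern_key(grid))))
  structure(list(universe_size = length(gene_universe),
                 single = single, pairs = pairs, patterns = grid),
            class = "cooccurrence_table")
}

#' Signed threshold matrix of log2 fold changes across contrasts
#'
#' Heatmap-facing encoding: +1 where log2FC >= `lfc_cutoff` and FDR passes,
#' -1 where log2FC <= -`lfc_cutoff` and FDR passes, 0 otherwise.
#'
#' @param de_tables Named list of per-contrast DE records.
#' @param genes Gene ids for the rows.
#' @param lfc_cutoff,fdr_cutoff Thresholds (defaults 1 and 0.05).
#' @return Integer matrix gene x contrast with values in `{-1, 0, 1}`.
#' @export
signed_lfc_matrix <- function(de_tables, genes, lfc_cutoff = 1,
                              fdr_cutoff = 0.05) {
  out <- matrix(0L, nrow = length(genes), ncol = length(de_tables),
                dimnames = list(genes, names(de_tables)))
  for (ct in names(de_tables)) {
    tab <- de_tables[[ct]]
    idx <- match(genes, tab$feature_id)
    hit <- !is.na(idx)
    lfc <- tab$log2fc[idx[hit]]
    fdr <- tab$fdr[idx[hit]]
    val <- ifelse(fdr <= fdr_cutoff & lfc >= lfc_cutoff, 1L,
                  ifelse(fdr <= fdr_cutoff & lfc <= -lfc_cutoff, -1L, 0L))
    out[which(hit), ct] <- val
  }
  out
}
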