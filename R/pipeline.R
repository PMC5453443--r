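# End-to-end orchestration with a stable output layout.

#' Build a pipeline run configuration
#'
#' @param genome,gff3,motifs Paths to the genome FASTA, GFF3 gene models and
#'   motif-library TSV.
#' @param de_tables Named character vector/list of per-contrast DE TSV paths
#'   (names are the contrast labels).
#' @param orthogroups,signature_sets,go_sets Optional paths for the
#'   ortholog-projection and set-enrichment stages (all three required to run
#'   those stages).
#' @param out_dir Output directory.
#' @param promoter_length Upstream window (default 1000 bp).
#' @param lfc_cutoff,fdr_cutoff DE thresholds (defaults 1 and 0.05; a
#'   stricter list uses `lfc_cutoff = 4`).
#' @param scan_policy Orientation policy for the scanner (default `both`).
#' @param motif_correction,set_correction Multiple-testing methods (defaults
#'   Bonferroni for motifs, BH for sets).
#' @param alpha Significance threshold (default 0.05).
#' @param source_species,target_species Orthogroup species labels for
#'   signature projection.
#' @param drop_truncated Drop truncated promoters before scanning (default
#'   keep).
#' @return A `run_config` list.
#' @export
run_config <- function(genome, gff3, motifs, de_tables, out_dir,
                       orthogroups = NULL, signature_sets = NULL,
                       go_sets = NULL,
                       promoter_length = 1000L, lfc_cutoff = 1,
                       fdr_cutoff = 0.05,
                       scan_policy = c("both", "sense", "antisense"),
                       motif_correction = c("bonferroni", "bh"),
                       set_correction = c("bh", "bonferroni"),
                       alpha = 0.05, source_species = "Ath",
                       target_species = "Pda", drop_truncated = FALSE) {
  scan_policy <- match.arg(scan_policy)
  motif_correction <- match.arg(motif_correction)
  set_correction <- match.arg(set_correction)
  if (is.null(names(de_tables)) || any(!nzchar(names(de_tables)))) {
    stop("de_tables must be a named vector (names = contrast labels)",
         call. = FALSE)
  }
  for (p in c(genome, gff3, motifs, unlist(de_tables), orthogroups,
              signature_sets, go_sets)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (lfc_cutoff < 0 || fdr_cutoff <= 0 || fdr_cutoff > 1) {
    stop("invalid cutoffs", call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: promoter extraction, motif scan, per-contrast DE filtering,
#' per-contrast motif enrichment (corrected within the motif family of the
#' contrast), optional signature projection + set enrichment + GO
#' enrichment, and a run manifest. All outputs are plain TSV/FASTA with
#' documented ordering (p ascending, ties by id) so reruns on identical
#' inputs are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory stage results and output
#'   paths.
#' @export
run_all <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  genome <- stage("read_genome", read_genome(config$genome))
  genes <- stage("read_gene_models", read_gene_models(config$gff3))
  motifs <- stage("read_motif_library", read_motif_library(config$motifs))

  prom <- stage("extract_promoters",
                extract_promoters(genes, genome, config$promoter_length,
                                  drop_truncated = config$drop_truncated))
  write_promoter_fasta(prom$promoters, out("promoters.fasta"))

  hits <- stage("scan_promoters",
                scan_promoters(prom$promoters, motifs, config$scan_policy))
  write_hit_table(hits, out("motif_hits.tsv"))

  de_lists <- list()
  enrich_all <- list()
  for (ct in names(config$de_tables)) {
    de <- stage(paste0("read_de_table[", ct, "]"),
                read_de_table(config$de_tables[[ct]], ct))
    universe <- intersect(de$feature_id, hits$genes)
    dl <- stage(paste0("filter_de[", ct, "]"),
                filter_de(de, config$lfc_cutoff, config$fdr_cutoff))
    de_lists[[ct]] <- dl
    write_tsv(data.frame(contrast = rep(ct, length(dl$members)),
                         gene_id = sort(dl$members),
                         stringsAsFactors = FALSE),
              out(paste0("de_list_", ct, ".tsv")))
    de_in_universe <- intersect(dl$members, universe)
    rows <- if (length(de_in_universe)) {
      stage(paste0("motif_enrichment[", ct, "]"),
            motif_enrichment(hits, de_in_universe, universe,
                             alpha = config$alpha,
                             correction = config$motif_correction,
                             contrast = ct))
    } else {
      motif_enrichment(hits, character(0), universe, contrast = ct)
    }
    enrich_all[[ct]] <- rows
    write_enrichment(rows, out(paste0("motif_enrichment_", ct, ".tsv")))
  }
  combined <- do.call(rbind, enrich_all)
  rownames(combined) <- NULL
  write_significance_matrix(combined, out("motif_significance_matrix.tsv"))

  set_results <- NULL
  if (!is.null(config$orthogroups) && !is.null(config$signature_sets)) {
    orthomap <- stage("read_orthogroups",
                      read_orthogroups(config$orthogroups))
    sig <- stage("read_gene_sets", read_gene_sets(config$signature_sets))
    projected <- stage("project_signature_sets",
                       project_signature_sets(sig, orthomap,
                                              config$source_species,
                                              config$target_species))
    proj_report <- do.call(rbind, lapply(projected, function(s) {
      data.frame(set_id = s$set_id, set_label = s$set_label,
                 n_members = length(s$members),
                 members = paste(s$members, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(proj_report, out("signature_projection.tsv"))
    set_results <- list(projected = projected)
    for (ct in names(de_lists)) {
      de <- read_de_table(config$de_tables[[ct]], ct)
      universe <- de$feature_id
      rows <- stage(paste0("set_enrichment[", ct, "]"),
                    set_enrichment(projected,
                                   intersect(de_lists[[ct]]$members,
                                             universe),
                                   universe, alpha = config$alpha,
                                   correction = config$set_correction,
                                   contrast = ct))
      write_enrichment(rows, out(paste0("signature_enrichment_", ct,
                                        ".tsv")))
      set_results[[paste0("signature_", ct)]] <- rows
      if (!is.null(config$go_sets)) {
        go <- read_gene_sets(config$go_sets)
        go_rows <- set_enrichment(go,
                                  intersect(de_lists[[ct]]$members,
                                            universe),
                                  universe, alpha = config$alpha,
                                  correction = config$set_correction,
                                  contrast = ct)
        write_enrichment(go_rows, out(paste0("go_enrichment_", ct, ".tsv")))
        set_results[[paste0("go_", ct)]] <- go_rows
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("promotif")),
    config = lapply(unclass(config), function(x)
      if (is.character(x) || is.numeric(x) || is.logical(x)) x else
        unlist(x)),
    counts = list(
      n_contigs = length(genome),
      n_genes = nrow(genes),
      n_motifs = nrow(motifs),
      n_promoters = nrow(prom$promoters),
      n_truncated_promoters = prom$report$n_truncated,
      de_list_sizes = vapply(de_lists, function(d) length(d$members),
                             integer(1)),
      n_significant_motifs = vapply(enrich_all, function(r)
        sum(r$significant), integer(1))))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(genome = genome, genes = genes, motifs = motifs,
                 promoters = prom, hits = hits, de_lists = de_lists,
                 motif_enrichment = enrich_all, sets = set_results,
                 manifest = manifest, out_dir = config$out_dir))
}
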