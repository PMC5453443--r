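#!/usr/bin/env Rscript

# Stage 4: orthogroup-mediated signature projection and set enrichment.
#
# Projects the model-species ROS signature sets onto the target species
# through the fixture orthogroups (keeping one-to-many relations), then
# tests each projected set and each GO-style set for over-representation
# among the DE genes of every contrast (one-sided Fisher, BH across the
# set family). Writes per-contrast tables under results/sets/.

suppressMessages(library(promotif))

orthomap <- read_orthogroups("results/fixtures/orthogroups.tsv")
sig_sets <- read_gene_sets("results/fixtures/signature_sets.tsv")
go_sets <- read_gene_sets("results/fixtures/go_sets.tsv")

projected <- project_signature_sets(sig_sets, orthomap, "Ath", "Pda")
cat("signature sets projected:", length(projected), "of",
    length(sig_sets), "\n")

dir.create("results/sets", showWarnings = FALSE, recursive = TRUE)
for (ct in c("D", "H", "HD")) {
  de_tab <- read_de_table(sprintf("results/fixtures/de_%s.tsv", ct), ct)
  de <- filter_de(de_tab, 1, 0.05)$members
  universe <- de_tab$feature_id

  rows <- set_enrichment(projected, de, universe, correction = "bh",
                         contrast = ct)
  write_enrichment(rows, sprintf("results/sets/signature_%s.tsv", ct))
  go_rows <- set_enrichment(go_sets, de, universe, correction = "bh",
                            contrast = ct)
  write_enrichment(go_rows, sprintf("results/sets/go_%s.tsv", ct))
  cat(ct, ": ", sum(rows$significant), " signature set(s), ",
      sum(go_rows$significant), " GO set(s) enriched\n", sep = "")
}

# signed log2FC matrix of the three-way-intersection genes (heatmap input)
tabs <- lapply(setNames(c("D", "H", "HD"), c("D", "H", "HD")),
               function(ct) read_de_table(
                 sprintf("results/fixtures/de_%s.tsv", ct), ct))
common <- intersect_de(lapply(tabs, filter_de))
cat("genes DE in all three contrasts:", length(common), "\n")
if (length(common)) {
  m <- signed_lfc_matrix(tabs, sort(common))
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              "results/sets/common_de_signed_lfc.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
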