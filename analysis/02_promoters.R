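#!/usr/bin/env Rscript

# Stage 2: strand-aware promoter extraction.
#
# Reads the fixture genome and gene models and extracts the 1-kbp upstream
# window of every gene, reverse-complemented for minus-strand genes so all
# promoters read 5'->3' toward the gene. Truncated windows (contig edge)
# are kept and flagged. Writes results/promoters.fasta.

suppressMessages(library(promotif))

genome <- read_genome("results/fixtures/genome.fasta")
genes <- read_gene_models("results/fixtures/genes.gff3")
res <- extract_promoters(genes, genome, length = 1000L)
write_promoter_fasta(res$promoters, "results/promoters.fasta")

cat("promoters extracted:", res$report$n_genes, "\n")
cat("  truncated:", res$report$n_truncated,
    " empty:", res$report$n_empty, "\n")
cat("  written to results/promoters.fasta\n")
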