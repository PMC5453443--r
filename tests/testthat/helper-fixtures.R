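# Small in-code fixtures shared by the unit tests.

write_fasta_lines <- function(lines, dir = withr::local_tempdir(.local_envir =
                                                                  parent.frame())) {
  path <- file.path(dir, "fixture.fasta")
  writeLines(lines, path)
  path
}

write_tsv_lines <- function(lines, name = "fixture.tsv",
                            dir = withr::local_tempdir(.local_envir =
                                                         parent.frame())) {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

tiny_gff3 <- function(rows, dir = withr::local_tempdir(.local_envir =
                                                         parent.frame())) {
  path <- file.path(dir, "fixture.gff3")
  writeLines(c("##gff-version 3", rows), path)
  path
}

tiny_motif_lib <- function(ids, seqs,
                           category = rep("test", length(ids)),
                           source = rep("unit", length(ids))) {
  data.frame(motif_id = ids, sequence = seqs, category = category,
             source = source, stringsAsFactors = FALSE)
}

promoter_frame <- function(gene_ids, seqs) {
  data.frame(gene_id = gene_ids, sequence = seqs, stringsAsFactors = FALSE)
}
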