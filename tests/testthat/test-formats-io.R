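test_that("read_genome uppercases, sanitises and rejects bad FASTA", {
  p <- write_fasta_lines(c(">c1", "acgt"))
  expect_identical(read_genome(p), c(c1 = "ACGT"))

  p2 <- write_fasta_lines(c(">c1 description text", "ACXT"))
  expect_message(g <- read_genome(p2), "1 non-ACGTN")
  expect_identical(g, c(c1 = "ACNT"))

  p3 <- write_fasta_lines(c(">c1", "ACGT", ">c1", "AAAA"))
  expect_error(read_genome(p3), "duplicate contig")
  expect_error(read_genome(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("read_gene_models keeps gene rows, 1-based coordinates, hard errors", {
  p <- tiny_gff3(c("c1\t.\tgene\t11\t40\t.\t+\t.\tID=g1",
                   "c1\t.\tmRNA\t11\t40\t.\t+\t.\tID=t1;Parent=g1",
                   "c2\t.\tgene\t5\t9\t.\t-\t.\tID=g2"))
  gm <- read_gene_models(p)
  expect_identical(gm$gene_id, c("g1", "g2"))
  expect_identical(gm$start, c(11L, 5L))
  expect_identical(gm$end, c(40L, 9L))
  expect_identical(gm$strand, c("+", "-"))

  only_mrna <- tiny_gff3("c1\t.\tmRNA\t1\t10\t.\t+\t.\tID=t1")
  expect_identical(nrow(read_gene_models(only_mrna)), 0L)

  expect_error(read_gene_models(
    tiny_gff3("c1\t.\tgene\t40\t11\t.\t+\t.\tID=g1")), "malformed|outside")
  expect_error(read_gene_models(
    tiny_gff3("c1\t.\tgene\t1\t10\t.\t+\t.\tName=g1")), "without ID")
  expect_error(read_gene_models(
    tiny_gff3("c1\t.\tgene\t1\t10\t.\t.\t.\tID=g1")), "strand")
})

test_that("read_motif_library validates the IUPAC alphabet", {
  p <- write_tsv_lines(c("motif_id\tsequence\tcategory\tsource",
                         "CCA1\taaaaatct\tcircadian\tpublication",
                         "PRE\tACTCAT\tproline\tpublication"))
  lib <- read_motif_library(p)
  expect_identical(lib$sequence, c("AAAAATCT", "ACTCAT"))
  expect_identical(nchar(lib$sequence[1]), 8L)

  bad <- write_tsv_lines(c("motif_id\tsequence\tcategory\tsource",
                           "M1\tACZ\tx\ty"), name = "bad.tsv")
  expect_error(read_motif_library(bad), "row 1")
  dup <- write_tsv_lines(c("motif_id\tsequence\tcategory\tsource",
                           "M1\tACGT\tx\ty", "M1\tACGG\tx\ty"),
                         name = "dup.tsv")
  expect_error(read_motif_library(dup), "duplicate motif_id")
})

test_that("read_de_table parses, drops NA rows with a note, rejects duplicates", {
  p <- write_tsv_lines(c("feature_id\tlog2fc\tpvalue\tfdr\textra",
                         "g1\t2.0\t0.001\t0.01\tfoo",
                         "g2\tNA\t0.5\t0.9\tbar"))
  expect_message(de <- read_de_table(p, "D"), "1 row")
  expect_identical(de$feature_id, "g1")
  expect_identical(de$contrast, "D")
  expect_equal(de$log2fc, 2.0)

  dup <- write_tsv_lines(c("feature_id\tlog2fc\tpvalue\tfdr",
                           "g1\t1\t0.1\t0.2", "g1\t2\t0.1\t0.2"),
                         name = "dup.tsv")
  expect_error(read_de_table(dup, "D"), "duplicate feature_id")
})

test_that("read_orthogroups parses the OrthoFinder dialect", {
  p <- write_tsv_lines(c("Orthogroup\tAth\tPda",
                         "OG1\tAT1G01060\tPD_1, PD_2",
                         "OG2\tAT2G00001\t"))
  om <- read_orthogroups(p)
  expect_identical(om$species, c("Ath", "Pda"))
  expect_identical(om$orthogroups$OG1$Pda, c("PD_1", "PD_2"))
  expect_identical(om$orthogroups$OG2$Pda, character(0))

  repeated <- write_tsv_lines(c("Orthogroup\tAth\tPda",
                                "OG1\tAT1\tPD_1",
                                "OG2\tAT1\tPD_2"), name = "rep.tsv")
  expect_warning(om2 <- read_orthogroups(repeated), "more than one")
  expect_identical(om2$orthogroups$OG1$Ath, "AT1")
  expect_identical(om2$orthogroups$OG2$Ath, "AT1")

  short <- write_tsv_lines(c("Orthogroup\tAth\tPda", "OG1\tAT1"),
                           name = "short.tsv")
  expect_error(read_orthogroups(short), "column")
})

test_that("read_gene_sets groups and deduplicates memberships", {
  p <- write_tsv_lines(c("set_id\tset_label\tgene_id",
                         "S1\tAPX\tAT1", "S1\tAPX\tAT2", "S1\tAPX\tAT1",
                         "S2\tCAT\tAT3"))
  sets <- read_gene_sets(p)
  expect_length(sets, 2L)
  expect_setequal(sets$S1$members, c("AT1", "AT2"))
  expect_identical(sets$S2$set_label, "CAT")

  empty <- write_tsv_lines("set_id\tset_label\tgene_id", name = "e.tsv")
  expect_error(read_gene_sets(empty), "empty")
})

test_that("collections round-trip through their writers and readers", {
  dir <- withr::local_tempdir()
  genome <- c(c1 = "ACGTACGTNN", c2 = "TTTTGGGG")
  write_genome(genome, file.path(dir, "g.fa"))
  expect_identical(read_genome(file.path(dir, "g.fa")), genome)

  genes <- data.frame(gene_id = c("g1", "g2"), contig = c("c1", "c2"),
                      start = c(2L, 1L), end = c(5L, 8L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  write_gene_models(genes, file.path(dir, "g.gff3"))
  expect_identical(read_gene_models(file.path(dir, "g.gff3")), genes)

  lib <- tiny_motif_lib(c("M1", "M2"), c("ACGT", "RYSW"))
  write_motif_library(lib, file.path(dir, "m.tsv"))
  expect_identical(read_motif_library(file.path(dir, "m.tsv")), lib)

  de <- data.frame(feature_id = c("g1", "g2"), contrast = "D",
                   log2fc = c(1.25, -0.5), pvalue = c(0.001, 0.5),
                   fdr = c(0.01, 0.7), stringsAsFactors = FALSE)
  write_de_table(de, file.path(dir, "de.tsv"))
  expect_equal(read_de_table(file.path(dir, "de.tsv"), "D"), de)

  om <- read_orthogroups(write_tsv_lines(
    c("Orthogroup\tAth\tPda", "OG1\tAT1\tPD_1, PD_2", "OG2\t\tPD_3"),
    dir = dir))
  write_orthogroups(om, file.path(dir, "og.tsv"))
  expect_identical(read_orthogroups(file.path(dir, "og.tsv")), om)

  sets <- gene_sets(c("S1", "S1", "S2"), c("APX", "APX", "CAT"),
                    c("AT1", "AT2", "AT3"))
  write_gene_sets(sets, file.path(dir, "sets.tsv"))
  expect_identical(read_gene_sets(file.path(dir, "sets.tsv")), sets)
})

test_that("wide supplementary DE tables unpack into per-contrast records", {
  p <- write_tsv_lines(c(
    "feature_id\tD_log2fc\tD_fdr\tH_log2fc\tH_fdr",
    "g1\t2.5\t0.01\t0.2\t0.8",
    "g2\t-1.1\t0.04\t4.2\t0.001"))
  tabs <- read_supplementary_de(p, c("D", "H"))
  expect_named(tabs, c("D", "H"))
  expect_equal(tabs$D$log2fc, c(2.5, -1.1))
  expect_equal(tabs$H$fdr, c(0.8, 0.001))
  expect_error(read_supplementary_de(p, "HD"), "HD_log2fc")
})
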