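de_records <- function(ids, lfc, fdr, contrast = "D") {
  data.frame(feature_id = ids, contrast = contrast, log2fc = lfc,
             pvalue = fdr / 2, fdr = fdr, stringsAsFactors = FALSE)
}

test_that("filter_de applies inclusive |log2FC| and FDR thresholds", {
  rec <- de_records(c("g1", "g2", "g3"), c(1.2, -0.5, -4.1),
                    c(0.01, 0.01, 0.2))
  expect_identical(filter_de(rec, 1, 0.05)$members, "g1")
  expect_identical(filter_de(rec, 4, 0.05, "down")$members, character(0))
  # boundary values are included (>= / <=)
  b <- de_records(c("a", "b"), c(1, -1), c(0.05, 0.05))
  expect_setequal(filter_de(b, 1, 0.05)$members, c("a", "b"))
  expect_identical(filter_de(b, 1, 0.05, "up")$members, "a")
  expect_identical(filter_de(b, 1, 0.05, "down")$members, "b")
  expect_error(filter_de(rec, -1), "lfc_cutoff")
  expect_error(filter_de(rbind(rec, de_records("g9", 1, 0.01, "H"))),
               "single contrast")
})

test_that("filter_de is monotone in its cutoffs", {
  set.seed(41)
  rec <- de_records(sprintf("g%03d", 1:200), rnorm(200, 0, 2),
                    runif(200))
  base <- filter_de(rec, 1, 0.05)$members
  expect_true(all(filter_de(rec, 2, 0.05)$members %in% base))
  expect_true(all(filter_de(rec, 1, 0.01)$members %in% base))
  # direction lists partition the two-sided list
  up <- filter_de(rec, 1, 0.05, "up")$members
  down <- filter_de(rec, 1, 0.05, "down")$members
  expect_setequal(c(up, down), base)
  expect_length(intersect(up, down), 0L)
})

test_that("intersect_de behaves as set intersection", {
  a <- list(members = c("a", "b", "c"))
  b <- list(members = c("b", "c"))
  c_ <- list(members = "c")
  expect_identical(intersect_de(list(a, b, c_)), "c")
  expect_identical(intersect_de(list(a, list(members = "z"))), character(0))
  expect_setequal(intersect_de(list(a, a)), a$members)
  expect_error(intersect_de(list(a)), "two")
})

local_orthomap <- function() {
  p <- write_tsv_lines(c("Orthogroup\tAth\tPda",
                         "OG1\tAT1\tPD1, PD2",
                         "OG2\tAT2\t",
                         "OG3\tAT3, AT4\tPD3",
                         "OG4\tAT5\tPD4"))
  read_orthogroups(p)
}

test_that("map_orthologs keeps one-to-many and reports unmapped genes", {
  om <- local_orthomap()
  expect_message(res <- map_orthologs(c("AT1", "AT2", "ATX"), om, "Ath",
                                      "Pda"), "2 of 3")
  expect_identical(res$AT1, c("PD1", "PD2"))
  expect_identical(res$AT2, character(0))
  expect_identical(res$ATX, character(0))
  # two source genes sharing one orthogroup map identically
  both <- map_orthologs(c("AT3", "AT4"), om, "Ath", "Pda")
  expect_identical(both$AT3, both$AT4)
  expect_error(map_orthologs("AT1", om, "Zma", "Pda"), "unknown species")
})

test_that("project_signature_sets carries labels and drops empty images", {
  om <- local_orthomap()
  sets <- gene_sets(c("S1", "S1", "S2"), c("APX cytosol", "APX cytosol",
                                           "CAT peroxisome"),
                    c("AT1", "AT2", "AT2"))
  expect_warning(proj <- project_signature_sets(sets, om, "Ath", "Pda"),
                 "S2")
  expect_length(proj, 1L)
  expect_identical(proj$S1$members, c("PD1", "PD2"))
  expect_identical(proj$S1$set_label, "APX cytosol")
  # union of projected members stays inside the image of the source union
  img <- unlist(map_orthologs(c("AT1", "AT2"), om, "Ath", "Pda"))
  expect_true(all(proj$S1$members %in% img))
})

test_that("set_enrichment mirrors the motif Fisher machinery on sets", {
  background <- sprintf("g%02d", 1:50)
  de <- background[1:5]
  sets <- list(
    hit = list(set_id = "hit", set_label = "x", members = de),
    miss = list(set_id = "miss", set_label = "y",
                members = background[40:50]),
    all = list(set_id = "all", set_label = "z",
               members = c(background, "extra_gene")))
  rows <- set_enrichment(sets, de, background, correction = "bh")
  expect_equal(rows$p_raw[rows$test_id == "hit"],
               oracle_tail(5, 5, 5, 50), tolerance = 1e-12)
  expect_equal(rows$p_raw[rows$test_id == "miss"], 1)
  # set covering the whole background: k = K, n = N, forced p = 1
  expect_identical(rows$n[rows$test_id == "all"], 50L)
  expect_equal(rows$p_raw[rows$test_id == "all"], 1)
  expect_identical(rows$method, rep("bh", 3))
  expect_error(set_enrichment(sets, de, character(0)), "empty background")
})

test_that("cooccurrence counts singles, pairs and conserving patterns", {
  genes <- c("g1", "g2", "g3")
  presence <- matrix(FALSE, 3, 2, dimnames = list(genes, c("CCA1", "ME")))
  presence["g1", ] <- c(TRUE, TRUE)
  presence["g2", "CCA1"] <- TRUE
  hits <- structure(list(genes = genes, motifs = colnames(presence),
                         presence = presence), class = "motif_hits")
  co <- cooccurrence(hits, genes, c("CCA1", "ME"))
  expect_identical(unname(co$single), c(2, 1))
  expect_identical(co$pairs$both, 1L)
  expect_identical(sum(co$patterns$count), 3L)
  neither <- co$patterns$count[co$patterns$CCA1 == 0 & co$patterns$ME == 0]
  expect_identical(neither, 1L)

  co_empty <- cooccurrence(hits, character(0), c("CCA1", "ME"))
  expect_identical(sum(co_empty$patterns$count), 0L)
  expect_error(cooccurrence(hits, genes, "nope"), "unknown motif_id")
  expect_error(cooccurrence(hits, c(genes, "gX"), "CCA1"), "universe")
})

test_that("signed_lfc_matrix thresholds fold changes into -1/0/1", {
  tabs <- list(
    D = de_records(c("g1", "g2", "g3"), c(2, -3, 0.5), c(0.01, 0.01, 0.01)),
    H = de_records(c("g1", "g3"), c(-1, 5), c(0.2, 0.04), contrast = "H"))
  m <- signed_lfc_matrix(tabs, c("g1", "g2", "g3"))
  expect_identical(m["g1", "D"], 1L)
  expect_identical(m["g2", "D"], -1L)
  expect_identical(m["g3", "D"], 0L)
  expect_identical(m["g1", "H"], 0L)   # fails FDR
  expect_identical(m["g3", "H"], 1L)
  expect_identical(m["g2", "H"], 0L)   # absent from the H table
})
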