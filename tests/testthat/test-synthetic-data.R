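small_config <- function(seed = 1, ...) {
  args <- modifyList(list(seed = seed, n_contigs = 2L, n_genes = 60L,
                          n_de_genes = 10L, n_motifs_null = 5L,
                          promoter_length = 200L),
                     list(...))
  do.call(simulation_config, args)
}

test_that("simulate_genome is deterministic, respects GC and packing limits", {
  cfg <- small_config(seed = 5)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a, b)
  expect_identical(nrow(a$genes), 60L)
  expect_true(all(a$genes$strand %in% c("+", "-")))

  at_only <- simulate_genome(small_config(seed = 5, gc_content = 0))
  expect_false(grepl("[GC]", paste(at_only$genome, collapse = "")))

  none <- simulate_genome(small_config(seed = 5, n_genes = 0L,
                                       n_de_genes = 0L))
  expect_identical(nrow(none$genes), 0L)

  expect_error(simulate_genome(small_config(seed = 5,
                                            contig_length = 100L)),
               "infeasible packing")
})

test_that("simulated promoter windows are private and full length", {
  cfg <- small_config(seed = 6)
  sim <- simulate_genome(cfg)
  prom <- extract_promoters(sim$genes, sim$genome, cfg$promoter_length)
  expect_identical(prom$report$n_truncated, 0L)
  # the extractor's spans equal the generator's recorded windows
  gt <- sim$truth$genes[order(sim$truth$genes$gene_id), ]
  expect_identical(prom$promoters$span_start, gt$window_lo)
  expect_identical(prom$promoters$span_end, gt$window_hi)
  # windows are pairwise disjoint within a contig
  for (ctg in unique(gt$contig)) {
    w <- gt[gt$contig == ctg, ]
    w <- w[order(w$window_lo), ]
    expect_true(all(diff(w$window_lo) >= (w$window_hi - w$window_lo + 1L)[
      -nrow(w)]))
  }
})

test_that("every recorded planting is found by the scanner at its gene", {
  cfg <- small_config(
    seed = 7,
    planted_motifs = data.frame(
      motif_id = c("P1", "P2"), sequence = c("ACTCAT", "TGGAWA"),
      rate_in_de = c(1, 0.8), rate_in_background = c(0.1, 0.1)))
  sim <- simulate_genome(cfg)
  dt <- simulate_de_truth(cfg, sim$genes)
  sim <- plant_motifs(sim, cfg, dt)
  planting <- sim$truth$planting
  expect_gt(nrow(planting), 0L)
  # instance present verbatim in the genome at the recorded offset
  for (i in seq_len(nrow(planting))) {
    got <- substr(sim$genome[[planting$contig[i]]], planting$offset[i],
                  planting$offset[i] + nchar(planting$instance[i]) - 1L)
    expect_identical(got, planting$instance[i])
  }
  # and the scanner sees the motif in that gene's promoter (policy both)
  prom <- extract_promoters(sim$genes, sim$genome, cfg$promoter_length)
  lib <- simulate_motif_library(cfg)
  hits <- scan_promoters(prom$promoters, lib, "both")
  for (i in seq_len(nrow(planting))) {
    expect_true(hits$presence[planting$gene_id[i], planting$motif_id[i]],
                info = paste(planting$gene_id[i], planting$motif_id[i]))
  }
  # rate_in_de = 1: every true-DE promoter carries a recorded P1 instance
  de_set <- dt$gene_id[dt$contrast == cfg$planting_contrast]
  expect_true(all(de_set %in%
                    planting$gene_id[planting$motif_id == "P1"]))
})

test_that("zero planting rates leave the genome unchanged", {
  cfg0 <- small_config(seed = 8)
  cfgp <- small_config(
    seed = 8,
    planted_motifs = data.frame(motif_id = "P1", sequence = "ACTCAT",
                                rate_in_de = 0, rate_in_background = 0))
  sim0 <- simulate_genome(cfg0)
  dt <- simulate_de_truth(cfgp, sim0$genes)
  planted <- plant_motifs(simulate_genome(cfgp), cfgp, dt)
  expect_identical(planted$genome, sim0$genome)
  expect_identical(nrow(planted$truth$planting), 0L)
})

test_that("background occurrence counts match the closed-form expectation", {
  # 6-mer over i.i.d. GC=0.5 background: E[sense hits per 1000-bp promoter]
  # = 995 * (1/4)^6; Monte-Carlo mean over 2000 promoters within 3 SE
  cfg <- simulation_config(seed = 9, n_contigs = 1L, n_genes = 2000L,
                           n_de_genes = 0L, gc_content = 0.5,
                           n_motifs_null = 1L, contrasts = "D")
  sim <- simulate_genome(cfg)
  prom <- extract_promoters(sim$genes, sim$genome, 1000L)
  counts <- vapply(prom$promoters$sequence, count_occurrences,
                   integer(1), motif = "TTACGC", policy = "sense",
                   USE.NAMES = FALSE)
  expected <- 995 * (1 / 4)^6
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("strict-margin DE tables are recovered exactly by filter_de", {
  cfg <- small_config(seed = 10)
  sim <- simulate_genome(cfg)
  dt <- simulate_de_truth(cfg, sim$genes)
  tabs <- simulate_de_tables(cfg, sim$genes, dt)
  expect_named(tabs, c("D", "H", "HD"))
  for (ct in names(tabs)) {
    got <- sort(filter_de(tabs[[ct]], 1, 0.05)$members)
    expect_identical(got, sort(dt$gene_id[dt$contrast == ct]))
    # FDR column is BH over the emitted p-values
    expect_equal(tabs[[ct]]$fdr, bh_fdr(tabs[[ct]]$pvalue))
  }
  expect_identical(simulate_de_tables(cfg, sim$genes, dt), tabs)
})

test_that("with no true DE genes, spurious discoveries respect the binomial bound", {
  # each null gene passes only if |lfc| >= 1, which the generator caps below
  # 1, so filter_de must return exactly the empty set in every replicate
  hits <- 0L
  for (r in 1:20) {
    cfg <- small_config(seed = 100 + r, n_de_genes = 0L)
    sim <- simulate_genome(cfg)
    dt <- simulate_de_truth(cfg, sim$genes)
    tabs <- simulate_de_tables(cfg, sim$genes, dt)
    hits <- hits + length(filter_de(tabs$D, 1, 0.05)$members)
  }
  expect_identical(hits, 0L)
})

test_that("null library motifs are sequence-independent of the planted panel", {
  cfg <- small_config(seed = 14, n_motifs_null = 40L,
                      planted_motifs = planted_panel())
  lib <- simulate_motif_library(cfg)
  nulls <- lib[lib$category == "null", ]
  expect_identical(nrow(nulls), 40L)
  for (p in planted_panel()$sequence) {
    for (s in nulls$sequence) {
      expect_false(promotif:::iupac_cross_reactive(s, p, 4L),
                   info = paste(s, "vs", p))
    }
  }
  # cross-reactivity detector sanity: a motif overlapping a planted element
  # in either orientation is flagged
  expect_true(promotif:::iupac_cross_reactive("ACGTGC", "CACGTG"))
  expect_true(promotif:::iupac_cross_reactive("AGTGTGGY", "CCACAC"))
  expect_false(promotif:::iupac_cross_reactive("TTTTTT", "CACGTG"))
})

test_that("orthogroup and set simulation respects relation proportions", {
  cfg <- small_config(seed = 11)
  sim <- simulate_genome(cfg)
  dt <- simulate_de_truth(cfg, sim$genes)

  one2one <- simulate_orthogroups_and_sets(
    modifyList(cfg, list(ortholog_props = c(one2one = 1, one2many = 0,
                                            absent = 0))), sim$genes, dt)
  sizes <- lengths(lapply(one2one$orthomap$orthogroups, `[[`, "Pda"))
  kept <- one2one$truth$relation == "one2one"
  expect_true(all(sizes[kept] == 1L))
  # 1:1-only: every projected set size equals its source size (minus any
  # genes whose relation fell back to absent when the pool ran out)
  expect_true(all(one2one$truth$n_targets[kept] == 1L))

  absent <- simulate_orthogroups_and_sets(
    modifyList(cfg, list(ortholog_props = c(one2one = 0, one2many = 0,
                                            absent = 1))), sim$genes, dt)
  expect_true(all(lengths(lapply(absent$orthomap$orthogroups,
                                 `[[`, "Pda")) == 0L))
  expect_warning(
    project_signature_sets(absent$signature_sets, absent$orthomap,
                           "Ath", "Pda"),
    "dropped")

  again <- simulate_orthogroups_and_sets(
    modifyList(cfg, list(ortholog_props = c(one2one = 0, one2many = 0,
                                            absent = 1))), sim$genes, dt)
  expect_identical(absent, again)
})

test_that("simulate_experiment writes a parseable, warning-free fixture set", {
  dir <- withr::local_tempdir()
  cfg <- small_config(
    seed = 12,
    planted_motifs = data.frame(motif_id = "P1", sequence = "ACTCAT",
                                rate_in_de = 0.8,
                                rate_in_background = 0.05))
  sim <- simulate_experiment(cfg, dir)
  expect_true(all(file.exists(unlist(sim$paths))))
  # parsers are total on generated fixtures: no warnings anywhere
  expect_no_warning({
    g <- read_genome(sim$paths$genome)
    gm <- read_gene_models(sim$paths$gff3)
    lib <- read_motif_library(sim$paths$motifs)
    om <- read_orthogroups(sim$paths$orthogroups)
    ss <- read_gene_sets(sim$paths$signature_sets)
    gs <- read_gene_sets(sim$paths$go_sets)
    de <- read_de_table(sim$paths$de_D, "D")
  })
  expect_identical(g, sim$genome)
  expect_identical(gm, sim$genes)
  expect_identical(nrow(de), nrow(sim$genes))
  # truth ledger round-trips
  planted <- read.delim(sim$paths$truth_planting)
  expect_identical(nrow(planted), nrow(sim$truth$planting))
  # different seed: same schema, different genome
  sim2 <- simulate_experiment(small_config(seed = 13), withr::local_tempdir())
  expect_false(identical(sim2$genome, sim$genome))
})
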