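# Synthetic-data generator: complete, self-consistent fixtures (genome +
# gene models + motif library + DE tables + orthogroups + gene sets) with a
# truth ledger, emulating the statistical structure the enrichment analysis
# assumes. Background sequence is i.i.d. at a configurable GC content so
# background motif-occurrence rates have closed forms; genes sit in disjoint
# slots so every promoter window is private and full length.

#' Build a simulation configuration
#'
#' Defaults emulate a compact stress-transcriptomics study: three contrasts
#' (drought D, heat H, combined HD), 1-kbp promoters, a mostly-null degenerate
#' motif library, and a plant-like AT-rich background (GC 0.4).
#'
#' @param seed Integer master seed; every output is a pure function of the
#'   configuration including this seed.
#' @param n_contigs,n_genes,gene_length Genome layout (genes are placed in
#'   disjoint slots on both strands).
#' @param contig_length Optional fixed contig length; the default (`NULL`)
#'   sizes contigs to fit the requested genes. A value too small to pack them
#'   is an error.
#' @param promoter_length Upstream window in bp (default 1000).
#' @param gc_content Background GC fraction in (0,1).
#' @param n_motifs_null Number of random (unplanted) library motifs.
#' @param motif_length_range Length range for random motifs.
#' @param planted_motifs data.frame with columns `motif_id`, `sequence`,
#'   `rate_in_de`, `rate_in_background` (per-gene planting probabilities;
#'   `rate_in_de >= rate_in_background`).
#' @param n_de_genes True-DE genes per contrast.
#' @param contrasts Contrast labels (default `c("D","H","HD")`).
#' @param planting_contrast Contrast whose true-DE set drives planting
#'   (default the first).
#' @param de_lfc_location,de_lfc_scale,de_lfc_min True-effect magnitude
#'   distribution: `|log2FC|` is normal(location, scale) resampled to stay
#'   `>= de_lfc_min`, sign uniform. With `de_lfc_min > 1` and null effects
#'   capped below 1 (see `null_lfc_max`), the (1, 0.05) filter recovers the
#'   true set exactly.
#' @param null_lfc_max Cap on null-gene |log2FC| (default 0.9).
#' @param n_signature_sets,signature_set_size Signature-set structure over
#'   the model species.
#' @param ortholog_props Proportions of 1:1, 1:many and absent ortholog
#'   relations (must sum to 1).
#' @param frac_de_in_sets Fraction of signature-set target genes drawn from
#'   the true-DE pool (the enrichment signal).
#' @param n_go_sets,go_set_size GO-style sets over target-species ids.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_contigs = 2L,
                              n_genes = 2000L,
                              gene_length = 100L,
                              contig_length = NULL,
                              promoter_length = 1000L,
                              gc_content = 0.4,
                              n_motifs_null = 150L,
                              motif_length_range = c(6L, 8L),
                              planted_motifs = NULL,
                              n_de_genes = 200L,
                              contrasts = c("D", "H", "HD"),
                              planting_contrast = contrasts[1],
                              de_lfc_location = 2.5,
                              de_lfc_scale = 0.8,
                              de_lfc_min = 1.2,
                              null_lfc_max = 0.9,
                              n_signature_sets = 8L,
                              signature_set_size = c(4L, 12L),
                              ortholog_props = c(one2one = 0.7,
                                                 one2many = 0.2,
                                                 absent = 0.1),
                              frac_de_in_sets = 0.5,
                              n_go_sets = 10L,
                              go_set_size = c(10L, 40L)) {
  if (gc_content < 0 || gc_content > 1) {
    stop("gc_content must lie in [0, 1]", call. = FALSE)
  }
  if (n_de_genes > n_genes) stop("n_de_genes > n_genes", call. = FALSE)
  if (abs(sum(ortholog_props) - 1) > 1e-9) {
    stop("ortholog_props must sum to 1", call. = FALSE)
  }
  if (!is.null(planted_motifs) && nrow(planted_motifs)) {
    stopifnot(all(c("motif_id", "sequence", "rate_in_de",
                    "rate_in_background") %in% names(planted_motifs)))
    assert_probability(planted_motifs$rate_in_de, "rate_in_de")
    assert_probability(planted_motifs$rate_in_background,
                       "rate_in_background")
    if (any(planted_motifs$rate_in_de < planted_motifs$rate_in_background)) {
      stop("rate_in_de must be >= rate_in_background", call. = FALSE)
    }
    if (!all(is_iupac(planted_motifs$sequence))) {
      stop("planted motif sequences must be IUPAC", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "simulation_config")
}

# distinct deterministic sub-seeds per stage, kept below 2^31
stage_seed <- function(config, stage) {
  offsets <- c(genome = 101L, plant = 211L, de = 307L, sets = 401L,
               motifs = 503L)
  (as.integer(config$seed) %% 20000000L) * 100L + offsets[[stage]]
}

random_nucleotides <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Simulate a genome with slotted gene models
#'
#' Contigs are i.i.d. nucleotides at the configured GC content. Each gene
#' occupies a private slot of `promoter_length + gene_length` bp: a `+` gene
#' sits after its upstream window, a `-` gene before it, so no promoter
#' window overlaps another window or gene body and none is truncated.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named character vector), `genes` (gene-model
#'   data.frame) and `truth` (per-gene promoter windows and strands).
#' @export
simulate_genome <- function(config) {
  set.seed(stage_seed(config, "genome"))
  P <- config$promoter_length
  L <- config$gene_length
  slot <- P + L
  n_per <- diff(round(seq(0, config$n_genes,
                          length.out = config$n_contigs + 1L)))
  needed <- max(n_per) * slot
  clen <- config$contig_length %||% needed
  if (clen < needed) {
    stop("infeasible packing: ", max(n_per), " genes need ", needed,
         " bp but contig_length is ", clen, call. = FALSE)
  }
  genome <- character(config$n_contigs)
  names(genome) <- sprintf("ctg%02d", seq_len(config$n_contigs))
  gene_rows <- vector("list", config$n_contigs)
  idx0 <- 0L
  for (ci in seq_len(config$n_contigs)) {
    ng <- n_per[ci]
    genome[ci] <- paste(random_nucleotides(clen, config$gc_content),
                        collapse = "")
    if (ng == 0L) next
    slot_start <- (seq_len(ng) - 1L) * slot + 1L
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    gstart <- ifelse(strand == "+", slot_start + P, slot_start)
    gend <- gstart + L - 1L
    win_lo <- ifelse(strand == "+", slot_start, gend + 1L)
    win_hi <- win_lo + P - 1L
    gene_rows[[ci]] <- data.frame(
      gene_id = sprintf("PDSIM_G%05d", idx0 + seq_len(ng)),
      contig = names(genome)[ci], start = gstart, end = gend,
      strand = strand, window_lo = win_lo, window_hi = win_hi,
      stringsAsFactors = FALSE)
    idx0 <- idx0 + ng
  }
  truth <- do.call(rbind, gene_rows) %||%
    data.frame(gene_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               window_lo = integer(), window_hi = integer())
  rownames(truth) <- NULL
  genes <- truth[, c("gene_id", "contig", "start", "end", "strand")]
  list(genome = genome, genes = genes, truth = list(genes = truth))
}

#' Choose the per-contrast true-DE gene sets
#' @param config A [simulation_config()].
#' @param genes Gene-model data.frame from [simulate_genome()].
#' @return data.frame `contrast`, `gene_id`.
#' @export
simulate_de_truth <- function(config, genes) {
  set.seed(stage_seed(config, "de"))
  do.call(rbind, lapply(config$contrasts, function(ct) {
    picked <- sort(sample(genes$gene_id, config$n_de_genes))
    data.frame(contrast = rep(ct, length(picked)), gene_id = picked,
               stringsAsFactors = FALSE)
  }))
}

resolve_iupac <- function(motif) {
  paste(vapply(strsplit(motif, "", fixed = TRUE)[[1]], function(code) {
    opts <- strsplit(IUPAC_CODES[[code]], "", fixed = TRUE)[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Plant motif instances into promoter windows
#'
#' For each planted motif and each gene, with probability `rate_in_de` (gene
#' in the planting contrast's true-DE set) or `rate_in_background`
#' (otherwise), one instance — IUPAC codes resolved uniformly at random,
#' orientation sense/antisense with probability 1/2 — overwrites a uniformly
#' chosen offset within the gene's promoter window. Offsets are
#' rejection-sampled so instances never straddle the window boundary and
#' never overwrite a previously planted instance; every planting is recorded.
#'
#' @param sim Result of [simulate_genome()].
#' @param config A [simulation_config()] with non-empty `planted_motifs`.
#' @param de_truth data.frame from [simulate_de_truth()].
#' @return `sim` with modified `genome` and a `truth$planting` data.frame
#'   (`gene_id`, `motif_id`, `contig`, `offset` (1-based genomic start),
#'   `orientation`, `instance`).
#' @export
plant_motifs <- function(sim, config, de_truth) {
  planting_empty <- data.frame(gene_id = character(), motif_id = character(),
                               contig = character(), offset = integer(),
                               orientation = character(),
                               instance = character(),
                               stringsAsFactors = FALSE)
  pm <- config$planted_motifs
  if (is.null(pm) || nrow(pm) == 0L ||
      all(pm$rate_in_de == 0 & pm$rate_in_background == 0)) {
    sim$truth$planting <- planting_empty
    return(sim)
  }
  set.seed(stage_seed(config, "plant"))
  if (any(nchar(pm$sequence) > config$promoter_length)) {
    stop("planted motif longer than the promoter window", call. = FALSE)
  }
  de_set <- de_truth$gene_id[de_truth$contrast == config$planting_contrast]
  chars <- lapply(sim$genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  gt <- sim$truth$genes
  occupied <- vector("list", nrow(gt))   # planted intervals per gene window
  records <- list()
  for (mi in seq_len(nrow(pm))) {
    width <- nchar(pm$sequence[mi])
    is_de <- gt$gene_id %in% de_set
    rate <- ifelse(is_de, pm$rate_in_de[mi], pm$rate_in_background[mi])
    do_plant <- runif(nrow(gt)) < rate
    for (gi in which(do_plant)) {
      lo <- gt$window_lo[gi]; hi <- gt$window_hi[gi]
      placed <- FALSE
      for (try in seq_len(200L)) {
        off <- lo + sample.int(hi - lo + 2L - width, 1L) - 1L
        clash <- any(vapply(occupied[[gi]], function(iv) {
          off <= iv[2] && off + width - 1L >= iv[1]
        }, logical(1)))
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed) next                  # window saturated; skip, unrecorded
      inst <- resolve_iupac(pm$sequence[mi])
      orient <- sample(c("sense", "antisense"), 1L)
      written <- if (orient == "antisense") revcomp_iupac(inst) else inst
      chars[[gt$contig[gi]]][off:(off + width - 1L)] <-
        strsplit(written, "", fixed = TRUE)[[1]]
      occupied[[gi]] <- c(occupied[[gi]], list(c(off, off + width - 1L)))
      records[[length(records) + 1L]] <- data.frame(
        gene_id = gt$gene_id[gi], motif_id = pm$motif_id[mi],
        contig = gt$contig[gi], offset = off, orientation = orient,
        instance = written, stringsAsFactors = FALSE)
    }
  }
  sim$genome <- vapply(chars, paste, character(1), collapse = "")
  sim$truth$planting <- if (length(records)) {
    do.call(rbind, records)
  } else planting_empty
  sim
}

#' Generate a random IUPAC motif library
#'
#' Letters are drawn mostly from `A,C,G,T` with a small fraction of two-fold
#' ambiguity codes, emulating the degeneracy of curated plant motif
#' libraries.
#'
#' @param config A [simulation_config()].
#' @return Motif-library data.frame (null motifs, then planted motifs if
#'   any), with `category` `"null"`/`"planted"` and `source` `"synthetic"`.
#' @export
simulate_motif_library <- function(config) {
  set.seed(stage_seed(config, "motifs"))
  letters_pool <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M")
  probs <- c(rep(0.22, 4), rep(0.02, 6))
  lens <- sample(seq(config$motif_length_range[1],
                     config$motif_length_range[2]),
                 config$n_motifs_null, replace = TRUE)
  planted_seqs <- config$planted_motifs$sequence %||% character(0)
  # a "null" motif must be sequence-independent of every planted element:
  # reject candidates whose degenerate match set can overlap a planted
  # motif (either orientation) by 4+ positions, since such motifs pick up
  # the planted signal and are not null
  draw_null <- function(l) {
    for (try in seq_len(1000L)) {
      cand <- paste(sample(letters_pool, l, replace = TRUE, prob = probs),
                    collapse = "")
      clash <- any(vapply(planted_seqs, function(p)
        iupac_cross_reactive(cand, p, 4L), logical(1)))
      if (!clash) return(cand)
    }
    stop("could not draw a null motif independent of the planted panel",
         call. = FALSE)
  }
  seqs <- vapply(lens, draw_null, character(1))
  null_lib <- data.frame(
    motif_id = sprintf("NULL_M%03d", seq_len(config$n_motifs_null)),
    sequence = seqs, category = "null", source = "synthetic",
    stringsAsFactors = FALSE)
  pm <- config$planted_motifs
  if (!is.null(pm) && nrow(pm)) {
    null_lib <- rbind(null_lib, data.frame(
      motif_id = pm$motif_id, sequence = toupper(pm$sequence),
      category = "planted", source = "synthetic",
      stringsAsFactors = FALSE))
  }
  null_lib
}

#' Simulate per-contrast DE tables consistent with the truth
#'
#' True-DE genes draw `|log2FC| >= de_lfc_min > 1` and p-values small enough
#' that their BH-adjusted FDR is strictly below 0.05; null genes draw
#' `|log2FC| <= null_lfc_max < 1` and uniform p-values. The FDR column is
#' recomputed with [bh_fdr()] over the emitted p-values, so
#' `filter_de(records, 1, 0.05)` recovers exactly the true-DE set.
#'
#' @param config A [simulation_config()].
#' @param genes Gene-model data.frame.
#' @param de_truth data.frame from [simulate_de_truth()].
#' @return Named list (one data.frame per contrast) in [read_de_table()]
#'   layout.
#' @export
simulate_de_tables <- function(config, genes, de_truth) {
  set.seed(stage_seed(config, "de") + 7L)
  m <- nrow(genes)
  out <- lapply(config$contrasts, function(ct) {
    true_set <- de_truth$gene_id[de_truth$contrast == ct]
    K <- length(true_set)
    is_true <- genes$gene_id %in% true_set
    p <- runif(m)
    lfc <- rnorm(m, 0, 0.3)
    lfc <- pmin(pmax(lfc, -config$null_lfc_max), config$null_lfc_max)
    if (K > 0L) {
      p_cap <- 0.04 * K / m
      p[is_true] <- runif(K, 0, p_cap)
      mag <- rnorm(K, config$de_lfc_location, config$de_lfc_scale)
      while (any(mag < config$de_lfc_min)) {
        bad <- mag < config$de_lfc_min
        mag[bad] <- rnorm(sum(bad), config$de_lfc_location,
                          config$de_lfc_scale)
      }
      lfc[is_true] <- mag * sample(c(-1, 1), K, replace = TRUE)
    }
    data.frame(feature_id = genes$gene_id, contrast = ct, log2fc = lfc,
               pvalue = p, fdr = bh_fdr(p), stringsAsFactors = FALSE)
  })
  names(out) <- config$contrasts
  out
}

#' Simulate orthogroups, signature sets and GO-style sets
#'
#' Model-species ("Ath") gene ids are invented and related to target-species
#' genes through orthogroups with configurable 1:1 / 1:many / absent
#' proportions. Signature sets are drawn so that a configurable fraction of
#' their target images are true-DE (in the planting contrast); GO-style sets
#' are drawn over target ids directly, the first with the same DE signal and
#' the rest at random.
#'
#' @param config A [simulation_config()].
#' @param genes Gene-model data.frame (target species).
#' @param de_truth data.frame from [simulate_de_truth()].
#' @return List with `orthomap`, `signature_sets` (model-species ids),
#'   `go_sets` (target ids) and `truth` (per-model-gene relation table).
#' @export
simulate_orthogroups_and_sets <- function(config, genes, de_truth) {
  set.seed(stage_seed(config, "sets"))
  de_set <- de_truth$gene_id[de_truth$contrast == config$planting_contrast]
  null_pool <- setdiff(genes$gene_id, de_set)

  n_model <- max(50L, config$n_signature_sets *
                   config$signature_set_size[2] * 2L)
  model_ids <- sprintf("AT%05dSIM", seq_len(n_model))
  relation <- sample(names(config$ortholog_props), n_model, replace = TRUE,
                     prob = config$ortholog_props)
  # pre-assign each model gene a DE-status so sets can hit their DE fraction
  model_is_de <- runif(n_model) < config$frac_de_in_sets
  model_is_de[relation == "absent"] <- NA
  targets <- vector("list", n_model)
  used <- list(de = 0L, null = 0L)
  shuffled <- list(de = sample(de_set), null = sample(null_pool))
  # each target gene belongs to at most one orthogroup: draw without
  # replacement and fall back to "absent" when a pool is exhausted
  take <- function(kind, n) {
    i <- used[[kind]]
    if (i + n > length(shuffled[[kind]])) return(NULL)
    used[[kind]] <<- i + n
    shuffled[[kind]][(i + 1L):(i + n)]
  }
  for (i in seq_len(n_model)) {
    if (relation[i] == "absent") next
    n_t <- if (relation[i] == "one2one") 1L else sample(2:3, 1L)
    kind <- if (isTRUE(model_is_de[i])) "de" else "null"
    t <- take(kind, n_t)
    if (is.null(t)) {
      relation[i] <- "absent"
      model_is_de[i] <- NA
      next
    }
    targets[[i]] <- t
  }
  ogs <- lapply(seq_len(n_model), function(i) {
    list(Ath = model_ids[i], Pda = targets[[i]] %||% character(0))
  })
  names(ogs) <- sprintf("OG%07d", seq_len(n_model))
  orthomap <- structure(list(species = c("Ath", "Pda"), orthogroups = ogs),
                        class = "orthomap")

  families <- c("APX", "CAT", "SOD", "GPX", "PRX", "GR", "TRX", "FER",
                "MDAR", "DHAR")
  compartments <- c("cytosol", "chloroplast", "mitochondrion", "peroxisome")
  sig_sets <- lapply(seq_len(config$n_signature_sets), function(si) {
    sz <- sample(seq(config$signature_set_size[1],
                     config$signature_set_size[2]), 1L)
    members <- sample(model_ids, sz)
    list(set_id = sprintf("ROS_S%02d", si),
         set_label = paste(families[(si - 1L) %% length(families) + 1L],
                           compartments[(si - 1L) %% length(compartments) +
                                          1L]),
         members = members)
  })
  names(sig_sets) <- vapply(sig_sets, `[[`, character(1), "set_id")

  go_sets <- lapply(seq_len(config$n_go_sets), function(gi) {
    sz <- sample(seq(config$go_set_size[1], config$go_set_size[2]), 1L)
    members <- if (gi == 1L) {
      n_de <- round(sz * config$frac_de_in_sets)
      c(sample(de_set, min(n_de, length(de_set))),
        sample(null_pool, sz - min(n_de, length(de_set))))
    } else {
      sample(genes$gene_id, sz)
    }
    list(set_id = sprintf("GO:%07d", gi),
         set_label = sprintf("synthetic process %d", gi),
         members = sort(unique(members)))
  })
  names(go_sets) <- vapply(go_sets, `[[`, character(1), "set_id")

  truth <- data.frame(model_gene = model_ids, relation = relation,
                      n_targets = lengths(targets),
                      stringsAsFactors = FALSE)
  list(orthomap = orthomap, signature_sets = sig_sets, go_sets = go_sets,
       truth = truth)
}

#' Simulate a complete experiment and write every fixture file
#'
#' One call produces all pipeline inputs (genome FASTA, GFF3 gene models,
#' motif-library TSV, one DE TSV per contrast, orthogroup TSV, signature and
#' GO set TSVs) plus the truth ledger (`truth_de.tsv`, `truth_planting.tsv`)
#' and a JSON echo of the configuration.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths), `truth`, `config` and the
#'   in-memory objects (`genome`, `genes`, `motifs`, `de_tables`,
#'   `orthomap`, `signature_sets`, `go_sets`).
#' @export
simulate_experiment <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  de_truth <- simulate_de_truth(config, sim$genes)
  sim <- plant_motifs(sim, config, de_truth)
  motifs <- simulate_motif_library(config)
  de_tables <- simulate_de_tables(config, sim$genes, de_truth)
  sets <- simulate_orthogroups_and_sets(config, sim$genes, de_truth)

  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    gff3 = file.path(dir, "genes.gff3"),
    motifs = file.path(dir, "motif_library.tsv"),
    orthogroups = file.path(dir, "orthogroups.tsv"),
    signature_sets = file.path(dir, "signature_sets.tsv"),
    go_sets = file.path(dir, "go_sets.tsv"),
    truth_de = file.path(dir, "truth_de.tsv"),
    truth_planting = file.path(dir, "truth_planting.tsv"),
    config = file.path(dir, "config.json"))
  for (ct in config$contrasts) {
    paths[[paste0("de_", ct)]] <- file.path(dir, paste0("de_", ct, ".tsv"))
  }
  write_genome(sim$genome, paths$genome)
  write_gene_models(sim$genes, paths$gff3)
  write_motif_library(motifs, paths$motifs)
  write_orthogroups(sets$orthomap, paths$orthogroups)
  write_gene_sets(sets$signature_sets, paths$signature_sets)
  write_gene_sets(sets$go_sets, paths$go_sets)
  for (ct in config$contrasts) {
    write_de_table(de_tables[[ct]], paths[[paste0("de_", ct)]])
  }
  write_tsv(de_truth, paths$truth_de)
  write_tsv(sim$truth$planting, paths$truth_planting)
  cfg <- unclass(config)
  cfg$planted_motifs <- if (is.null(cfg$planted_motifs)) NULL else
    as.list(cfg$planted_motifs)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")

  list(paths = paths, config = config,
       truth = c(sim$truth, list(de = de_truth, sets = sets$truth)),
       genome = sim$genome, genes = sim$genes, motifs = motifs,
       de_tables = de_tables, orthomap = sets$orthomap,
       signature_sets = sets$signature_sets, go_sets = sets$go_sets)
}
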