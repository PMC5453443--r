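---
title: "Promoter cis-motif enrichment: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter cis-motif enrichment: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promotif)
```

## The question the pipeline answers

Stress experiments in plants typically end with lists of differentially
expressed (DE) genes per contrast — say drought (D), heat (H) and combined
heat-and-drought (HD) versus control. A natural follow-up is regulatory:
are known transcription-factor binding elements over-represented in the
promoters of the responding genes? promotif implements that analysis as a
reusable, testable pipeline: extract the upstream promoter of every gene,
scan a curated library of degenerate (IUPAC) cis-elements, and test each
motif's over-representation among DE genes with a one-sided Fisher exact
test under family-wise (Bonferroni) control. Companion stages project
curated signature gene sets (e.g. ROS-scavenging enzyme families annotated
by subcellular compartment) from a model species through orthogroups, run
generic gene-set over-representation with Benjamini–Hochberg control, and
tabulate motif co-occurrence within a gene set of interest.

## The statistical model

For one motif and one contrast, gene-level *presence* (at least one match
in the promoter, on either orientation) is crossed with DE status over a
background universe of $N$ genes containing the $K$ DE genes:

* $n$ — background genes whose promoter carries the motif,
* $k$ — DE genes whose promoter carries it.

Under the null that presence is independent of DE status, $k$ follows a
hypergeometric$(N, n, K)$ law, and the reported p-value is the upper tail
$P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{n}{i}\binom{N-n}{K-i} /
\binom{N}{K}$ — a one-sided ("greater") Fisher exact test, since only
over-representation is of interest. `fisher_greater()` evaluates the tail
directly via `phyper(..., lower.tail = FALSE)` (no $1-\mathrm{CDF}$
cancellation); the test suite checks it against an independent brute-force
tail summation to $10^{-10}$.

P-values are corrected within the motif family of one contrast:
Bonferroni ($p_{\mathrm{adj}} = \min(1, m\,p)$, $m$ = number of motifs
tested, configurable upwards via `family_size`) with significance at
$p_{\mathrm{adj}} \le 0.05$. Contrasts are corrected independently, which
matches how per-condition significance grids are usually presented. Set
enrichment (GO, projected signatures) uses the same 2×2 machinery with
membership in place of presence and BH step-up FDR in place of Bonferroni,
the convention for large set families.

### Choices where the procedure is genuinely open

* **Presence, not counts.** A 2×2 table needs a per-gene binary; "gene has
  the motif" is the standard reading, so occurrence counts are kept in the
  outputs but presence feeds the test.
* **Background universe.** Default: all genes in the contrast's DE table —
  the genes that *could* have been called DE. Using all genome genes
  instead is a flag away (`background=`), and matters when many genes are
  unexpressed.
* **Both orientations.** Scanning is strand-aware; the default policy
  `both` takes the union of sense and antisense matches for presence, a
  conservative superset of either single-orientation reading. Per-strand
  tables remain available (`policy = "sense"`/`"antisense"`).
* **Truncated promoters are kept** (flagged), with presence = FALSE when
  empty: they were scanned and could not contribute hits; dropping them
  would shrink $n$ and $N$ asymmetrically. `drop_truncated = TRUE`
  reverses this.
* **Promoters are not trimmed at upstream gene boundaries**; the window is
  a fixed 1 kbp (configurable) upstream of the annotated gene start.

## Matching semantics

Motifs use the 15-letter IUPAC alphabet. A motif letter matches a subject
base iff the base is in the letter's allowed set; every (possibly
overlapping) offset is counted; an `N` in the *subject* matches no motif
letter, including motif `N` — unknown sequence must never create hits.
This last rule is why the scanner is implemented in the package (a compact
bit-parallel Shift-And kernel in C++) rather than delegated: the common
ambiguity-aware matchers treat subject `N` as matchable. Minus-strand
promoters are reverse-complemented at extraction so all promoters read
5′→3′ toward the gene; with policy `both` the final presence matrix is
invariant under reverse-complementing the genome and mirroring the gene
coordinates, which the suite verifies exactly.

Motif libraries are four-column TSVs (`motif_id`, `sequence`, `category`,
`source`); a small starter library ships in
`inst/extdata/starter_motifs.tsv` with the circadian CCA1 element
(AAAAATCT), the morning (CCACAC) and evening (TGGATA) elements and the
proline/hypoosmolarity PRE (ACTCAT), and doubles as a format example.

## Coordinates

GFF3 coordinates stay 1-based inclusive everywhere in the package. For a
`+` gene the promoter window is $[\mathrm{start}-L, \mathrm{start}-1]$;
for a `-` gene it is the reverse complement of $[\mathrm{end}+1,
\mathrm{end}+L]$; windows are clipped at contig edges and flagged
truncated. This arithmetic lives in exactly one place
(`extract_promoter()`), so there is a single conversion site to audit.

## What the synthetic generator emulates

`simulate_experiment()` produces every input the pipeline consumes, with a
truth ledger, so each stage is verifiable by construction:

* **Genome** — i.i.d. nucleotides at a configurable GC content (default
  0.40, AT-rich as is typical for plant genomes). i.i.d. background is a
  deliberate simplification: it gives closed-form expected background
  occurrence rates (a 6-mer in a 1000-bp window at GC 0.5 is expected
  $995 \cdot 4^{-6} \approx 0.243$ times per orientation), which the suite
  checks by Monte Carlo. Real promoters have dinucleotide structure, CpG
  avoidance and repeats; passing tests here say nothing about such
  backgrounds.
* **Gene models** — default 2,000 genes on both strands (three contrasts
  D/H/HD, 200 true-DE genes each), placed in private
  $L_{\mathrm{prom}} + L_{\mathrm{gene}}$ slots so every promoter window
  is full-length and disjoint from all gene bodies and other windows.
  Real annotations have truncated and overlapping promoters; those paths
  are exercised by dedicated unit fixtures instead.
* **Planted signal** — each panel motif is planted in a true-DE promoter
  with probability `rate_in_de` (default panel: five known plant elements,
  6–8 bp, planted at 0.6) versus `rate_in_background` (0.05) elsewhere;
  IUPAC codes are resolved uniformly, orientation is a fair coin, offsets
  are rejection-sampled so instances never straddle the window edge or
  overwrite one another, and every planting is recorded.
* **Null motifs** — random IUPAC 6–8-mers (mostly concrete letters, a
  small fraction of two-fold codes). A candidate whose degenerate match
  set can align over a planted element by four or more fully compatible
  positions (either orientation) is rejected and redrawn: such a motif
  picks up the planted signal and is genuinely enriched, so calling it
  "null" would corrupt the truth ledger. This matters: without the
  independence filter, motifs like `AGTGTGGY` (reverse complement sits on
  the morning element CCACAC) reach significance on real signal and the
  exact-recovery rate collapses.
* **DE tables** — true-DE genes draw $|\log_2 FC|$ from a normal
  (location 2.5, scale 0.8) resampled to stay $\ge 1.2$, and p-values
  small enough that BH-adjusted FDR lands strictly under 0.05; null genes
  draw uniform p-values and $|\log_2 FC|$ capped at 0.9. With these strict
  margins `filter_de(·, 1, 0.05)` recovers the true set exactly, which is
  what makes end-to-end recovery tests sharp. The FDR column is recomputed
  with the package's own `bh_fdr()` so fixtures are internally consistent.
* **Orthogroups and sets** — invented model-species genes related 1:1,
  1:many or absent (default 0.7/0.2/0.1) to target genes, each target in
  at most one orthogroup; signature sets are drawn so a configurable
  fraction (default 0.5) of their target images are true-DE.

All outputs are pure functions of the configuration (the master seed
derives one fixed sub-seed per stage), so identical configurations give
byte-identical files.

## Calibration

Two replicate-level benchmarks run the full simulate → extract → scan →
Fisher → Bonferroni path:

* `benchmark_null_fwer()` — no planting, so DE labels are independent of
  sequence; the fraction of replicates with *any* Bonferroni-significant
  motif estimates the family-wise error, compared against
  $\alpha + 3\sqrt{\alpha(1-\alpha)/R}$. The suite runs $R = 200$
  replicates at 2,000 genes × 150 motifs.
* `benchmark_planted_recovery()` — the five-element panel at 0.6 vs 0.05
  planting over 3,000 genes, 300 DE, 150 null motifs; 50 replicates. Both
  the all-recovered rate and the exact significant-set = planted-set rate
  are reported.

These problem sizes are the package's calibration conditions; the
`analysis/05_benchmarks.R` driver runs a lighter quick-look subset of the
same checks.

## Numerical and formatting conventions

P-values are serialised with 12 significant digits; enrichment rows are
ordered by raw p ascending with ties broken lexicographically by id, so
reruns on identical inputs are byte-identical. Contingency validation is
strict (integer counts, $k \le \min(K, n)$, $K, n \le N$) and violations
are hard errors, as are malformed inputs everywhere at the I/O boundary;
recoverable oddities (unknown characters in FASTA, rows with missing
effect sizes, genes in no orthogroup) are handled and counted aloud.

## Known limitations

* No position-weight-matrix scoring, background correction or de novo
  discovery — the library is a fixed set of IUPAC words.
* Promoters are anchored at annotated gene starts, not transcription
  start sites; no transcript evidence is used.
* GO sets are tested flat: no true-path propagation up the ontology.
* The generator's i.i.d. background and slotted gene placement make
  truth exact but are simpler than real genomes (see above).
* One-sided over-representation only; depletion is intentionally out of
  scope.
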