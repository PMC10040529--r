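---
title: "Screening gene families for co-occurrence with halotolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene families for co-occurrence with halotolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancooc)
```

## The problem

Closely related bacterial strains often differ sharply in a measurable
phenotype — here, the maximum NaCl concentration they tolerate — while
sharing most of their gene content. When several such genomes are
available, a simple and powerful screen asks: *which gene families are
present (or amplified) preferentially in the tolerant strains?* Families
whose per-genome abundance tracks the phenotype are candidate effectors:
osmolyte transporters, compatible-solute synthesis enzymes, membrane
remodelling proteins, and so on.

`pancooc` implements that screen end to end for a small panel of genomes:

1. **ORF prediction** — six-frame scanning of each assembly.
2. **Gene-family clustering** — all-vs-all protein distances from local
   alignment, single-linkage clustering.
3. **Pan-matrix** — the family × genome copy-count matrix.
4. **Co-occurrence screen** — Pearson correlation of each family's
   abundance vector with the phenotype vector, thresholded at 0.8.

A synthetic-genome generator plants gene families with known copy-number
patterns, so every stage of the pipeline — and the screen's final answer —
can be checked against ground truth without downloading anything.

## The statistic

For a family with per-genome copy counts $x = (x_1, \dots, x_n)$ and
phenotype $y = (y_1, \dots, y_n)$ (maximum NaCl, % w/v, one value per
strain), the co-occurrence is the sample Pearson correlation

$$ r(x, y) \;=\; \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
   {\sqrt{\sum_i (x_i - \bar x)^2 \; \sum_i (y_i - \bar y)^2}}. $$

The $1/(n-1)$ normalization factors cancel, so the sample and population
variants coincide; the tests verify this identity on random vectors.
A family present in every genome at equal copy number has
$\sum_i (x_i - \bar x)^2 = 0$ and no defined correlation: such "core" rows
are excluded from the pass list but always reported in a side channel,
never silently dropped.

Worked values against the six-strain phenotype $(10, 9, 9, 5, 4, 3)$:

```{r statistic}
y <- c(10, 9, 9, 5, 4, 3)
round_half_away(pearson_cooccurrence(c(1, 1, 1, 0, 0, 0), y))  # 3 tolerant strains
round_half_away(pearson_cooccurrence(c(1, 1, 1, 1, 0, 0), y))  # 4 strains
round_half_away(pearson_cooccurrence(c(1, 1, 2, 0, 0, 0), y))  # a duplication
```

Two design points deserve emphasis:

* **Copy counts, not presence/absence, by default.** Exhaustive
  enumeration (`enumerate_patterns()`) shows that no binary occupancy
  pattern of six genomes yields a correlation rounding to 0.84, 0.86 or
  0.87 against this phenotype vector, while copy-count vectors do (for
  example $(1,1,2,0,0,0) \to 0.84$). Values in that range can therefore
  only arise from paralog counts; binary mode is retained as an option.
* **Reporting convention.** Screening is on the unrounded value with a
  strict `>` threshold; reporting is at two decimals, rounded
  half-away-from-zero (`round_half_away()`), so 0.8146 prints as 0.81 on
  every platform.

No multiple-testing correction is applied: the screen is a raw threshold
on a handful of genomes, intended to generate hypotheses, not to control
a genome-wide error rate.

## The pattern-enumeration oracle

`enumerate_patterns(y, max_count)` tabulates the statistic over every
abundance vector in $\{0, \dots, \texttt{max\_count}\}^n$ (guarded to
$n \le 8$, `max_count` $\le 4$). It serves two purposes: an independent
check that the screen computes the same value for any pan-matrix row, and
a way to invert printed correlations back to candidate abundance patterns.
Against $(10,9,9,5,4,3)$ exactly one binary pattern rounds to 0.97
— presence in the three most tolerant strains — and exactly one rounds
to 0.81. Pearson antisymmetry under complementation
($r(\mathbf{1}-x, y) = -r(x, y)$ for binary $x$) holds across the table.

## ORF prediction

The ORF caller is deliberately minimal and fully deterministic: in each of
the six frames, every maximal stop-to-stop interval contributes at most one
ORF, from the first start codon after the previous stop to the next stop.
Defaults: `ATG` starts (GTG/TTG can be enabled), standard genetic code,
100-residue minimum, terminal stop required. Coordinates are 1-based,
inclusive, always on the forward strand (GFF3 convention), with the stop
codon included, so the protein has $(end - start + 1)/3 - 1$ residues.
Ambiguity codes are rejected rather than skipped — the intended inputs are
clean assemblies or synthetic contigs, and silent skipping hides bugs.
Pipelines that already have gene calls can supply per-strain protein FASTA
(`mode = "proteins"`) and bypass this stage.

## Clustering

Pairwise protein distances are
$d(a,b) = 1 - 2S(a,b)/(S(a,a) + S(b,b))$, where $S$ is the Smith–Waterman
local alignment score under BLOSUM62 with affine gap penalties 11/1 (a gap
of length $L$ costs $11 + L$), clamped at 0 when no positive-scoring local
alignment exists. The distance is 0 for identical sequences and 1 for
unalignable ones. Alignment is delegated to `Biostrings::pairwiseAlignment()`;
the test suite pins its scores to an independently written brute-force
dynamic-programming oracle on hundreds of random short pairs.

Families are the connected components of the graph joining pairs with
$d < 0.75$ (strict inequality, so `threshold = 1` cleanly merges every
connected pair) — equivalently, the single-linkage dendrogram cut at 0.75.
The threshold is the documented default of the pan-genomics clustering
tool this stage is modelled on. Cluster labels `Cluster_1, Cluster_2, ...`
are assigned by ascending order of each cluster's lexicographically
smallest member id, making the output invariant under permutation of the
input — necessary because any serial numbering from a particular run order
would be irreproducible.

An optional k-mer prefilter (default $k = 4$) assigns $d = 1$ without
alignment to pairs sharing no k-mer. At 5% within-family divergence a
related pair shares many 4-mers, so the prefilter only skips pairs far
above the threshold; the tests assert both paths give identical partitions.

## The synthetic-genome generator

`generate_dataset()` emulates the *input side* of a multi-genome screen:
six strains whose phenotype vector is $(10, 9, 9, 5, 4, 3)$, each genome a
single contig carrying mutated copies of family prototypes separated by
spacer DNA. Defaults, chosen once as the study conditions:

| parameter | default | why |
|---|---|---|
| strains / phenotype | 6 strains, (10, 9, 9, 5, 4, 3) % w/v | the panel the screen is designed around |
| planted families | 5: patterns (1,1,1,0,0,0), (1,1,1,1,0,0), (1,1,2,0,0,0), (0,0,0,1,1,1), (1,1,1,1,1,1) | cover a strong positive, a moderate positive, a copy-number signal, a negative control and an undefined core row |
| background families | 30, counts iid on {0,1,2} | desk-scale filler; resampled until \|r\| ≤ 0.8 so the background is phenotype-unassociated by construction ("unrelated") |
| protein length | 120 residues | above the 100-residue ORF floor with margin |
| substitution rate | 0.05 per residue per copy | within-family distance ≪ 0.75 threshold; between random families ≈ 1 |
| spacer | ≥ 60 nt, TTAA tiles + 30-nt random stretches | see below |

Two constructions make recovery *exactly countable* rather than merely
likely:

* **Spacers.** The 12-nt tile `TTAATTAATTAA` is its own reverse
  complement, contains no G (hence no ATG on either strand), and places a
  stop codon in all six frames within 12 nt. Spacers start and end on a
  tile and alternate tiles with 30-nt random stretches, so no reading
  frame can cross a spacer for more than ~14 codons and every planted gene
  occupies its own stop-to-stop interval with its own ATG as the first
  start.
* **Codon sampling with rejection.** Codons are drawn uniformly from each
  residue's synonymous set (seeded, hence reproducible). A fixed
  one-codon-per-residue table is *not* used for genome synthesis: any such
  table skews off-frame codon statistics, and the lexicographic-minimum
  table in particular places no T in third codon positions, leaving one
  shifted reading frame of every gene structurally stop-free — long
  spurious ORFs overlapping every planted gene. Even with uniform codons a
  rare gene can leave a long stop-free stretch in one of its five
  non-coding frames, so each candidate CDS is checked (flanked by one
  spacer tile per side, which is exactly its contig context) and
  resampled with the next derived seed until the only ORF of ≥ 50 residues
  it contains is the gene itself. The check is deterministic and bounded.
* **Mutation.** Copies are diverged by `mutate_protein()` at 5% per
  residue; the initial Met of each copy is kept fixed, since a substituted
  start residue would remove the ATG and make the copy unrecoverable by
  construction rather than by biology.

All randomness flows from the single config seed through a fixed integer
recurrence, so identical configurations give byte-identical FASTA output.

The generator's truth ledger records each family's copy-count vector, its
expected co-occurrence *computed with the same statistic the screen uses*
(oracle consistency), and the exact contig coordinates of every embedded
gene, so tests can trace cluster → member ORFs → coordinates → family.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: realistic GC content and codon usage,
multi-contig draft assemblies (single contig per genome by default),
pseudogenes, mobile elements and horizontal transfer, overlapping genes
and antisense ORFs (real genomes have them; the generator deliberately
excludes them so recovery is countable), and any phylogenetic structure in
the background families. On real assemblies the screen inherits the usual
caveats of pan-GWAS without tree correction: phenotype-correlated clades
produce correlated families that are not causal.

## The pipeline and its file contracts

`run_pipeline()` chains the stages and writes every intermediate: per-strain
genome FASTA (simulate mode), protein FASTA + GFF3 per strain, the cluster
TSV (`orf_id`, `cluster_id`), the pan-matrix TSV, the results TSV
(`cluster_id`, `cooccurrence` at 2 decimals, `n_members`, `annotation`),
the undefined-rows TSV, and a JSON manifest with package version,
parameters, seed, input MD5 checksums and per-stage record counts. Logging
goes to standard error; results never interleave with logs. Re-running an
identical configuration reproduces identical result files.

Functional annotation is a join against a user-supplied
`cluster_id → annotation` TSV (`join_annotations()`), defaulting to
"hypothetical protein"; searching an external protein database is out of
scope for the package.

```{r pipeline}
run <- run_pipeline(pipeline_config(mode = "simulate",
                                    out_dir = tempfile("pancooc"),
                                    seed = 1L), quiet = TRUE)
run$screen
```

The three passing families are exactly the planted patterns with expected
co-occurrence above 0.8; the negative-control family (−0.97) is reported
with its sign but does not pass (an `absolute = TRUE` switch admits
negative exceedances), and the core family lands in the undefined side
channel.

## Problem sizes and numerical choices

The default simulated screen — 6 genomes, 35 families, ~150 ORFs of 120
residues, ~12,000 pairwise alignments with the prefilter — runs in a few
seconds on one CPU; module-level tests use a reduced configuration
(60-residue proteins, fewer background families) for speed. Degenerate
inputs are hard errors with named stages: a constant phenotype (every
correlation undefined) is rejected at load; families with all-zero counts
and duplicate strain or sequence ids are configuration errors; an ORF
mapped to a strain missing from the phenotype table aborts the pan-matrix
stage.

Applying the pipeline to real assemblies (the intended six-strain panel
or any comparable set) is supported through `mode = "genomes"` with
downloaded FASTA files and the phenotype TSV shipped under
`inst/extdata/phenotype_six_strains.tsv`. Reproducing a published cluster
table from public assemblies additionally depends on the original study's
(unstated) gene caller and clustering parameters, so equality with any
specific published list is not asserted by the test suite; the synthetic
ground-truth recovery tests stand in for it.
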