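---
title: "Methods: chromatin-context analysis of CRISPR off-target editing"
author: "chromoff package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-context analysis of CRISPR off-target editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoff)
library(dplyr)
```

## The problem and the study design

Whether a CRISPR nuclease or base editor edits a given locus depends on two
things that are hard to disentangle: the local DNA sequence (how well it
matches the sgRNA) and the local chromatin context (whether the editing
machinery can reach it). Observing editing at differently-sequenced loci in
differently-packaged chromatin confounds the two.

The design implemented here breaks the confound with the genome's own
redundancy. Repeat-rich genomes contain families of near-identical short
sequences scattered across many loci. If an sgRNA targets one member of such
a family, every sequence-similar locus is a *potential off-target site*.
Crucially, many of those sites are exactly sequence-identical to each other
while sitting in different chromatin neighbourhoods. Grouping
sequence-identical sites into an *off-target type* holds sequence constant
within the group: any difference in editing between members of one type must
come from something other than sequence — in particular, chromatin context.

The package implements the full computational side of such a study:

1. **Candidate scan** (`scan_pam_sites()`, `apply_filters()`,
   `rank_candidates()`): find protospacer+PAM loci whose off-target pools are
   large enough to power the per-type comparison.
2. **Off-target enumeration** (`enumerate_offtargets()`, `assign_types()`,
   `flag_callable()`): list every locus within a Hamming-distance budget of
   the target, group sequence-identical loci into types, and mark loci whose
   sequence context is unique enough for short-read variant calling.
3. **Edit extraction** (`load_filtered_variants()`,
   `assign_edits_to_sites()`, `summarize_edits()`): turn somatic-style
   variant calls into per-site edit calls and characterisation statistics.
4. **Chromatin scoring** (`score_sites()` and friends): thirteen
   chromatin-context features per site over a 50-bp window.
5. **Association screen** (`test_type_feature()`, `screen_types()`,
   `summarize_influence()`): per-type Wilcoxon comparisons of each feature
   between edited and unedited sites.
6. **Prediction model** (`encode_features()`, `train_offtarget_model()`,
   `evaluate_model()`): a 75-feature tree-ensemble classifier of editing.
7. **Synthetic data** (`sim_config()`, `simulate_offtarget_study()`): a
   seeded generator of toy studies with known ground truth.

Variant calling itself, read alignment, and signal-track generation are
upstream of this package: it consumes their standard outputs (VCF, bedGraph,
FASTA, BED, gene score tables).

## The candidate scan

`scan_pam_sites()` reports every position on both strands where a 20-nt
protospacer sits immediately 5' of a PAM-matching 3-mer (IUPAC patterns
supported; `NGG` default). Reverse-strand candidates are reported in genomic
coordinates with sequences in targeted-strand orientation; all coordinates in
the package are 0-based half-open (BED convention). Windows containing `N`
are discarded at scan time as uncallable sequence.

`apply_filters()` then applies seven further steps (the scan itself being
step 1). Their semantics, and the choices made where a rule has more than
one reading:

* **GC bound** — pass when `gc_min <= GC < gc_max` on the 20-mer, defaults
  0.40 and 0.80. The inclusive lower bound is chosen so a GC of exactly 40%
  passes; both bounds are configurable.
* **Soft-masking** — a candidate is rejected only when *all 23* bases are
  lowercase in the source FASTA; partially masked candidates pass. FASTA
  input goes through a case-preserving reader (`read_genome()`) for exactly
  this reason.
* **Perfect copies** — reject when any single chromosome carries more than
  `max_perfect_copies_per_chrom` (default 14) exact copies of the 23-mer,
  counting both strands and the candidate itself as one of its own copies.
* **Gene exclusion** — reject candidates whose protospacer interval overlaps
  a user-supplied BED of intervals (intended for lethal and cell-cycle
  genes). The package never fetches gene lists; they are an input.
* **Simple repeats** — reject protospacers containing a run of four
  identical bases or three consecutive tandem copies of any 2-mer or 3-mer
  unit.
* **Editing window** — require at least one `A` and at least one `C` inside
  the window (default protospacer positions 4–8; start and width are
  parameters, as different base editors have different active windows).
* **Pool size** — require strictly more than `min_offtarget_pool` (default
  5000) potential off-target sites.

Each rejected candidate records the *first* failing step in its
`filter_trace`, following the printed step order, though the surviving set
is order-independent (every filter is a pure predicate). Survivors are
ranked by callable pool size with a deterministic `(chrom, start, strand)`
tie-break.

## Enumeration, types, and callability

A potential off-target site is any genomic 23-mer window (both strands)
within `max_mismatches` (default 9) Hamming distance of the target's full
protospacer+PAM sequence — mismatches in the PAM count like any other
position, which is what lets the analysis quantify PAM-relaxed ("non-NGG")
editing. The implementation is a direct vectorised comparison at every
window, so it is exhaustive by construction; the test suite cross-checks it
site-for-site against an independent `Biostrings::matchPattern()` oracle on
seeded random genomes. Windows containing `N` are excluded. A site's
`pam_class` is `NGG` exactly when its last two bases are `GG`.

Types are the partition of sites by exact sequence, with ids assigned in
lexicographic sequence order so they are deterministic for a given site set.

*Callability* is a property the study needs but that has no single standard
definition: a site's edits can only be confidently assigned if short reads
covering it map uniquely. The package operationalises this as exact-match
uniqueness of the site plus `flank` bp of context on each side (default 27,
i.e. a 77-bp context, comparable to a short-read footprint) across both
strands of the genome; sites too close to a contig edge for full flanks are
not callable. The flank width is a parameter, and the definition is
deliberately conservative and sequence-only — it does not model mappability
tracks or paired-end rescue.

## Edit extraction

`load_filtered_variants()` consumes tumor–normal style VCFs (edited sample
vs unedited control) that have already passed a somatic caller's filters. It
keeps `FILTER == PASS` records, splits multi-allelic records per ALT, and
then *re-applies* two defensive thresholds matching common somatic
post-filtering: tumor allele fraction at least `min_allele_fraction`
(default 0.01) and no more than `max_events_in_region` (default 5) records
in any `region_window` (default 50 bp) window — windows that exceed it have
all their records dropped, since dense clusters are characteristic of
alignment artefacts. The window width is a package choice (the upstream
tool's internal region concept is not re-specified here) and is
configurable.

`classify_variant()` classifies any length-preserving substitution as an
SNV and decomposes it into per-position base changes; this covers the
homopolymer-run records (`AA>GG`, `CCC>TTT`, and reverse complements) that
callers sometimes emit as multi-base events even though each position is a
single-nucleotide change. Length-changing variants are InDels.
From/To bases are always reported on the reference genome strand.

A variant is assigned to every enumerated site whose 23-mer window contains
its position (optionally the full 50-bp context window instead — off by
default, since flank edits are not unambiguously attributable to the site).
Sites with zero mismatches and an NGG PAM are the on-target loci; their
calls are labelled and excluded from all off-target tallies. A site is
*edited* if it has at least one assigned call in a sample; replicate merging
is the union of edited flags with per-replicate provenance kept.

`summarize_edits()` computes the per-editor characterisation set: off-target
edit/site/type counts, the 4×4 From→To matrix over SNV base changes, the
per-PAM-class editing frequency (edited / potential sites, as a percent
rounded half-up to two decimals — base R's banker's rounding would change
printed values like 65.63), the mismatch-count histogram, and the
per-position mismatch profile of edited sites. `edited_set_overlap()` gives
the pairwise Venn-style comparison across editors.

## Chromatin features

Thirteen features are scored per site over a 50-bp window: the 23-bp site
plus 15 bp upstream and 12 bp downstream. The window is strand-aware by
default (upstream means 5' of protospacer position 1), with a
`strand_aware = FALSE` switch since a purely positional convention is also
defensible; the choice is recorded in the output's metadata attribute.

* Eleven interval-signal features (four histone marks, ATAC, DNase, RNAP2,
  and four TF/cofactor occupancies) are the coverage-weighted mean of
  bedGraph values over the window. Uncovered bases count as signal 0 by
  default (the bedGraph convention that absence means zero); an
  `exclude-uncovered` mode divides by covered bases only, because some
  fold-change tracks omit unenriched regions rather than reporting zero.
* DNA methylation is the *count* of methylation-site records inside the
  window (half-open: a record at `win_start` counts, one at `win_end` does
  not).
* Expression (FPKM) is the mean score of genes whose interval overlaps the
  window, with `max` and `sum` as alternative aggregations for multi-gene
  windows; no overlapping gene scores 0.

A feature whose track is not supplied is *absent* from the output, never
silently zero — downstream encoding fails loudly unless zero-imputation is
requested explicitly.

## The association screen

Within one type, sequence is constant, so comparing a chromatin feature
between edited and unedited members is a clean two-group location test. The
package uses the two-sided Wilcoxon rank-sum test:

* For combined sample sizes up to `exact_max_n` (default 25) the p-value is
  computed from the exact permutation distribution of the rank sum via a
  subset-sum dynamic program over doubled midranks. This handles ties
  exactly — the p-value is the probability, over all equally-likely
  assignments of the observed values to groups, of a rank-sum deviation at
  least as large as observed. The suite verifies equality with a brute-force
  permutation oracle (within 1e-9) on small inputs with and without ties.
* Above that, the normal approximation with tie correction and continuity
  correction is used, matching the classical large-sample test. All
  observations identical in both groups gives p = 1.

Direction is the sign of the median difference (edited minus unedited),
falling back to the mean difference when medians tie and to a flagged
`positive` when both are zero. Median is the primary definition because the
test itself is rank-based; the fallback chain is recorded in the result's
`note` column.

`screen_types()` tests every feature in every type with at least
`min_edits` (default 10) edited sites and at least one unedited site — a
comparison needs two groups, so fully-edited types are reported as untested
rather than silently dropped. Significance is called on the **raw** p-value
at `alpha = 0.05` and a type is "influenced" when any feature is
significant; this deliberately applies no multiple-testing correction so
that influenced-type fractions are comparable with raw-threshold screens,
and a Benjamini–Hochberg `bh_q` column is emitted alongside for readers who
want it. The direction map in `summarize_influence()` restricts to types
with at least 50 edited sites (default), a reporting filter that reduces
sampling noise in per-type directions.

## The prediction model

`encode_features()` produces a fixed, versioned 75-feature vector per site:
a 62-feature sequence block and the 13 chromatin scores. The sequence block
covers total mismatch count; per-position mismatch indicators (23);
transition/transversion counts; a 3-way PAM one-hot (NGG, NAG/NGA-like,
other); the 12 ordered target→site substitution counts; site GC;
min/max/mean mismatch position; seed-region (positions 11–20) and PAM-region
(21–23) mismatch counts; maximum homopolymer run; CpG count; editing-window
A and C counts; a distance-weighted mismatch score (sum of 1/position); and
ten reserved zero-filled slots that version the layout. The exact
composition of a "sequence-derived feature" set is a design choice; this
layout is a documented contract (encoding version stamped on the output),
not a claim that it is the only reasonable one.

The data are split 80/20 stratified by label with the training size exactly
`round(0.8 n)`; the seed is recorded. `train_offtarget_model()`
grid-searches hyperparameters on a stratified validation fold carved from
the training data (default 25%), picks the highest validation accuracy with
ties broken by grid order, and refits on the full training set. The
reference grid (`model_grid("full")`) spans estimators
{50, 100, 150, 200, 250, 500}, depth {3, 5, 7, 9, 12, 15}, learning rate
{0.001, 0.01, 0.05, 0.1, 0.2}, subsample {0.6, 0.8, 1.0} and column
subsample {0.6, 0.8, 1.0} — 1620 combinations; a small `"fast"` grid is the
default for interactive use. The primary backend is gradient-boosted trees,
because learning-rate and column-subsampling parameters belong to boosting;
a random-forest backend is available behind the same interface with the
grid restricted to its applicable parameters. Class imbalance (unedited
sites usually dominate) is left unresampled by default and the balance is
recorded on the model object.

`evaluate_model()` reports accuracy (percent, half-up to two decimals), the
ROC curve and AUC, and normalised feature importances (gain for boosting,
Gini decrease for forests) with the summed importance of the 13-feature
chromatin block alongside — individually modest chromatin features can still
carry substantial aggregate weight. A one-class test set yields a defined
accuracy but `NA` AUC.

## The synthetic-data generator

`simulate_offtarget_study()` builds a complete toy study, deterministic
under its seed:

* **Genome** — a random background (single chromosome) with planted repeat
  families. Each family is one scan-eligible target sequence (drawn to pass
  the GC, repeat, and editing-window filters, with an NGG PAM) whose planted
  sites are grouped into types: distinct variant sequences at configured
  mismatch distances, each planted in several sequence-identical copies at
  separate loci on random strands. This reproduces the structure the whole
  analysis relies on — sequence-identical sites in different contexts.
  With `flank_uniqueness` the generator verifies every planted context is
  globally unique (re-randomising flanks on collision), so callability
  ground truth is exact.
* **Tracks** — per-site feature values drawn from a per-feature
  `baseline + sd · z` model and materialised as valid bedGraph / point /
  gene-table files whose intervals exactly cover each site's 50-bp window,
  so the scoring functions recover the drawn values exactly and file
  round-trips are lossless.
* **Edits** — per-site editing probability
  `plogis(intercept + b_mm · mismatches + Σ b_f · z_f)` over standardised
  feature values, realised independently per replicate, and emitted as
  tumor–normal VCFs with editor-signature substitutions (CBE: C→T on the
  targeted strand; ABE: A→G; or unbiased) and allele fractions ≥ 0.01.
  The logistic form is the minimal generative mechanism consistent with
  accessibility raising, and mismatch burden lowering, editing odds; its
  coefficients are user-set simulation knobs, not estimates of any editor's
  biology.

What the generator does *not* emulate: read-level noise (no FASTQ, no
mapping bias, no sequencing error), background mutation processes,
correlated chromatin features, indel-type edits (simulated edits are SNVs),
or bulge/non-Hamming off-target geometry. Passing tests on simulated data
therefore demonstrate correctness of the pipeline's bookkeeping and
statistics under a known model, not performance on real WGS data.

## Problem sizes, numerical choices, and defaults

The test suite and the acceptance script run everything at desk scale,
chosen to exercise each code path with comfortable statistical power:
enumeration exactness on twenty 6-kb seeded genomes; Wilcoxon exactness on
all-ties and continuous inputs with combined n ≤ 12 plus a 1000-type null
calibration (15 vs 20 sites per type); association recovery on simulated
studies of one 200-site family in a 40-kb genome (five types of 40 copies,
DNase log-odds +2 per SD); and model runs on two 300-site families in a
150-kb genome (~800 encoded sites per run, 80/20 split, 100 trees of depth
5). Enumeration at these scales also sweeps up a modest number of
background loci at 8–9 mismatches, which join the pools as unedited
singleton types — exactly as they would in a real genome.

Other numerical choices: percentages print half-up at two decimals;
exact-mode Wilcoxon uses an 1e-9 deviation guard against floating-point
ties; ranking and type ids break ties lexicographically so every output is
reproducible bit-for-bit under a fixed seed; the boosting backend runs
single-threaded by default so fits are deterministic.

## Known limitations

* The scan's pool computation enumerates per candidate and is meant for
  toy/simulated genomes; chromosome-scale scans would want a seed-and-verify
  index, which the enumeration contract (exactness vs brute force) leaves
  room for.
* Callability is a sequence-uniqueness proxy; it does not consume mappability
  tracks.
* The association screen is correlational by design — it inherits the
  study's own caveat that chromatin state, repair, and regional genomic
  features are entangled.
* Off-target geometry is Hamming-only: no DNA/RNA bulges, no PAM-distal
  truncation models.
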