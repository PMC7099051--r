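---
title: "Locus and sample QC for target-capture phylogenomics: methods and design"
author: "hybQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus and sample QC for target-capture phylogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybQC)
```

## The problem

Hyb-Seq studies — target capture of a few hundred nuclear loci combined
with genome skimming — increasingly rely on herbarium specimens, whose DNA
is fragmented and unevenly recovered. Between read assembly and
phylogenetic inference sits a chain of quality-control decisions: which
samples carry enough sequence to be worth keeping, how aggressively to trim
gap-rich alignment columns, and which gene trees are reliable enough for
downstream species-tree and divergence-time analyses. Each decision is
simple, but their interaction determines the final data matrix, and ad hoc
scripts make them hard to audit. hybQC implements this QC chain as tested,
deterministic functions with one orchestrating pipeline, plus a synthetic
data generator that plants known defects so every stage can be checked
against ground truth.

## Alignment statistics

A column is **parsimony-informative** when, counting only unambiguous
states (A, C, G, T), at least two distinct states each occur in at least
two sequences. `alignmentSummary()` reports the count (`n_pic`) and the
proportion over all columns, `p_pic` (the quantity written P_PIC below),
along with variable-column counts and the missing-data fraction.

Two conventions needed fixing:

* **Missing characters** are `-`, `?` and `N`. IUPAC partial ambiguities
  (R, Y, S, W, ...) are *not* missing under the default, but they never
  count as states either; `ambiguousAsMissing = TRUE` switches to the wider
  convention. Keeping the two metrics decoupled means a trimming decision
  driven by P_PIC is not silently entangled with how ambiguities are
  booked.
* **Standard deviations** in `summarizeAlignments()` are sample (n-1) SDs,
  the convention of the usual alignment summary tools; single-locus classes
  report SD 0 and carry a `single_member` flag.

## Gap-threshold trimming and its optimization

`trimAtThreshold(aln, gt)` keeps exactly the columns whose fraction of
non-gap characters is at least `gt` (gap is `-`; `?` and `N` count as
present). This is the conventional gap-threshold semantics of column-based
trimmers. Threshold comparisons use a 1e-9 slack so that a column sitting
exactly on the threshold (for example non-gap fraction 0.7 against
gt = 0.7 computed in floating point) is kept.

`optimizeTrim()` sweeps a threshold grid (default 0, 0.1, ..., 1), scores
every trimmed alignment by P_PIC, and selects, among thresholds whose
**data loss** does not exceed 30%, the one maximizing P_PIC:

* Data loss is residue-based by default: one minus the ratio of non-gap
  residues retained. The trimming literature speaks of retaining adequate
  *sequence length*, which is a statement about residues, not columns; a
  column-based metric is available via `lossMetric = "columns"`.
* Ties break toward the **lowest** threshold — when two thresholds achieve
  the same informativeness, keep more sequence.
* A locus is discarded when no threshold keeps data loss within bounds
  *or* when the best attainable P_PIC is 0 (no signal worth keeping).
* The full per-threshold curve is always returned, so a discarded locus
  can be audited.

Because a column's informativeness does not depend on which other columns
survive, the sweep is computed from one pass of per-column statistics; an
independent brute-force re-evaluation lives in the test suite and must
agree with the optimized path on random inputs.

## Recovery scoring

`captureSuccess(recovered, target)` is the proportion of the reference
length recovered, capped at 1 (over-assembly warns). The composite
**coverage score** of an accession over m loci multiplies three components:

* representativeness `r` — fraction of loci with any sequence;
* completeness `c` — mean capture success over the *recovered* loci only.
  Absence is already penalized by `r`; folding it into `c` as well would
  double-count missingness in the product. The alternative total-over-total
  denominator is available via `completenessDenominator = "all"`, since
  published analyses do not always state which convention they used;
* evenness `e` — Pielou evenness, H'/log(m), of the capture-success
  fractions across recovered loci. Evenness is computed on capture
  fractions rather than raw base-pair counts deliberately: an accession
  that fully recovers loci of heterogeneous lengths is perfectly evenly
  recovered relative to its targets, and the score of a complete accession
  must be exactly 1. `e` is 0 when at most one locus is recovered (no
  distribution to speak of), and 1 in the degenerate m = 1 matrix when the
  locus is present.

The default retention cutoff is a score of at least 0.5, applied once,
before any locus-level filtering. `ageEffectReport()` regresses
per-accession mean capture success on collection year (herbarium samples
only, ordinary least squares, p from the F distribution on (1, n-2)
degrees of freedom) and contrasts herbarium against DNA-bank/silica
samples with a Welch t test — the two standard readouts for age-driven
degradation.

## Tree-based locus filters

**Diameter outliers.** The diameter is the maximum leaf-to-leaf path
length. `flagOutlierLeaves()` repeatedly removes the leaf whose removal
shrinks the diameter the most, while the relative increase
(D - D_without)/D_without exceeds 20%. This is a deliberate, literal
simplification of signature-based tools that test per-species diameter
contributions; the greedy per-leaf loop is transparent, deterministic, and
recovers planted long-branch taxa reliably. Pruning never reduces a tree
below 3 leaves (it stops with a warning instead).

**Low-support contraction.** Internal edges with support *less than or
equal to* 10 are contracted into polytomies — inclusive, matching the
conventional `i & b <= 10` filter expression rather than the looser prose
"below 10%". Contraction splices the child node out and adds the removed
edge's length to the child edges, so tip depths (and hence root-to-tip
statistics computed later) are preserved. Edges with absent or non-numeric
support labels are *retained*: unknown support is not evidence of low
support. The operation is idempotent and never changes the leaf set.

**Clock statistics and locus selection.** For each gene tree,
`clockStats()` reports the sample variance of root-to-tip path lengths,
the tree length, the taxon count, and concordance with a species tree: the
fraction of the species tree's internal bipartitions — after pruning it to
the taxa shared with the gene tree — that occur in the gene tree.
`selectClockLoci()` keeps loci satisfying all four of: concordance > 0.1,
root-to-tip variance < 0.024, tree length > 0.1, and at least 25 taxa. The
inequalities are strict exactly as conventionally printed (a locus at
variance 0.024 is rejected). Two conventions are configurable because the
0.024 threshold is used in the field without stating them: rooting is
midpoint by default (outgroup rooting, or the tree's own rooting via
`rooting = "given"`, are available), and the variance is the sample (n-1)
variance.

**Concordance accounting.** `concordancePies()` classifies every gene tree
against every internal species-tree bipartition as concordant (the
bipartition, restricted to shared taxa with at least two on each side,
occurs in the gene tree), conflicting (the gene tree contains an
incompatible bipartition on the same restricted taxon set), or
uninformative (anything else — missing taxa or unresolved polytomies).
Unresolved regions are counted as uninformative, not conflicting: a
polytomy is consistent with the bipartition, it just fails to support it.

## The synthetic generator

`simulateDataset()` produces datasets with the statistical structure the
pipeline assumes, with all planted defects recorded in a truth slot:

* a pure-birth species tree scaled to a root-to-tip depth of 0.35
  substitutions/site — deep enough that the absolute clock thresholds
  (variance 0.024, length 0.1) operate in a sensible regime;
* per-locus gene trees that copy the species tree with per-branch
  lognormal rate multipliers. Multipliers are **median-preserving**
  (meanlog 0): clock-like loci use sdlog 0.05 (root-to-tip variance around
  1e-4), planted violators sdlog 1.5, which puts essentially all of them
  above the 0.024 rejection threshold. A mean-preserving parameterization
  was rejected during design because increasing its spread shrinks the
  median branch and can *reduce* depth variance;
* rogue taxa whose terminal branches are set to 10 times the gene tree's
  mean terminal branch length, emulating contaminant or paralogous
  sequence with a deterministic detectability margin;
* bootstrap-style support labels on internal edges (Beta-distributed, mean
  about 83, occasionally at or below the contraction cutoff);
* sequences evolved under the simplest equal-rates substitution model
  along each gene tree — realism beyond what the QC statistics exercise
  (no indel process, no codon structure, no rate-across-sites variation)
  is out of scope;
* an age-dependent recovery process: a herbarium accession collected in
  year y has expected recovered fraction 0.55 + 0.002 (y - 1850), with
  Beta-distributed accession- and locus-level noise; DNA-bank/silica
  samples sit at 0.85 with little noise. Recovered fragments shorter than
  50 bp count as unrecovered. The recovery fraction drives both the
  recovery table and the alignment masking (one contiguous retained window
  per cell, plus a configurable fraction of gap-rich columns).

The recovery defaults emulate the *retained cohort* of a typical
herbariomic study — the accessions that survive the coverage cutoff — so
that the downstream stages (including the 25-taxon clock criterion)
operate in a non-degenerate regime; the heavily degraded raw-cohort regime
(herbarium capture success centred near 28%) is reachable by lowering
`fragBase`. The noise scale was chosen so the age effect is weak
(population R-squared roughly 0.1-0.2) yet its sign is recoverable with
p < 0.05 in the large majority of replicates at 60 accessions.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: alignment error (sequences are evolved
on the true tree, so gene-tree discordance beyond planted noise is
absent), paralogy and allelic variation, indels (gaps arise only from
masking), GC or rate heterogeneity across sites, and read-level artifacts.
The generator validates the *bookkeeping and decision rules* of the
pipeline, not the biological realism of any particular threshold.

Determinism is a contract: one integer seed governs every draw, the same
spec and seed reproduce byte-identical datasets, and recovery and trees are
drawn before sequences so skipping sequence simulation
(`alignments = FALSE`) leaves them unchanged.

## The pipeline

`runQC()` chains the stages in the order used in practice: accession
coverage filtering (once, before any locus work) → trimming optimization
with locus discard → alignment summaries → outlier-leaf pruning →
low-support contraction → clock statistics and locus selection →
per-bipartition concordance. Taxa pruned as outliers are removed from the
trimmed alignments rather than triggering realignment — realignment is an
external-tool step outside this package's scope, and the divergence is
deliberate and documented here. Reports are plain data frames; when an
output directory is given, tables are written with fixed formatting so
identical inputs produce byte-identical files.

## Numerical and degenerate-input choices

* Alignment columns are 0-based half-open internally (matrix indexing);
  all reported positions are 1-based inclusive.
* Threshold and loss comparisons carry a 1e-9 slack toward keeping data.
* Zero-length or empty alignments summarize to zeros and are flagged
  degenerate; an all-gap original makes data loss undefined (error).
* A gene tree sharing fewer than 2 taxa with the species tree makes
  concordance undefined (error); fewer than 4 shared taxa yields no
  internal bipartitions and concordance NA.
* Coverage scoring of an empty matrix returns an empty frame; the one-locus
  matrix defines evenness 1 when that locus is recovered.

## Problem sizes used in the test suite

The suite exercises two standard sizes: small (8 taxa x 12 loci) for
fast unit and pipeline tests, and medium (40 taxa x 150 loci) for the
end-to-end determinism and truth-recovery checks. Property checks run 100-200
randomized replicates against brute-force re-implementations; the
clock-filter recovery check aggregates 50 simulated datasets at the medium
size. These sizes were chosen to exercise every code path at comfortable
desk scale.

## Known limitations

* The outlier rule is per-leaf and greedy; correlated outliers (two rogue
  sisters) can mask each other in ways the per-species signature test of
  dedicated tools would catch.
* Concordance treats bipartitions as unweighted; no account is taken of
  support values when counting conflict.
* The trimming optimizer scores thresholds only by P_PIC; other signal
  measures (site rates, likelihood-based informativeness) are out of
  scope.
* Published composite-score counts from real studies may not be exactly
  reproducible because the original completeness and evenness conventions
  are not always stated; both implemented variants should be reported when
  they disagree.
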