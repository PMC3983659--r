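---
title: "Promoter signatures as tissue-specific enhancer predictors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter signatures as tissue-specific enhancer predictors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Tissue-specific transcription is driven both by proximal promoters and by
distal enhancers, and the two classes of elements recruit overlapping sets
of transcription factors (TFs). `promsig` operationalizes that observation
as a supervised learning problem:

1. For a tissue, take the promoters (−2.5 kb … +0.5 kb around the TSS) of
   the 200 most highly and the 200 least expressed genes.
2. Within each promoter, extract the conserved non-coding elements (CNEs):
   maximal runs of cross-species alignment blocks with ≥ 70% identity,
   merged and length-filtered (default ≥ 100 bp).
3. Represent every CNE as a vector of TF binding-site occurrence counts
   over a motif library, counted by PWM scanning at an exact per-position
   p-value threshold.
4. Train a class-weighted linear SVM to separate high-promoter CNEs (+1)
   from low-promoter CNEs (−1), with a *consistent positive set* step that
   prunes heterogeneous positives.
5. Apply the model to distal CNEs (or promoter-free sliding windows) across
   the genome; call a candidate an enhancer prediction when its decision
   score exceeds `s = min(0, δ)`, where δ is the lowest score of the top 5%
   of candidates in the control (lowly-expressed-gene) loci.
6. Evaluate predictions at locus level: ratio-of-proportions fold
   enrichment, fraction-of-loci fold, score-shift tests, and overlap with
   external mark sets via length-matched randomization.

The linear SVM solves the usual soft-margin primal
min ½‖w‖² + C Σᵢ cᵢ ξᵢ with per-class error weights: cᵢ = w₁ for positive
samples and 1 for negatives. The solver behind `train_svm()` is libsvm
(through e1071); everything specific to this method — the C heuristic, the
w₁ grid, the consistent-set loop, weight scaling, the δ threshold — is
implemented in this package.

## Coordinates and interval algebra

All coordinates are 0-based, half-open (the BED convention), including the
TSS. Intervals are plain data frames; the exact tiling and merging
semantics matter here (loci must tile chromosomes exactly, abutting
conserved blocks must merge, 1-bp abutment must *not* count as overlap),
so these operations are implemented directly and tested against per-base
bitmask oracles rather than adapted from a 1-based container.

Locus definition follows the "closest half of the intergenic sequence"
rule: overlapping transcripts (strand ignored) are clustered by single
linkage; each gap between adjacent clusters is split at
`floor((end_left + start_right) / 2)`, with the floor assigned to the left
locus. The floor rule is arbitrary but deterministic and keeps the tiling
exact; chromosome ends go to the terminal loci.

Promoters span 2.5 kb upstream and 0.5 kb downstream of the TSS,
strand-aware and clipped at chromosome ends. Both lengths are arguments of
`promoter_regions()`.

## Motif scanning and its calibration

Count matrices (JASPAR, TRANSFAC dialects) become probability matrices
with a pseudocount of 0.25 per cell — symmetric Laplace smoothing that
avoids −∞ log-odds. MEME-format probabilities are taken as-is. Scores are
log₂(p/bg) ("bits") against a 0-order background; by default the
background is estimated from the scanned sequence set itself, with the
uniform model as fallback.

A scan hit is a window (either strand) whose score has an exact background
tail probability ≤ 10⁻⁴. The null distribution of each motif's score is
computed exactly by position-wise convolution over a discretized score
grid (bin width 10⁻³ bits), the same construction used by standard motif
scanners; for motif lengths ≤ 6 the test suite checks it against full
k-mer enumeration. Overlapping hits are all counted and windows containing
N are skipped. Counting every overlapping hit (rather than one best hit
per region) is the simpler rule and is exposed as the only mode.

## Classifier details

**C heuristic.** `estimate_cost()` returns `C = 1 / meanᵢ‖xᵢ‖²`, the
standard scale-normalizing choice (doubling all feature vectors divides C
by 4); it is overridable via `train_config(C_override=)`.

**Class weight.** `w₁ = (n⁻/n⁺)·γ`, γ from {1/3, 2/3, 1, 4/3, 5/3}:
class-balancing times γ, so γ = 1 recovers the balanced classifier. The
fraction direction can be flipped in `train_config()`.

**Consistent positive set.** For every positive promoter P in a training
fold, a model is trained on the fold *minus* P's elements, P's elements
are scored, and up to two positive-scoring ones (chosen uniformly at
random) represent P. Promoters with fewer than two positive-scoring
elements contribute what they have; none contribute nothing.

**Double-loop cross-validation.** 5 folds × 5 repeats, grouped by
promoter: all CNEs of one promoter share a fold, so held-out promoters are
never visible at training time (grouping is the leakage-free choice of
splitting unit). The consistent set is built once per fold with the
balanced weight (γ = 1); the γ grid is then applied to the final per-fold
classifier — the grid tunes the classifier's class weight, and this
variant keeps the cost linear rather than quintic in the grid size. The
final fold classifier trains on consistent positives plus the
*training*-fold negatives and is evaluated on the held-out fifth of both
classes; a variant that instead trains on the held-out negatives exists
behind `train_config(literal_heldout_negatives = TRUE)`, but the default
never trains on evaluation data. γ is chosen once per tissue as the grid
value maximizing the median AUC over all 25 splits, ties resolved toward
γ = 1 (the least-perturbed weight).

**Weight scaling.** To compare motifs across models, weights map
sign-preservingly into [−1, 1]: positive weights divide by the maximum
positive weight, negative weights map by `−(1 − (w − w_min)/(−w_min))`.
Models with median AUC ≥ 0.6 (inclusive) are labeled reliable.

**Determinism.** All randomness (fold assignment, per-promoter picks,
generator draws) descends from a single integer seed through fixed
congruential substreams below 2³¹; identical seeds give identical reports.

## Prediction thresholding

For each candidate class (conserved elements; windows), control scores are
the scores of candidates lying in the loci of the lowly expressed gene
set. With N controls, `k = max(1, floor(0.05·N))` and δ is the k-th
largest control score; predictions require a score strictly greater than
`s = min(0, δ)`. When δ < 0 (the usual case for a calibrated model) this
admits ≈ 5% of the controls, which is the sense in which the expected
false-positive rate is about 5%; when δ > 0 the cap at 0 deliberately
admits every positive-scoring candidate. Ties at the threshold never pass,
and δ is computed separately per candidate class (conserved elements vs.
windows).

Sliding windows are 230 bp stepped by 115 bp (the mean conserved-block
length and half of it), scored on the + strand only — scanning itself is
double-stranded, so window orientation is immaterial.

## The synthetic study generator

`generate_synthetic()` builds a fully specified study whose structure
matches the conditions above: 200 high and 200 low genes by default, one
gene per 60 kb locus laid end to end (20 loci per chromosome), i.i.d.
background sequence, Poisson(2.4) promoter CNEs with geometric lengths of
mean 249 bp, conservation identity ~ Uniform(0.70, 0.95) (a binary
conserved/not mask with a drawn identity exercises the extraction
threshold without simulating an alignment), two distal truth enhancers per
high locus, and three planted motifs embedded with probability 0.8 per
motif per element — *sampled from the PWM*, not pasted as consensus, so
the scan threshold is genuinely exercised. Planted and decoy PWMs are
sharp (dominant base 0.95), the information content typical of
high-quality vertebrate TF matrices; at the 10⁻⁴ scan threshold a sampled
site is detected ~91% of the time, so positives carry ≈ 2.2 detectable
planted hits on average while background hits stay below one per element.

Two generator choices are not stated in the study conditions and are fixed
here once: every locus receives Poisson(4) *neutral* distal CNEs (without
them the control loci would contain nothing to scan, and neither the δ
threshold nor the fold enrichments would be defined), and the decoy count
defaults to 57. The 57 makes the library 60 motifs, so "the planted motifs
rank in the top 5% of scaled weights" is a property about the top three
positions; with a much smaller library (say 20 decoys) the top-5% band
would hold fewer motifs than are planted and the recovery property would
be unsatisfiable by construction.

The second expression column (`tissue_b`) is a permutation of the focal
column: a model trained against it has no signal, which the null tests
exploit.

What the generator does *not* emulate: CpG islands, TATA boxes, realistic
conservation score distributions, repeat structure, GC heterogeneity along
chromosomes, or overlapping genes. Passing the recovery benchmarks
therefore demonstrates that the pipeline machinery works end to end —
extraction, calibration, training, thresholding, enrichment — not that
real tissues would reach these AUCs; on real data the signal is weaker and
heterogeneous.

## Problem sizes used by the test suite

The bundled checks run the full default conditions (200 + 200 genes,
60-motif library) for five seeds in the recovery suite and ten in the
weight-ranking suite. The null battery (promoter-label permutation, 20
seeds) runs at 60 + 60 genes with single-repeat cross-validation: the
chance level of the AUC is scale-free, and this size keeps the battery a
few minutes long. Locus-shuffle controls reuse one reduced run and
re-randomize only the locus classes.

## Known limitations

* The per-position exact p-value is discretized at 10⁻³ bits; scores
  within one bin of a threshold can flip hit status relative to an
  un-discretized scanner.
* `estimate_cost()` and the w₁ direction are documented renderings of
  ambiguous sources; both are configurable rather than silently fixed.
* Randomized placement in `randomization_pvalue()` does not
  collision-check randomized intervals against each other.
* No motif discovery, no higher-order backgrounds, no kernels, no
  probability calibration, no enhancer→gene assignment beyond locus
  containment.
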