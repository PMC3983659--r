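# promsig

Tissue-specific gene expression is encoded twice over: in proximal
promoters and in distal enhancers that contact them. Because the two
element classes recruit overlapping sets of transcription factors, the
motif content of a tissue's promoters carries information about that
tissue's enhancers. `promsig` turns this into a prediction engine for
regulatory genomicists: it learns a *promoter signature* for a tissue and
then scans the rest of the genome for distal elements carrying the same
signature.

## What it computes

For a tissue *t* with an expression table over genes:

1. **Training set** — promoters (−2.5 kb … +0.5 kb of the TSS) of the 200
   most highly vs. 200 least expressed genes; the conserved non-coding
   elements (CNEs, ≥ 70% cross-species identity) inside them; each CNE
   becomes a vector **x** of motif-occurrence counts over a PWM library,
   counted at an exact per-position p-value ≤ 10⁻⁴ (both strands,
   discretized-convolution null).
2. **Classifier** — a class-weighted linear SVM, `min ½‖w‖² + C Σ cᵢ ξᵢ`
   with `cᵢ = w₁` on the positive class, `C = 1/mean‖xᵢ‖²`, and
   `w₁ = (n⁻/n⁺)·γ` grid-searched over γ ∈ {1/3, 2/3, 1, 4/3, 5/3}. A
   *consistent positive set* (up to two positive-scoring CNEs per
   promoter, scored by leave-one-promoter-out models) prunes heterogeneous
   positives; accuracy is reported as the median AUC of a 5×5 double-loop
   cross-validation grouped by promoter, with models at median AUC ≥ 0.6
   labeled reliable.
3. **Predictions** — distal CNEs (or 230/115-bp sliding windows) scored by
   `f(x) = wᵀx + b`; candidates are called enhancer predictions when
   `f(x) > s = min(0, δ)`, δ being the lowest score of the top 5% of
   candidates in the loci of the lowly expressed genes (expected control
   false-positive rate ≈ 5%).
4. **Evaluation** — locus-level fold enrichments (ratio of proportions and
   fraction-of-loci ratio) with Fisher p-values, rank-sum score shifts,
   motif ranking by sign-preserving weight scaling into [−1, 1], and
   overlap with external mark sets via length-matched randomization.

A fully seeded synthetic-genome generator with planted motifs and truth
enhancers makes the entire pipeline testable end to end without any
external download.

## Worked example

```r
library(promsig)

spec <- synthetic_spec(n_high = 30, n_low = 30, locus_length = 30000,
                       n_decoys = 10, seed = 3)
bundle <- generate_synthetic(spec)
bundle
#> synthetic_bundle: 3 chromosomes, 60 genes, 451 conserved blocks, 60 truth enhancers

trained <- run_train(bundle, n_top = 30, n_bottom = 30,
                     cfg = train_config(repeats = 1, seed = 5))
trained$cv
#> cv_report: median AUC 0.993 (reliable), gamma = 1

ps <- run_scan(bundle, trained$model)
ps
#> prediction_set: 54 predictions of 303 candidates (s = -0.7593)

ev <- run_evaluate(bundle, ps)
ev$enrichment
#> enrichment_report: fold(predictions) = 34.28 (p = 2.94e-12); fold(loci fraction) = 28.03 (p = 1.52e-14)

str(ev$truth)
#> List of 4
#>  $ precision        : num 0.926
#>  $ recall           : num 0.833
#>  $ precision_defined: logi TRUE
#>  $ tp               : int 50

head(sort(scale_weights(trained$model$w)$scaled, decreasing = TRUE), 3)
#>  planted1  planted2  planted3
#> 1.0000000 0.8797588 0.8797056
```

Reading the output: the cross-validated model separates high- from
low-promoter CNEs almost perfectly (median AUC 0.993, hence "reliable");
scanning the distal candidates calls 54 enhancers above the control
threshold `s = min(0, δ) = −0.76`; the called set is 34-fold enriched in
the loci of highly expressed genes relative to control loci; 92.6% of the
predictions overlap a planted truth enhancer and 83.3% of the planted
enhancers are recovered; and the three planted motifs rank first among the
13 scaled model weights.

A thin CLI over the same functions ships in `inst/scripts/promsig`
(`simulate`, `train`, `scan`, `evaluate` subcommands with a YAML config).

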