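# gopred

Sequence-homology Gene Ontology (GO) function prediction and CAFA-style
evaluation, as a tidyverse-native R package.

## What problem this solves

Most newly sequenced proteins receive their functional annotation by
transfer from database search hits. `gopred` implements, on top of parsed
BLAST/PSI-BLAST tabular output, an annotation database (GAF) and a GO is_a
DAG (OBO), the family of homology-based GO predictors that competed in the
first CAFA experiment, together with the four assessment metric families
used to score them. It is aimed at people developing or benchmarking
automatic function prediction methods who want the classic scorers and the
evaluation machinery in one tested, scriptable place — with a seeded
synthetic benchmark generator so everything runs at desk scale without any
database download.

### The predictors

For a target with search hits *i* (E-value `E_i`, percent identity
`id_i`), hit annotations `f_j`, and an annotation database:

* **PFP** — raw score
  `s(f_a) = Σ_i Σ_j (−log10(E_i) + b) · P(f_a | f_j)`, with `b = 2 =
  log10(100)` so every hit up to the E-value ceiling of 100 contributes a
  non-negative weight, and `P(f_a|f_j)` the co-occurrence conditional
  probability of the two terms in single-protein annotations. Raw scores
  are then transferred to each ancestor `f_p` in proportion
  `freq(f_a)/freq(f_p)`, and can be calibrated into confidence scores via
  term-specific empirical p-values and the fraction of benchmark
  predictions correct within edge distance k ∈ {0, 2, 4} of a true term.
* **ESG** — two-level iterated search: each hit gets the weight
  `−log10(E)` normalised within its search; a hit that seeded a
  second-level search mixes its own annotations (weight `a`) with its
  second-level hits' annotations (weight `1−a`). Scores lie in [0, 1].
* **GOtcha** — every hit adds `max(0, −log10(E))` to each annotating term
  and all its ancestors; sums are normalised by the root's sum
  (the *I-score*, I(root) = 1).
* **BLAST baseline** — a term scores the maximum sequence identity over
  hits directly annotated with it.
* **Prior** — target-independent ranking of terms by database frequency
  with a pseudocount of 1: `score(c) = (freq(c)+1)/(freq(root)+1)`.
  `enrich_with_prior()` merges Prior terms into PFP/ESG prediction sets
  (`PFP+Prior`, `ESG+Prior`).

`freq(c) = annot(c) + Σ_{h ∈ child(c)} freq(h)` is the recursive term
frequency; `p(c) = freq(c)/freq(root)` and `IC(c) = −log10 p(c)` drive the
information-content metrics.

### The metrics

Threshold sweeps (precision / recall / specificity with predictions
propagated to the root), top-N sweeps with score ties included, a rank
sweep for unscaled raw scores, IC-weighted precision/recall, Resnik-style
semantic similarity / precision / recall, per-term F1 (maximum harmonic
mean over cutoffs for terms annotating enough targets), per-target Fmax,
and a leaf-level ranking AUC diagnostic.

## Worked example

```r
library(gopred)
options(gopred.quiet = TRUE)

# A seeded synthetic benchmark: ontology + annotated proteins + targets
# whose truth comes from hidden donor proteins + two-level search hits.
bundle <- make_bundle(fixture_config(seed = 42, n_targets = 10))
db     <- parse_gaf(write_gaf(bundle$db))          # drop IEA evidence
stats  <- compute_term_stats(bundle$dag, annotation_counts(db))

preds <- predict_targets(bundle$hits, db, bundle$dag, stats,
                         method = "esg", level2 = bundle$hits_level2)
head(preds, 5)
#> # A tibble: 5 × 3
#>   target term       score
#>   <chr>  <chr>      <dbl>
#> 1 T00001 GO:1000056 0.724
#> 2 T00001 GO:1000085 0.284
#> 3 T00001 GO:1000073 0.227
#> 4 T00001 GO:1000068 0.214
#> 5 T00001 GO:1000069 0.140
```

Each row is one (target, GO term, score) prediction, scores in [0, 1],
sorted best-first per target. Evaluating against the bundle's truth:

```r
curves <- threshold_curves(preds, bundle$truth, bundle$dag)
dplyr::filter(curves, threshold %in% c(0.5, 0.9))
#> # A tibble: 2 × 7
#>   threshold precision recall specificity    f1 n_targets n_precision_targets
#> 1       0.5     0.956  0.692       0.996 0.803        10                   9
#> 2       0.9     1      0.1         1     0.182        10                   1

mean(target_fmax(preds, bundle$truth, bundle$dag)$fmax)
#> [1] 0.925
mean(prediction_auc(preds, bundle$truth, bundle$dag)$auc)
#> [1] 0.996
```

At threshold 0.5, averaged over the 10 targets, 95.6% of propagated
predicted terms are correct and 69.2% of true terms are recovered; the
mean per-target Fmax is 0.925 and ESG ranks the targets' true leaf terms
essentially perfectly (AUC 0.996). `autoplot(curves)` draws the
precision-recall curve, `autoplot(curves, type = "roc")` the ROC.

The same pipeline is available from a shell:

```sh
gopred simulate --out bench --seed 42
gopred predict --method esg --obo bench/ontology.obo --gaf bench/annotations.gaf \
       --hits bench/hits_level1.tsv --hits-level2 bench/hits_level2.tsv --out esg.tsv
gopred evaluate --metric threshold --obo bench/ontology.obo \
       --truth bench/truth.tsv --pred esg.tsv --out report
```

(the `gopred` script ships at `system.file("cli", "gopred", package = "gopred")`).

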