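---
title: "Methods: homology-based GO prediction and its evaluation in gopred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based GO prediction and its evaluation in gopred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gopred)
options(gopred.quiet = TRUE)
```

# Scope and data model

`gopred` predicts Gene Ontology terms for protein targets from parsed
sequence-search results and evaluates those predictions the way the CAFA
community experiments do. It never runs BLAST or PSI-BLAST itself: the
inputs are tabular search output (12-column outfmt 6), a GAF annotation
file, and an OBO ontology. Four data shapes flow through the package:

* a `go_dag` — the is_a DAG of one or more GO namespaces, with one root
  per namespace and precomputed ancestor closures;
* an `annotation_db` — a tibble of (protein, term, namespace, evidence
  set) rows after evidence filtering;
* prediction sets — plain tibbles `target`, `term`, `score`, sorted
  best-first;
* `go_term_stats` — per-term direct counts, recursive frequencies,
  probabilities and information content.

Only is_a edges are used. `relationship:` lines such as part_of are
ignored at parse time (counted and logged once): annotation propagation
through part_of is a different semantic commitment, and the propagation
conventions implemented here are defined over is_a alone. Obsolete terms
and cross-namespace edges are dropped with logged counts.

# Term statistics

The recursive frequency is

$$freq(c) = annot(c) + \sum_{h \in child(c)} freq(h),$$

with `annot(c)` the number of proteins directly annotated with `c` after
evidence filtering, and $p(c) = freq(c)/freq(root)$,
$IC(c) = -\log_{10} p(c)$. Two deliberate consequences:

* the child-sum is taken literally, so a protein annotated under a
  multi-parent descendant is counted once per path. This matches the
  stated definition of the frequency rather than a set-theoretic
  "distinct proteins below c" count; the latter is available as
  `compute_term_stats(mode = "unique")` for users who want it, but the
  literal recursion is the default and is what the tests' path-counting
  oracle checks;
* IC uses log base 10 throughout, consistent with the E-value weights
  ($-\log_{10} E$) used by every scorer.

Terms with zero frequency have undefined probability and IC (`NA`) and
are excluded from IC-based metrics rather than imputed.

# The predictors

**PFP.** The raw score of a candidate term $f_a$ is
$\sum_i \sum_j (-\log_{10} E_i + b)\, P(f_a \mid f_j)$ over hits $i$ and
their direct annotations $f_j$. The conditional probability is the
fraction of proteins annotated with $f_j$ that also carry $f_a$, over
*direct* annotations: computing it over propagated sets would push
$P(\cdot \mid f_j)$ toward 1 for every ancestor pair and drown the
co-occurrence signal. The denominator reads "annotated with $f_j$", not
"annotated with $f_j$ and nothing else"; the exclusive reading would make
$P(f|f)$ ill-defined for multi-annotated proteins. Since $P(f|f) = 1$, a
hit's own annotations contribute their full weight, and terms that merely
co-occur with hit annotations can be predicted at all — which is the
point of PFP. The constant $b$ defaults to 2 $(= \log_{10} 100)$ so that
hits up to the default E-value ceiling of 100 contribute non-negative
weight; the ceiling and $b$ are both tunable in `pfp_params()`.

Raw scores are transferred root-ward: a scored term adds
$s(f_a) \cdot freq(f_a)/freq(f_p)$ to each of its proper ancestors
$f_p$. The transfer goes directly from each scored term to every
ancestor (not iteratively through the parent chain, which would compound
the ratios); with the ratio of frequencies this makes the received share
the fraction of the ancestor's annotation mass attributable to the
descendant.

**PFP confidence.** Per-term background raw-score distributions from a
benchmark run give empirical p-values; a calibration table maps p-value
bins to the fraction of benchmark predictions lying within edge distance
k ∈ {0, 2, 4} of a true term. The empirical p-value is the inclusive
tail count $\#\{bg \ge x\}/n$, with a $1/(n+1)$ floor when the observed
score exceeds every background sample, so p is never 0. Terms with fewer
than 5 background samples fall back to a pooled global background
(logged). Bin fractions are pooled with a weighted
pool-adjacent-violators pass so confidence is non-increasing in the
p-value; empty bins inherit the previous pooled value. The ranking
confidence defaults to k = 0 (exact-term correctness) — the strictest
choice, which cannot inflate scores — with the k = 2 and k = 4 columns
exposed for inspection.

**ESG.** Hits within one search are weighted by
$-\log_{10} E$ normalised to sum to 1; hits with $E > 1$ would carry
negative mass and are excluded from the normalisation (weight 0). A
level-1 hit with a level-2 search splits its weight `a : 1 − a` between
its own annotations and its level-2 hits' annotations; without a level-2
search its full weight goes to its own annotations, which keeps one-level
ESG well-defined and all scores in [0, 1]. The mixing weight defaults to
`a = 0.5` — no published value forces a particular split, and an equal
split treats the two exploration levels symmetrically; it is a plain
argument of `esg_scores()`.

**GOtcha.** Hit mass $\max(0, -\log_{10} E)$ is added to every
annotating term and all its ancestors, then normalised by the root's
total. The clamp at 0 is required for I-scores to stay in [0, 1]: hits
with E > 1 otherwise contribute negative mass.

**BLAST baseline and Prior.** The baseline scores a term by the maximum
identity over directly annotated hits — no propagation, no co-occurrence
— so a target whose hits carry no (non-IEA) annotation gets an empty
prediction set. The Prior scores every namespace term
$(freq(c)+1)/(freq(root)+1)$ and assigns the same top-1000 list to every
target. Prior enrichment imports missing Prior terms into a method's
predictions: for PFP the imported frequency scores are linearly mapped
from the Prior list's [min, max] onto the target's own score [min, max]
(the literal reading of rescaling "by considering maximum and minimum
scores"; this allows an imported term to tie the target's best score,
which is flagged but accepted), for ESG they are kept unchanged because
both scales already live in [0, 1]. A degenerate Prior range maps
imports to the target's minimum score.

All prediction lists are truncated to the 1000 best-scoring terms per
target; boundary ties break lexicographically by term id so truncation
is deterministic.

# Evaluation

Every set-based metric builds the same two sets per target and cutoff:
the predicted terms with score ≥ τ propagated to the root, and the
propagated truth. Three conventions, all configurable where meaningful:

* **"above the threshold" means score ≥ τ**, so τ = 1 retains scores of
  exactly 1 (the Prior's root and GOtcha's I(root));
* **the namespace root is excluded** from counting — it is implied by
  every prediction, and counting it would add one guaranteed true
  positive to every method uniformly (`include_root = TRUE` restores
  literal inclusion);
* **precision is averaged only over targets that predict something at
  the cutoff** (0/0 is undefined), while recall and specificity average
  over all evaluable targets, counting silent targets as recall 0. The
  specificity universe is all namespace terms minus the root; using only
  annotated terms would shrink the true-negative pool in a
  database-dependent way.

The top-N sweep keeps every term tied with the N-th score. The rank
sweep (`n_grid = seq(1, 1000, by = 5)`) exists because unscaled PFP raw
scores have no [0, 1] threshold interpretation: only ranks are
comparable across targets.

Weighted precision/recall replace counts by IC sums over the same sets;
terms with undefined IC are dropped from the sums and a target-cutoff
point with a zero denominator is skipped.

Semantic similarity / precision / recall operate on the *unpropagated*
predicted and true sets: the quantities are pairwise IC differences
against the best shared ancestor, and over propagated sets every
ancestor pair would contribute a zero-difference pair, collapsing the
metrics toward 0 regardless of prediction quality. IC can come from the
local annotation database or from an external per-term probability table
(`term_stats_from_probabilities()`), mirroring evaluations that use
organiser-provided priors.

Per-term F1 declares a target predicted-positive for term `c` at cutoff
τ when its propagated prediction set contains `c` — equivalently, when
it predicted `c` or any descendant at ≥ τ — and reports the maximum over
cutoffs of the harmonic mean of precision and recall. Terms are
shortlisted by `evaluable_terms()` (≥ 25 annotated targets by default;
at desk scale the tests use smaller minima, since 25+ targets per term
needs benchmark-scale truth sets).

**Ranking AUC.** `prediction_auc()` is the diagnostic used to verify
that predictors recover planted signal. It deliberately evaluates over
*leaf* terms only, against the pre-propagation truth: ancestors are
implied by any annotation, so generality-correlated scorers (the Prior;
GOtcha's monotone I-scores) would earn structural credit on propagated
truth even with no target-specific information, and the chance level
would sit above 0.5. Over leaves, a predictor independent of the truth
scores AUC ≈ 0.5, which is what the σ = 0 null check asserts.

# The synthetic benchmark generator

`fixture_config()` + `make_bundle()` emulate the structure every
homology-based predictor assumes:

* an ontology of the requested depth/branching (default 4 × 3, 121
  terms), optionally rewired to a DAG (default 10% multi-parent);
* a database (default 200 proteins, 1–3 leaf-biased direct annotations,
  20% IEA rows to exercise evidence filtering);
* targets (default 50) whose truth is the direct annotation set of a
  hidden donor — a clone of a database protein, so genuine homologs
  with overlapping annotations exist in the searchable database;
* level-1 hits that are, with probability σ (default 0.9), signal hits
  sharing a direct term with the donor at E-values log-uniform in
  [1e-50, 1e-10], and otherwise random proteins at E-values log-uniform
  in [1e-3, 10] — the noise range deliberately crosses E = 1 so the
  clamping rules are exercised; plus level-2 hits (fan-out 3) drawn the
  same way around each level-1 hit.

Truth files store the donor's direct terms; all set metrics propagate
internally, so storing the closure would be redundant, and the
pre-propagation set is what the leaf-level AUC needs. Every artifact
draws from its own seed-derived stream, so ontology, database and
searches can be regenerated independently and byte-identically.

What the generator does **not** model: actual sequences or alignment
coordinates, realistic E-value distributions (two log-uniform bands
only), inter-protein annotation correlation beyond donor cloning, and
namespace mixtures (one namespace per bundle). Passing the planted-signal
checks therefore shows the scorers exploit E-value-weighted annotation
overlap correctly — not that they would rank a real CAFA benchmark in
any particular order.

# Numerical choices and degenerate inputs

* E-values of 0 (perfect hits) are clamped to 1e-180 before
  $-\log_{10}$; the floor is configurable.
* Duplicate (query, subject) rows keep the lowest E-value; self-hits are
  dropped at parse.
* Score ties everywhere break lexicographically by term id, making
  every output deterministic.
* Empty inputs degrade, they do not error: no hits → empty predictions;
  an empty prediction set has Fmax 0 and is skipped by precision
  averaging; a target with empty truth is skipped with a log message
  (recall undefined).
* `freq(root) = 0` (no annotation in a namespace) is a hard error — no
  statistic downstream is defined.
* Test-suite problem sizes: the property and equivalence tests run on
  randomly generated DAGs of ≤ 20 terms with ≤ 10 proteins and ≤ 8 hits
  (100 instances against brute-force oracles), and the signal-recovery
  checks on the default 50-target bundle; these sizes keep the whole
  suite at roughly two minutes while covering every code path.

# Known limitations

* Only is_a propagation; no alt_id/consider resolution, no taxon or
  qualifier semantics beyond NOT.
* The PFP confidence calibration needs a benchmark with truth; without
  one the package ranks by (max-normalised) raw score and says so —
  the command line falls back automatically.
* The per-term analysis at its conventional threshold (25 targets per
  term) requires benchmark-scale truth sets; desk-scale runs use
  smaller minima.
* Co-occurrence probabilities are computed from whatever evidence
  filter the annotation database was parsed with; whether a historical
  PFP background used a different snapshot/filter is not modelled —
  the filter in use applies uniformly.
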