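---
title: "Stump-tree ensembles for imbalanced drug-combination classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stump-tree ensembles for imbalanced drug-combination classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edst)
```

## The problem

Predicting whether a pair of drugs acts synergistically, additively or
antagonistically on a given cell line is a three-class problem with two
awkward properties: the Additive class dominates (in a typical screen it
outnumbers the two interesting classes combined), and the features — two
concatenated per-drug expression signatures, hundreds of dimensions each
— are far wider than the sample count. Black-box learners can fit such
data but give a pharmacologist nothing to inspect. `edst` implements an
ensemble whose every component remains readable: the base decision unit
is a one-feature, multi-branch *decision stump*, stumps are spliced into
shallow trees, and any prediction can be replayed as an IF–THEN rule
over feature intervals.

## The model

**Decision stumps.** For a feature \(f\), training samples are sorted by
value and partitioned into ordered intervals. Each interval takes the
majority label of its samples; adjacent intervals with the same label
merge into *groups*; cut-points fall at midpoints between neighbouring
groups, the outer groups extending to \(\pm\infty\). A stump is thus a
step function over one axis with \(u\) half-open intervals
\((lo, hi]\).

**Interval granularity.** With per-drug signature features, a feature
column takes one value per drug, each carried by every sample involving
that drug — so "one interval per distinct value" is a natural, populated
partition, and that is what the stump uses when values repeat (mean run
occupancy of at least 3 samples per distinct value). On genuinely
continuous columns that convention collapses: every interval is a pure
singleton, every feature looks perfect, and impurity cannot rank
features at all. The stump therefore coalesces value runs into
occupancy bins of at least \(\lceil\sqrt{p}\rceil\) samples (run
boundaries are never split; the trailing underfull bin merges
backwards). The switch is automatic and deterministic; passing
`min_interval = 1` to `build_stump()` forces the per-value partition.

**Size-unweighted Gini.** Stumps are scored by
\[
\mathrm{Gini} = \sum_{z=1}^{u}\Bigl(1 - \sum_{j=1}^{c} p_{j,z}^2\Bigr),
\]
the sum of per-group impurities *without* weighting by group size. This
is a deliberate departure from the classical criterion: a leaf's vote
counts the same whether it holds 5 samples or 500, so features are
judged by how cleanly they partition the whole axis, which also
penalizes fragmenting the axis into many groups (each group adds a
non-negative term). When a candidate stump from the shared pool is
re-evaluated on a subset of samples, empty groups contribute zero. A
stump whose groups all merged (\(u = 1\)) cannot split anything and is
never selected as a node.

**One-vs-one stump trees.** A \(c\)-class task is decomposed into
\(c(c-1)/2\) pairwise tasks. Per task, the root stump is chosen from the
subset's (possibly exchanged) stump pool by minimal re-evaluated Gini;
every root group becomes a branch, and deeper nodes refit fresh stumps
on the branch's samples over the features not yet used on that path. A
branch becomes a leaf — storing its empirical two-class distribution —
when it is pure, thinner than \(\theta = \lceil n_{task}/10\rceil\)
samples, or ten stump layers deep. Ties between equally scoring
features break to the lower index, so growth is fully deterministic.
Branches that receive no samples inherit the parent's distribution
(uniform at an empty root); single-sample tasks get a uniform leaf.

**Balanced bagging and stump exchange.** Sub-datasets are bootstrap
draws of size \(n\) where a sample of class \(j\) is drawn with
probability proportional to
\(\alpha_j = (1/N_j)\big/\sum_{j'} 1/N_{j'}\); each class then
contributes equal expected mass, so minority classes are heavily
re-represented. \(2m\) such subsets are drawn, one stump per feature is
fit on each, and stumps are compared *within* a subset by the cosine of
their predicted-class-code vectors over the full training set. The
least informative half of each subset's stumps (highest similarity sum)
are marked exchangeable, and features exchangeable in two or more
subsets have their stumps randomly permuted across those subsets —
capped at 10% of the stumps per subset — passing information between
bags before any tree is grown. One tree ensemble (a DST) is grown per
subset; the \(m\) with the best training macro-F1 are retained, and
their probability votes are averaged at prediction time. Tied class
votes go to the rarer training class.

**Rules.** Every leaf of every pairwise tree is a rule: the conjunction
of its path's interval conditions plus the pairwise verdict
"PREDICT X THAN Y". Rule quality combines coverage (fraction of the
pair's samples matched) and accuracy (fraction of matched samples whose
label is X) by the harmonic mean
\(2 R_{cov} R_{acc} / (R_{cov} + R_{acc})\), zero when both are zero.
The denominator population is the two verdict classes; a flag switches
to the whole dataset. Rules render in a fixed dialect —
`IF 0.59 < feature 1695 ≤ 0.66 AND ... THEN PREDICT Additive THAN
Synergy` — with an infinite bound dropping its clause, and
`parse_rule()` inverts `render_rule()` exactly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 100 | retained trees (2m candidates are fit) |
| `exchange_prop` | 0.10 | cap on exchanged stumps per subset |
| `max_depth` | 10 | stump layers per pairwise tree |
| `leaf_frac` | 0.10 | \(\theta\) as a fraction of a task's samples |
| `k` | 300 | features kept by chi-square selection |
| `min_interval` | adaptive | samples per initial stump interval |

The defaults are the method's published operating point. Chi-square
selection treats each (min-max scaled, hence non-negative) feature as a
mass split across classes and keeps the top `k` statistics; it is refit
inside every training fold, never on the full data, which is the
leak-free reading — whether the original protocol refit per fold is
unstated, so absolute numbers may differ slightly from runs that select
once globally. Min-max scaling is fit on training data only; test
values extrapolate outside [0, 1] deliberately, which is why rules like
`IF 1.0 < feature 1850` can fire.

## The synthetic data generator

`generate_synthetic()` emulates the structure of a drug-combination
screen without any download: each of `n_drugs` drugs carries a latent
standard-normal signature of length `signature_dim`; a sample
concatenates the signatures of its two drugs (every drug is guaranteed
at least one appearance) plus i.i.d. Gaussian noise (`noise_sd`,
default 0.05 against unit-variance signal); labels follow a planted
decision list on one or two informative coordinates — Antagonism below
a threshold on the first, Synergy above a threshold on the second among
the rest — with thresholds placed at the value boundaries that bring
class shares closest to the requested ratios (default 134/451/140
normalized, the imbalance of a real 725-sample colorectal screen).
Because feature values repeat per drug, shares move in drug-sized
blocks; with the default 40 drugs the realized shares land within about
±0.03 of target. Features are min-max scaled and the ground-truth rule
is attached for recovery checks; `planted_rule_predict()` reproduces
the labels exactly at zero noise.

The planted rule is axis-aligned by design — the same hypothesis class
stumps express — so feature-recovery tests are fair but *easy*; a
`nonlinear = TRUE` variant replaces the Synergy condition with an XOR
of two thresholds for robustness testing. What the generator does not
emulate: correlated genes within a signature, batch structure,
dose-dependent effects, label noise from borderline synergy scores.
Passing tests on this generator demonstrate the machinery is correct
and recovers plantable signal; they do not certify performance on real
screens.

## Numerical and design choices

- Interval membership is `lo < x <= hi` everywhere (a value equal to a
  cut-point goes left), matching the rendered-rule dialect.
- Majority ties inside an interval prefer the globally rarer class,
  then the lower class code; prediction ties prefer the rarer training
  class. Both keep the pipeline deterministic and minority-friendly.
- Stump-similarity uses 1-based class codes, so the cosine is always
  positive; two constant stumps predicting different classes score 1 —
  acceptable, as both are equally uninformative and both belong in the
  exchangeable half.
- Candidate subsets that draw a single class are redrawn (5 attempts).
- `theta` is anchored to each binary task's own sample count, the
  conservative reading of "a tenth of n" after subsetting.
- Degenerate chi-square inputs (zero-mass features) score 0; `k`
  exceeding the feature count returns everything with a warning.
- Model persistence is versioned JSON (cut-points, distributions,
  configuration) — no binary serialization, and two identically seeded
  fits serialize to identical bytes.

## Evaluation protocols

`compute_metrics()` reports per-class one-vs-rest precision/recall/F1
(0/0 conventions resolve to 0 with a warning), macro-F1, rank-based AUC
(Mann–Whitney with midranks for ties, macro-averaged one-vs-rest for
multiclass) and F1\* — the unweighted mean F1 of the designated
minority classes, by default every non-modal class — which summarizes
exactly the classes the screen cares about. `kfold_cv()` is stratified
five-fold by default with all preprocessing refit per fold.
`leave_drug_out_cv()` partitions *drugs* (default six groups) and tests
each group on every sample containing any of its drugs, so a fold's
test drugs never appear in its training set; a pair spanning two groups
is tested twice and trained on never.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the generator at
`n = 1000`, `v = 40` (two 20-dim halves), 40 drugs, noise 0.05 and the
screen's class ratios, fitting `m = 20` (recovery, cross-validation) or
`m = 10` (sampling ablation, leave-drug-out) trees over `k = 40`
features — sizes chosen so a full run completes in minutes on one core
while every pipeline stage (selection, balanced bagging, exchange, tree
growth, voting, rules, both CV protocols) is exercised end to end.
Under these conditions training macro-F1 exceeds 0.94 across seeds,
both planted features rank in the top-5 importance, and mean tree depth
stays near 1.4 stump layers with under ten leaves per pairwise tree.

## Known limitations

- The occupancy-bin granularity is a pragmatic fix for continuous
  features; a principled minimum-description-length or cost-complexity
  choice of interval count is future work.
- Exchange currently permutes stumps uniformly at random among holders;
  no attempt is made to match donor/recipient subset composition.
- Rule coverage/accuracy are in-sample unless the caller supplies a
  held-out dataset to `rank_rules()`.
- `F1*` needs the minority classes named (or inferred as non-modal); on
  a balanced dataset the inference is arbitrary.

## A minimal session

```{r example, eval = FALSE}
ds <- generate_synthetic(synth_config(seed = 1))
model <- edst_fit(ds, edst_config(m = 20, k = 40, seed = 1))
compute_metrics(ds$class_names[ds$labels],
                edst_predict(model, ds$features),
                edst_predict_proba(model, ds$features),
                class_names = ds$class_names)
head(feature_importance(model)$importance)
render_rule(rank_rules(model, ds)[[1]])
```
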