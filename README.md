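# edst — ensembles of decision-stump trees

`edst` is an R package for interpretable multiclass classification on
imbalanced tabular data, built for (but not tied to) drug-combination
effect prediction: given a feature vector made of two concatenated
per-drug expression signatures, classify the pair's effect on a cell
line as **Synergy**, **Additive** or **Antagonism**. The Additive class
typically dominates such screens, and practitioners need to see *why* a
pair was called synergistic — two constraints that rule out most
black-box learners.

## The method

The base decision unit is a **multi-branch decision stump**: one
feature's axis, sorted and partitioned into ordered intervals, adjacent
intervals with the same majority label merged into groups with midpoint
cut-points. Stumps are scored by a **size-unweighted Gini impurity**

    Gini = Σ_z (1 − Σ_j p²_{j,z})   over the stump's u groups,

so every group counts equally regardless of its size and fragmenting
the axis is penalized. A C-class problem is decomposed **one-vs-one**
into C(C−1)/2 pairwise tasks; per task, stumps are spliced into a
shallow tree (root from a shared per-subset stump pool, deeper stumps
refit per branch, stop below θ = ⌈n/10⌉ samples, at purity, or at 10
layers). The **EDST ensemble** draws 2m bootstrap subsets with
class-balanced probabilities

    α_j = (1/N_j) / Σ_{j'} (1/N_{j'}),

each sample drawn proportionally to its class's α, exchanges the
least-informative stumps between subsets (cosine similarity of
predicted-class vectors; 10% cap), grows one tree bundle per subset,
keeps the m best by training macro-F1, and averages their probability
votes. Every leaf is exportable as a rule

    IF 0.59 < feature 1695 ≤ 0.66 AND 0.52 < feature 431 ≤ 1.0
    THEN PREDICT Additive THAN Synergy

scored by the harmonic mean of coverage and accuracy.

## Worked example

```r
library(edst)

ds <- generate_synthetic(synth_config(seed = 1))   # emulated screen
ds
#> <labeled_dataset> 1000 samples x 40 features, 3 classes
#>   classes: Antagonism (177), Additive (619), Synergy (204)
#>   drug pairs over 40 distinct drugs

model <- edst_fit(ds, edst_config(m = 20, k = 40, seed = 1))
model
#> <edst_model> 20 DSTs over 3 classes (Antagonism, Additive, Synergy)
#>   features kept: 40 of 40; seed 1
#>   mean max depth 1.48, mean leaf count 9.22

compute_metrics(ds$class_names[ds$labels],
                edst_predict(model, ds$features),
                edst_predict_proba(model, ds$features),
                class_names = ds$class_names)
#> macro-F1 1.0000 | F1* 1.0000 | AUC 1.0000 | accuracy 1.0000

round(head(feature_importance(model)$importance, 5), 3)
#> feature 29 feature 35 feature 33 feature 26 feature 22
#>      0.416      0.225      0.090      0.056      0.034

rank_rules(model, ds)[[1]]
#> IF feature 29 ≤ 0.332025061210502 THEN PREDICT Antagonism THAN Synergy
#>   coverage 0.465, accuracy 1.000, score 0.634
```

The generator planted its class rule on features 29 and 35 — exactly
the two the ensemble ranks first, and its top rule is the planted
Antagonism threshold. `kfold_cv()` (stratified five-fold) and
`leave_drug_out_cv()` (drugs partitioned into six groups; a fold tests
every pair containing one of its held-out drugs) evaluate
generalization; `edst_to_json()` / `edst_from_json()` persist models as
portable JSON.

A command-line front end ships in `inst/cli/edst.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "edst.R", package = "edst"))')
Rscript $CLI simulate --out data.csv --n 1000 --seed 1
Rscript $CLI train    --data data.csv --drug-cols d1,d2 --m 20 --k 40 --out model.json
Rscript $CLI rules    --model model.json --data data.csv --drug-cols d1,d2 --out rules.tsv
Rscript $CLI evaluate --data data.csv --drug-cols d1,d2 --m 20 --k 40 --strategy leave_drug_out
```

## Package layout

- `R/` — datasets and I/O, stumps, exchange, trees, ensemble, rules,
  evaluation, synthetic generator, JSON persistence
- `tests/testthat/` — unit, property and end-to-end tests against
  brute-force references
- `vignettes/edst-methods.Rmd` — the model, its assumptions, parameter
  meanings and known limitations
- `inst/cli/edst.R` — command-line interface
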