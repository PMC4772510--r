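# rfscreen

Ligand-based virtual screening with a from-scratch random forest whose
decision trees are built **iteratively** — depth-first from a stack frontier
while the tree is small, breadth-first from a queue frontier once the node
count crosses a threshold — without the switch ever changing the fitted
model.

## Who this is for

Computational chemists and method developers who want a self-contained,
fully reproducible screening classifier: train on a labelled bioassay (SDF
with an activity tag, or a descriptor CSV), then screen SMILES/SDF compound
libraries of arbitrary size in constant memory, with the standard
evaluation panel (recall, precision, F-score, ROC area, accuracy).

## The method

A binary random forest: each of `n_trees` trees grows on a bootstrap
resample, splits nodes by maximum GINI gain

```
gain = G(parent) − [ n_L · G(left) + n_R · G(right) ] / n ,   G = 1 − Σ p_i²
```

over `f` randomly drawn candidate features per node, and the forest
predicts by majority vote (ties → active; the vote fraction doubles as a
ranking score). Tree construction is non-recursive: unexpanded nodes wait
in a frontier that is popped LIFO (depth-first) until the number of created
nodes reaches the crossover threshold

```
threshold(n, f) = 3705 + 0.0577 · n + 21.84 · f      [nodes]
```

and FIFO (breadth-first, level by level) from then on. Because each node's
feature subset is keyed by its root-to-node path — not by expansion order —
every `bfs_threshold` value yields the *identical* predictor; the threshold
only matters for batch-parallel execution efficiency. Evaluating the
formula at a 296,456-compound assay with 179 descriptors gives
`24719.87` nodes.

Molecules are featurized into 179 descriptors in three fixed blocks:
8 drug-likeness properties, 24 Burden-matrix (BCUT-style) eigenvalues under
three atomic weightings, and 147 pharmacophore-pair fingerprint bits
(21 class pairs × 7 topological-distance bins). See the methods vignette
(`vignettes/virtual-screening-forests.Rmd`) for definitions and caveats.

## Worked example

```r
library(rfscreen)

# a synthetic bioassay: 1000 compounds, 12.5% active, strong signal
assay <- generate_assay(assay_spec(n = 1000, effect_size = 2, seed = 1))
#> <feature_table: 1000 compounds x 179 descriptors, 125 active / 875 inactive>

train <- feature_table(assay$matrix[1:700, ],    labels = assay$labels[1:700])
test  <- feature_table(assay$matrix[701:1000, ], labels = assay$labels[701:1000])

model <- train_forest(train, forest_params(n_trees = 50, seed = 1))
#> <forest_model: 50 trees, 179 features, trained on 700 compounds (86 active)>

evaluate_model(model, test)
#> Recall  Precision  F-score  ROC area  Accuracy
#> 0.462   1.000      0.632    0.983     0.930
#> (n = 300, actives = 39)
```

Held-out accuracy 0.930 with ROC area 0.983: the forest ranks actives
almost perfectly, while the hard 0.5-vote cutoff under 12.5% imbalance
trades recall (0.462) for perfect precision — compounds it does call active
are reliable, and the score column supports any other cutoff.

Screening a molecule file in batches:

```r
lib  <- generate_molecules(200, seed = 7, path = tempfile())  # toy .sdf/.smi
tab  <- featurize(read_sdf(lib$sdf, activity_tag = "ACTIVITY"))
m2   <- train_forest(tab, forest_params(n_trees = 25, seed = 2))
screen_stream(m2, molecule_stream(lib$smi), batch_size = 64)
#> <screening_report: 200 screened (48 predicted active, 0 failed) in 4 batches>
```

The per-compound table (`$results`) carries id, predicted label, vote
score and status; output is identical for every batch size.

## Command line

```sh
Rscript exec/rfscreen.R simulate --n 1000 --effect-size 2 --seed 1 --out assay.csv
Rscript exec/rfscreen.R train    --features assay.csv --trees 50 --out model.json
Rscript exec/rfscreen.R evaluate --model model.json --features assay.csv --out metrics.json
Rscript exec/rfscreen.R describe --input library.sdf --activity-tag ACTIVITY --out features.csv
Rscript exec/rfscreen.R predict  --model model.json --library library.smi --batch-size 4096 --out report.csv
```

Logs go to stderr, data to the named files; exit codes are 0 (success),
1 (user/input error), 2 (internal error).

## Acceptance script

`scripts/acceptance.R` recomputes the package's machine-checkable target —
the crossover-threshold regression evaluated at `n = 0, f = 0` — from the
installed package, runs a seeded end-to-end train/evaluate pass as a
liveness check, and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
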