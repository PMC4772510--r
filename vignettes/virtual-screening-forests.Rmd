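---
title: "Hybrid depth/breadth random forests for ligand-based virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid depth/breadth random forests for ligand-based virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Ligand-based virtual screening asks a classifier, trained on compounds with
known activity against a target, to rank or filter a large untested library
so that wet-lab effort concentrates on the most promising molecules. The
training data are bioassay outcomes (active/inactive, typically heavily
imbalanced toward inactive) and the features are 2D molecular descriptors.

`rfscreen` implements the classifier as a from-scratch binary random
forest:

* a predetermined number of decision trees, each grown on a bootstrap
  resample (n draws with replacement) of the training rows;
* node splitting by maximum GINI-impurity gain over a random subset of `f`
  candidate features per node; for a candidate feature the thresholds
  examined are the midpoints between consecutive distinct sorted values
  ("value `<=` threshold" sends a row left);
* prediction by majority vote over the trees, with the vote fraction
  exposed as a ranking score.

What distinguishes the construction is that tree induction is *iterative*,
never recursive: created-but-unexpanded nodes wait in an explicit frontier
array. While the tree is small the frontier is popped last-in-first-out (a
stack, so growth is depth-first); once the number of nodes created crosses
a threshold it is consumed first-in-first-out (a queue, so whole levels are
expanded breadth-first). The crossover threshold, in nodes, is the
regression

```
threshold(n, f) = 3705 + 0.0577 * n + 21.84 * f
```

with `n` the training-sample count and `f` the per-split feature count
(`crossover_threshold()`, the default for `bfs_threshold = "auto"`). The
switch exists for throughput on batch-parallel hardware — depth-first is
cheap near the root, breadth-first amortizes better once a level holds many
small nodes — so it must not change the statistical result. The package
guarantees that by construction: each node's candidate-feature subset is
drawn from an RNG stream keyed by `(tree_seed, root-to-node path)`, not by
expansion order, so any `bfs_threshold` value produces the identical
predictor. The test suite checks this exhaustively
(`bfs_threshold` in {0, auto, 1e9} over 20 assays).

A frontier node becomes a leaf when its impurity is at or below
`gini_leaf_threshold`, when fewer than `2 * min_samples_leaf` rows remain,
at `max_depth`, or when no split gains more than `min_gain`. Leaves take
the majority label of their rows; *ties resolve to active*, as does an
exact tie in forest voting — in a screening campaign the cost of discarding
a true active exceeds the cost of carrying a false positive forward.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 50 | ensemble size; more trees stabilize votes, cost is linear |
| `max_features` | 14 (= ceiling of sqrt(179)) | candidate features per split; the `f` of the crossover formula |
| `bfs_threshold` | `"auto"` | depth-to-breadth crossover in nodes; has no effect on predictions |
| `gini_leaf_threshold` | 0 | impurity at/below which a node is a leaf; 0 grows trees fully, as in the serial baseline |
| `min_gain` | 1e-7 | guards against splits whose gain is numerical noise |
| `min_samples_leaf` | 1 | minimum rows per child |
| `max_depth` | unlimited | optional cap |
| `seed` | 1 | all randomness (bootstraps, feature subsets) derives from it |

The forest is a pure function of `(table, params)`: tree seeds are folded
from `(seed, tree index)` with a 31-bit Lehmer generator whose streams are
platform-independent, so serialized models are byte-identical across runs
and machines.

## The 179-descriptor featurization

Each molecule maps to a fixed vector of 179 values in three blocks:

1. **Drug-likeness (8):** molecular weight, a crude atom-contribution logP,
   H-bond donor count (N/O bearing H), H-bond acceptor count (N + O),
   rotatable bonds, a reduced Ertl-style topological polar surface area
   (N/O contributions only), cyclomatic ring count, heavy-atom count.
2. **Burden-matrix eigenvalues (24):** the 4 lowest and 4 highest
   eigenvalues of the Burden connectivity matrix (diagonal = atomic
   property; 0.1 × bond order for bonded pairs, 0.001 otherwise) under
   three atomic weightings — mass, Pauling electronegativity, covalent
   radius. These BCUT-style values give a low-dimensional continuous
   chemistry space.
3. **Pharmacophore-pair bits (147):** six atom classes (donor, acceptor,
   aromatic, hydrophobe, positive, negative) give 21 unordered class pairs;
   each pair is observed at 7 binned topological (bond-path) distances
   (1, 2, ..., 6, ≥7), and a bit is set iff some atom pair of those classes
   occurs at that distance.

The 8/24/147 block structure is the contract the rest of the package
depends on. The definitions inside each block are a documented stand-in:
the descriptor tool the scheme emulates is proprietary and its exact
descriptor list is not public, so no attempt is made to reproduce its
values bit-for-bit — tests assert block structure, determinism, and
format-independence (a structure parsed from SDF and from SMILES yields the
identical vector), not chemical identity. All descriptors are computed on
the implicit-hydrogen heavy-atom graph. Neutral nitrogen is fixed at
valence 3 (legacy uncharged pentavalent nitro notation is rejected), which
is what makes the SDF/SMILES round trip exact for pyrrole-type N–H.

## What the synthetic generator emulates — and what it does not

`generate_assay()` produces tables shaped like a PubChem-style screen:
exactly `ceiling(n * active_fraction)` actives (default fraction 0.125,
echoing a 37,055-of-296,456 assay), 32 Gaussian continuous columns, 147
sparse Bernoulli bits (base on-probability 0.1). Signal enters through
`n_informative` seed-chosen columns: actives get a `effect_size * noise_sd`
mean shift on continuous columns and a `min(effect_size * 0.1, 0.4)`
on-probability increase on bit columns.

This is linear-ish, axis-aligned signal injection. It deliberately does
*not* simulate real structure–activity relationships: no descriptor
correlations, no activity cliffs, no assay noise or label errors, no
scaffold clustering. A green signal-recovery test therefore establishes
that the forest finds axis-aligned signal of the stated size under class
imbalance — not that it would rank a real screening deck as well.

Two property choices deserve a note:

* *Separability monotonicity* is tested on a **balanced** assay
  (`active_fraction = 0.5`). Under the default 12.5% imbalance the
  majority-class baseline is 0.875 accuracy, which masks small effect
  sizes; on balanced labels the mean held-out accuracy rises cleanly
  (about 0.51 / 0.57 / 0.75 / 0.92 for effect sizes 0 / 0.5 / 1 / 2).
* *Null calibration* (effect size 0) is asserted on the **mean** ROC area
  over 20 seeds. A single desk-scale null AUC has a standard deviation
  near 0.05, so individual seeds stray outside [0.4, 0.6] by chance; the
  mean is the stable quantity.

## Numerical choices

* **Split thresholds** are midpoints of consecutive distinct values. When
  the two values are adjacent doubles the midpoint can round onto the upper
  value and produce an empty child under the `<=` rule; the threshold is
  then clamped to the lower value so the realized partition is the scored
  one. Ties in gain break toward the lowest feature index, then the lowest
  threshold.
* **`min_gain` default 1e-7** with `gini_leaf_threshold` 0 reproduces fully
  grown trees while absorbing floating-point noise in gain comparisons.
* **Node elimination** by the impurity threshold is read as "sufficiently
  pure ⇒ leaf" (the threshold bounds impurity from above); the opposite
  reading would discard pure nodes, which cannot terminate construction.
* **Model JSON** carries doubles at 17 significant digits, the minimum that
  makes text round trips exact; `load_model()` rejects any other
  format-version string.
* **Degenerate inputs**: single-class training sets are an error for
  `train_forest()` (a vote among identical leaves is meaningless) but a
  single-leaf tree is legal for `build_tree_hybrid()`; undefined metric
  ratios (e.g. precision when nothing is predicted active) are reported as
  `NA` with a warning, never silently as 0.

## Design decisions taken where the design was open

* **Per-node feature sampling** (rather than per-tree): matches the
  crossover formula's definition of `f` as "features considered at each
  node split" and is what makes construction-order invariance provable and
  testable. A per-tree draw would also be order-invariant but would couple
  tree diversity to far fewer random choices.
* **Crossover unit**: the threshold counts *nodes created so far*, compared
  before each expansion; the frontier's pop side flips the first time the
  count reaches the threshold.
* **Tie votes and tie leaves go to active**, an explicit screening-oriented
  policy (documented in `predict_forest()`), since the stated aim of this
  kind of screen is to avoid false negatives.
* **ROC area from vote fractions** via the Mann–Whitney rank identity (ties
  at half weight): a hard-label forest has no native score, and the vote
  fraction is the standard resolution.
* **Activity-tag mapping** accepts active/1/true and inactive/0/false
  case-insensitively and *drops* anything else (e.g. "Inconclusive") with a
  warning rather than guessing a label.

## Known limitations

* The SMILES/SDF layer covers the organic subset plus common hetero
  elements and ignores stereochemistry (descriptors are 2D); wildcards,
  isotope effects and radicals are rejected. Blocks that fail to parse are
  skipped and counted, never silently repaired.
* logP and TPSA are reduced schemes adequate for a deterministic,
  qualitatively sensible drug-likeness block — not calibrated predictions.
* The forest handles binary labels only; no regression, no multiclass, no
  pruning, no GPU execution (batched screening bounds memory, not time).
* Training is serial; the per-seed tree independence means a parallel map
  over trees would give the identical model, but none is built in.
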