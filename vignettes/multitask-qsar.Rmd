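---
title: "Multi-tasking QSAR for G-quadruplex ligands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tasking QSAR for G-quadruplex ligands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtqsar)
```

## The modeling problem

G-quadruplex (G4) bioactivity data are intrinsically multi-condition: a
ligand's measured K~d~, ΔT~m~ or IC~50~ depends on the G4-forming sequence,
the buffer (which selects the G4 topology), the assay, the ligand-to-G4
ratio, the cell line and the exposure time. A single-condition QSAR model
either discards most of the data or mixes incomparable measurements. The
multi-tasking approach keeps all records in one classifier by moving the
experimental context into the feature space.

### Box–Jenkins condition-modified descriptors

For descriptor $d$, record $i$ and condition field $f$ with category
$c_f(i)$, the modified descriptor is the deviation from the per-category
moving average:

$$\Delta D(i,d,f) \;=\; D_{comp(i)}(d)\;-\;\overline{D}_{f=c_f(i)}(d),$$

where the mean runs over all modeling-set records sharing the category.
One column per (descriptor, field) pair results, so a schema with $p$
retained descriptors and $m$ condition fields yields $p \times m$ modified
columns. Two properties follow by construction and are asserted by the test
suite:

* within every (field, category) cell, the modeling-set mean of
  $\Delta D$ is zero to machine precision;
* the per-category means are fitted on the modeling set only, so no
  information from the held-out external set can reach the features — the
  external 20% stays untouched until final validation, which is why it is
  split off *before* the means are fitted.

The averaging set is configurable (`average_over = "all"` or
`"positives"`); the default averages over all records of the category,
which makes the transform a pure re-centering and keeps the zero-mean
invariant unconditional. Numeric conditions (exposure time, ligand:G4
ratio) are treated as discrete categorical levels, since screening grids
enumerate a small fixed set of values for them.

## Workflow and tunable parameters

`mtqsar()` runs the stages in a fixed order; the table lists the
parameters that matter, with defaults.

| stage | parameter | default | meaning |
|---|---|---|---|
| pretreatment | `variance_cutoff` | 1e-4 | drop near-constant descriptor columns |
| pretreatment | `correlation_cutoff` | 0.99 | greedy first-kept-wins Pearson filter |
| external split | `external_fraction` | 0.2 | activity-stratified hold-out, rounded half-up per class |
| train/test | `test_fraction` | 0.2 | of the modeling set |
| train/test | `test_method` | random | or `euclidean`: rank records by distance from the modeling-set centroid in modified-descriptor space, send every $k$-th ($k = \mathrm{round}(1/\text{fraction})$) to the test set |
| GA | `n_features` | 5 | fixed chromosome size |
| GA | `pop_size` / `generations` | 50 / 30 | tournament selection (size 2), uniform crossover repaired to fixed size, single-column swap mutation, elitism 1 |
| GA | `fitness` | wilks | $-\lambda$; `mcc` (training MCC of an LDA fit) and `combined` (within-population rank-sum of both) available |
| LDA | priors / threshold | equal / 0 | pooled covariance; ridge $10^{-6}$ added when singular |
| RF | `n_trees`, `min_leaf` | 500, 1 | randomForest, unlimited depth |
| CV | `cv_folds` | 10 | stratified; refits the classifier only — feature selection and condition means stay fixed, since CV validates the already-selected model |
| AD | `tanimoto_min` | 0.3 | min structural-key similarity to any training compound |
| AD | `euclidean_k` | 3 | inside if NN distance ≤ mean + k·SD of training NN distances |
| AD | leverage | $h^* = 3(k{+}1)/n$ | $h = x^\top(X^\top X)^{-}x$ via pseudo-inverse; disabled when $n \le k+1$ |

The applicability domain combines its three tests with a union rule: a
compound is inside if at least one method accepts it. This is monotone —
relaxing any single threshold can only admit more compounds — and every
training compound is inside its own domain through the similarity branch.
The Tanimoto and Euclidean cutoffs are this package's documented defaults;
treat them as starting points, not as universal constants.

### Validation metrics

All metrics derive from the confusion matrix: accuracy, precision,
sensitivity, specificity (percentages), F-measure (harmonic mean of
precision and sensitivity, on [0, 1]) and Matthews correlation coefficient.
A metric whose denominator is zero is reported as `NA` (undefined), never
silently as zero — an all-positive prediction vector has undefined
specificity and MCC. Wilks lambda is computed as
$\lambda = \det(W)/\det(T)$ over the within-group and total SSCP matrices;
for the one-dimensional instance $\{1,2\}$ vs $\{4,5\}$, $W=1$, $T=10$,
$\lambda = 0.1$, which the suite checks against the MANOVA Wilks statistic.

## The synthetic-data generator

Real G4 datasets need downloads and manual curation, so the package ships a
generator whose output has the statistical structure the pipeline assumes,
with ground truth recorded:

* **Structures** come from a combinatorial fragment library (ring cores ×
  linkers × terminal groups, deduplicated on canonical SMILES), so every
  compound parses, survives curation, and yields fingerprints.
* **Conditions**: two fields by default — a 3-category buffer and a
  2-level ligand:G4 ratio — sampled uniformly per record.
* **Planted signal**: latent values $z_1, z_2 \sim N(0,1)$ decide the true
  class by $\mathrm{sign}(z_1 + z_2)$. The *observed* descriptors are
  shifted per category: field 1 shifts informative descriptor 1 by
  $\{-1.5, 0, +1.5\}$, field 2 shifts informative descriptor 2 by
  $\{-1, +1\}$. A model on raw descriptors therefore sees a
  condition-confounded boundary, while the Box–Jenkins deviation columns
  recover $z_1, z_2$ exactly — the transform is precisely the operation
  that removes the planted confound. Each field shifts its own descriptor
  because simultaneous shifts of one descriptor by two fields cannot be
  undone by any linear combination of the (descriptor, field) deviation
  columns.
* **Label noise** flips 10% of classes by default; the continuous endpoint
  (ΔT~m~ by default) is back-computed from the flipped class so that
  thresholding it reproduces the observed class for every record.
* **Curation exercise**: 2% of records are duplicated verbatim and 2% of
  compounds are emitted with a chloride counter-ion, so the duplicate
  analysis and salt stripping have real work to do.
* **Noise columns**: 20 standard-normal descriptors with no class
  information.

`recovery_benchmark()` runs the full pipeline on this data and scores the
external predictions **against the ground-truth classes** (the noise-free
planted labels), because the benchmark asks whether the pipeline recovered
the planted mechanism; metrics against the observed (flipped) labels are
reported alongside and are capped near $1 - \text{noise}$ by construction.
At the default conditions (600 records, 10% noise) the GA selects exactly
the two planted modified columns — verified in the test suite against
exhaustive search over all column pairs — and both LDA and RF classify the
external set well above 90% against ground truth.

What the generator does *not* emulate: real structure–activity
relationships (descriptors are synthetic, not computed from the
structures), assay-specific error distributions, activity cliffs, and the
class imbalance of literature data. Green tests therefore demonstrate that
the machinery is correct and leak-free, not that any particular chemistry
is learnable.

## Numerical and design choices

* **Duplicate analysis II** applies the 0.5 averaging window to the group
  *range* (max − min) on the endpoint's native scale; the window is
  configurable per endpoint. When distant values agree in class, the
  record closest to the group median is kept (ties to input order) for
  determinism.
* **Correlation filtering** is greedy in input column order:
  the first of a correlated pair wins, which makes pretreatment
  deterministic and order-stable.
* **Class cutoffs** follow the printed inequalities exactly: K~d~ < 1 µM
  and IC~50~ < 10 µM are positive strictly, ΔT~m~ ≥ 15 °C inclusively;
  the FRET stabilizer call is strict (ΔT~m~ > 4 °C).
* **Degenerate inputs**: single-atom molecules get zero topological
  indices; a singular pooled covariance triggers a logged ridge; a
  singular total-scatter matrix in Wilks lambda raises with a pruning
  hint; unseen condition categories at transform time raise by default
  (`unseen = "skip"` opts into flag-and-drop).
* **Oncogene/target** is derived from the G4 sequence via the bundled
  lookup rather than enumerated as an independent grid factor, since each
  screening sequence identifies its target.
* **Model bundles** persist the selected columns, classifier parameters,
  condition means, AD reference and per-file checksums; loading verifies
  the checksums and refuses descriptor matrices from a different backend,
  so screening of new compounds is self-contained and tamper-evident.
* **Problem sizes** in the shipped tests and the acceptance script were
  chosen to keep a full run in the low minutes on one CPU: the default
  synthetic study has 600 records, 2 + 20 descriptors and 44 modified
  columns, which is large enough for stable external estimates and small
  enough for exhaustive feature-subset cross-checks.

## Known limitations

* The builtin descriptor backend is intentionally small (~18 scalar
  descriptors + 166 structural keys); it is not a substitute for a large
  descriptor suite when modeling real data, and models are tagged with
  their backend so the two are never mixed.
* Only two-class endpoints are supported; regression endpoints and
  multi-class schemes are out of scope.
* The Euclidean train/test division concretizes "distance-based division"
  as centroid-distance rank striding; other published variants exist.
* The GA's `combined` fitness uses a within-population rank-sum, which is
  scale-free but not comparable across runs; the reported best fitness for
  `combined` is the rank-sum, not a raw statistic.
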