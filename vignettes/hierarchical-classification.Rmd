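---
title: "Hierarchical probability-calibrated cell-type classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical probability-calibrated cell-type classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scTypeTree)
```

## The model

scTypeTree annotates single cells by applying one *binary* classifier
per cell type, rather than a single multiclass model. Each classifier
answers "is this cell of type $t$, versus everything else?" with a
calibrated probability. This one-vs-rest design is what makes a
*rejection option* possible: a cell that no classifier accepts is
reported as `"unknown"` instead of being forced into the nearest class,
so populations absent from the reference remain detectable.

For cell type $t$ with feature panel $G_t$ (its marker genes), the
decision function on a cell's normalized expression vector $x$ is

$$ f_t(x) = w_t \cdot z_t(x) + b_t, \qquad
   z_{t,g}(x) = \frac{x_g - \mu_{t,g}}{\sigma_{t,g}}, $$

a soft-margin linear SVM on features standardized with *training-set*
constants $(\mu_t, \sigma_t)$ that are stored in the classifier and
re-applied verbatim at prediction time. Linear kernels are the only
supported kernel: for marker-panel inputs they match or beat more
flexible kernels while keeping models small, fast, and interpretable
(each weight is attached to a named gene).

Decision values are mapped to probabilities by Platt scaling,

$$ p_t(x) = \frac{1}{1 + \exp(A_t f_t(x) + B_t)}, $$

with $(A_t, B_t)$ fitted by minimizing the negative log-likelihood with
Platt's smoothed targets $t_+ = (N_+ + 1)/(N_+ + 2)$,
$t_- = 1/(N_- + 2)$ (Newton's method with backtracking on the convex
objective). A cell is *accepted* by classifier $t$ when
$p_t(x) \ge \theta_t$; the comparison is `>=`, so a probability exactly
at the threshold passes. Thresholds default to $0.5$ and can be changed
at any time without retraining (`setThreshold()`, or per-run overrides
in `classifyCells()`).

### The classifier tree

Classifiers form a forest. A child (say, a plasma-cell classifier under
a B-cell classifier) is evaluated *only* on cells its parent accepted;
gated-off cells carry an `NA` probability, deliberately distinct from a
low probability. Per cell, the candidate set is the deepest accepted
type along each accepted branch — an accepted child *replaces* its
accepted ancestor, because the child is a refinement of the same call,
not a competing one. Candidates from different branches are reported as
an ambiguous, slash-joined, lexicographically sorted assignment
(`"B cells/T cells"`); an empty candidate set is `"unknown"`;
`best_guess` is the candidate with the highest probability, ties broken
lexicographically. Cell-type names may not contain `/` for this reason.

### Training pipeline

`trainClassifier()` runs, in order: restriction to the parent lineage
(for child classifiers), library-size normalization of raw counts,
feature-panel extraction, removal of constant features (warning, not
error — z-scores are undefined for them), standardization, class
balancing, SVM fitting, and Platt calibration on the balanced training
decision values.

Choices that deserve justification:

* **Lineage restriction by labels, not by parent predictions.** A child
  classifier is trained on cells whose *label* belongs to the parent's
  lineage. This keeps training reproducible and independent of the
  parent model's quality; the alternative (gate training cells through
  the parent's predictions) couples a child's quality to its parent's
  errors.
* **Descendant labels count as positives for an ancestor.** A plasma
  cell *is* a B cell, so when the B-cell classifier is trained, cells
  labeled with descendant types are treated as positive via the
  `aliases` mechanism. `trainDatabase()` wires this automatically from
  the hierarchy.
* **Feature inheritance** (`inherit_features = TRUE` in
  `trainDatabase()`): a parent's panel is the union of its own and its
  descendants' markers, since it must accept all its subtypes. We do
  *not* pool panels across unrelated types: panels restricted to
  positive markers are what make rejection work — a cell that is
  background on every panel is rejected, whereas a classifier trained
  on "my markers high AND your markers low" will confidently claim
  cells that are low on everything.
* **Class balancing** by seeded downsampling of the majority class
  (default): one-vs-rest labeling is extremely imbalanced for rare
  types, and an unbalanced fit shifts the operating point of the
  calibrated 0.5 threshold.
* **Cost selection** (`tune_cost = TRUE`): the regularization cost $C$
  is chosen by stratified 5-fold cross-validated accuracy on the
  balanced training set over $\{0.01, 0.1, 1, 10\}$, with ties resolved
  toward the smallest $C$ (the strongest regularization). Marker panels
  are low-dimensional but training sets are often only a few hundred
  cells per side; a fixed $C = 1$ measurably overfits there, which
  shows up not as a bad ranking (AUCs stay high) but as an overconfident
  sigmoid whose 0.5 operating point accepts too eagerly. Resampling-based
  selection is the behavior of the caret-style training stacks this
  workflow descends from. Set `tune_cost = FALSE` to use `cost_c`
  directly.

Training is deterministic: the configuration seed drives the balancing
draw and the CV folds, and the SVM solver is deterministic given its
input.

## Scoring

`scorePredictions()` implements two variants. Under **strict** scoring
a cell with an in-reference truth is correct only when the assignment
is exactly that single type — an ambiguous set is counted wrong *even
if it contains the truth*. Under **intermediate_accepted** scoring a
cell is additionally correct when the truth is a member of the
assignment set, or the assignment is a single ancestor of the truth
(an intermediate call like "B cells" for a plasma cell). In both
variants a cell whose true type is absent from the reference is correct
exactly when it was rejected as `"unknown"`; dataset-level accuracy
includes those cells in the denominator by default
(`include_unknown_truth = FALSE` excludes them). The
unknown-population detection rate is reported separately: among cells
whose truth is outside the reference, the fraction left unassigned
(`NA` when no such cells exist).

Per-type sensitivity is the fraction of truth-$t$ cells scored correct
under the variant in use; specificity for $t$ counts a cell against $t$
whenever $t$ appears *anywhere* in its assignment set, because an
ambiguous call still asserts $t$. Mean sensitivity and specificity are
unweighted across reference types present in the truth. By
construction, intermediate-accepted accuracy and sensitivities dominate
their strict counterparts on any input.

`rocPoints()` sweeps the acceptance threshold over the observed unique
probabilities and integrates the curve by the trapezoid rule (this
equals the pairwise concordance count with ties at one half).
`tuneThreshold()` supports the Youden criterion (maximal
$\mathrm{tpr} - \mathrm{fpr}$, ties to the lowest threshold, i.e. the
most sensitive operating point) and a target-sensitivity rule (largest
threshold still achieving the requested sensitivity).

## The synthetic-data generator

`simulateDataset()` draws counts from a negative binomial,
$X_{cg} \sim \mathrm{NB}(\mu = s_c\, \mu_0 F_{cg},\ \phi)$ with
variance $\mu + \mu^2/\phi$, where $s_c$ is a per-cell log-normal
library factor (meanlog 0, sdlog `libsize_sigma`), $\mu_0$ the baseline
mean, and $F_{cg}$ the planted fold change: `fold_change` of the
marker-owning type when gene $g$ is a marker of the cell's type *or of
one of its ancestors* (so subtypes carry their lineage's markers, the
mirror image of feature inheritance at training time), otherwise 1.
Marker sets must be disjoint among siblings; parent/child overlap is
allowed.

Defaults describe the package's reference scenario: three root immune
types ("B cells", "T cells", "NK cells") plus "Plasma cells" under
"B cells"; 500 cells and 30 markers per type, 1000 genes, baseline mean
0.5, dispersion 2, `libsize_sigma` 0.3, with "NK cells" held out of
training so unknown-population rejection is exercised. These sizes make
an end-to-end train-and-evaluate round trip run in seconds while
keeping per-gene signal realistically weak (marker means of 2 counts
against a background of 0.5, with heavy zero inflation from the NB).

What the generator deliberately does **not** emulate: batch effects,
doublets, dropout beyond NB zeros, gene–gene correlation within a cell
type, or ambient RNA. Passing tests therefore demonstrate that the
machinery is correct under its stated model, not that real tissues will
classify at the same accuracy.

## Numerical choices and degenerate inputs

* Probabilities are clamped to the open interval $(0, 1)$ at machine
  precision; the Platt solver stops at a gradient below $10^{-6}$, or
  when no representable line-search step improves the objective.
* Normalization refuses all-zero cells (their library size is
  undefined) and names the offenders.
* Features requested but absent from a matrix are zero-filled with a
  warning — gene panels differ across platforms and zero is the
  sparse-consistent neutral value; a panel with *no* overlap is an
  error. Exact string matching only; no alias resolution.
* Sparsity is preserved end to end: normalization rescales only stored
  nonzeros, and the only densification anywhere is the
  cells-by-panel feature block (instrumented via `sparseAuditPeak()`,
  which tests use to prove classification of a 50,000-cell matrix never
  widens beyond the largest panel).
* `.ctdb` archives are JSON with every real-valued array additionally
  base64-encoded as IEEE-754 doubles, so a save/load round trip is
  bit-exact while the manifest stays human-readable. Loading checks the
  format version and names the offending field on malformed input.
* Run configuration files for the command line are YAML (flat,
  diff-friendly, overridable by flags); every run writes a JSON
  manifest recording the command, package version, seed, parameters,
  and any warnings (dropped constant features, zero-filled markers).

## Known limitations

Feature panels must be supplied (marker files or simulation truth);
there is no built-in differential-expression feature selection. Only
linear kernels are implemented, and cluster-level majority voting is
out of scope — every cell is classified independently. The scoring
utilities assume each cell has exactly one true label; overlapping or
graded truth is not supported.
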