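---
title: "Supervised Kohonen map classifiers for structure-activity modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised Kohonen map classifiers for structure-activity modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somsar)
```

# The modelling problem

Ligand-based structure–activity modelling starts from a table of molecules
by precomputed molecular descriptors (topological indices, counts of
functional groups, surface-area terms, and so on) and a categorical outcome:
active versus inactive against a target, or which of several related targets
(here typified by the cyclin-dependent kinases CDK1/2/4/5/9) a molecule
inhibits. `somsar` implements one complete, reproducible pipeline for this
problem: descriptor cleaning, supervised feature selection, two
self-organizing-map classifiers, the validation battery that the QSAR field
expects (interleaved cross-validation, external test set, y-randomization),
a leverage applicability domain, and spike-in virtual screening.

All stages consume and produce one container, the `descriptor_table`: a
numeric molecules-by-descriptors matrix with unique molecule ids and an
optional class label per molecule.

# Models

## Toroidal Kohonen maps

Both classifiers live on a square grid of `side^2` neurons with wrap-around
edges (a torus), so no neuron sits on a boundary. Topological distance
between neurons is the Chebyshev ring distance with wrap-around, giving
square rings of neighbours. When a training molecule is presented, the
neuron whose weight vector is nearest (Euclidean) becomes the best matching
unit (BMU), and every neuron `j` is pulled towards the presented vector:

$$ w_j^{new} = w_j^{old} + \eta(t)\, a(d_j - d_c)\, (x - w_j^{old}) $$

with learning rate `eta(t)` decaying over epochs and a neighbourhood factor
`a` in [0, 1] that is 1 at the winner and 0 beyond the current radius.

**CPANN** (counter-propagation) keeps two coupled layers: the competitive
Kohonen layer over descriptors, and a Grossberg output layer holding one
class-membership weight per class. The BMU is found on the Kohonen layer
only; both layers then update with the same `eta * a` factor, the output
layer being pulled towards the one-hot class vector:

$$ u_j^{new} = u_j^{old} + \eta(t)\, a(d_j - d_c)\, (y - u_j^{old}) $$

Because targets are one-hot and `eta * a` stays in [0, 1], Grossberg
weights remain in [0, 1] throughout training — an exact invariant the test
suite checks.

**SKN** (supervised Kohonen network) fuses the descriptor block and the
class block into one weight vector per neuron (the XY map). Training finds
the BMU on the concatenation `[x, class_weight * y]` and updates the whole
fused vector; prediction uses the descriptor block only, reading class
memberships off the class block. `class_weight` defaults to 1 (equal
blocks); at 0 training degenerates to an unsupervised map on the
descriptors.

For both models the predicted class of a query molecule is the argmax of
its BMU's membership weights (clipped to [0, 1]); a secondary scoring mode
averages the 3x3 BMU neighbourhood's memberships with triangular distance
weights, which breaks the many score ties a small map produces and is the
mode used for ranking tasks (ROC curves, virtual screening).

## Numerical and design choices

Several training details are deliberately simple, exposed, and frozen:

* **Neighbourhood kernel** — triangular, `a = max(0, 1 - d / (radius + 1))`.
  The classic MATLAB Kohonen-toolbox lineage of these models uses a linear
  kernel; a Gaussian alternative would change nothing structural.
* **Schedules** — learning rate 0.5 to 0.01 and radius `side / 2` to 0,
  both linear over epochs, constant within an epoch.
* **Initialisation** — uniform per feature within the training data's
  [min, max], seeded; presentation order is reshuffled every epoch from the
  same seed stream, so training is bit-reproducible.
* **Tie-breaks** — BMU ties go to the smallest row-major neuron index,
  class-score ties to the earlier class in `class_names`, nearest-neighbour
  ties in the similarity analysis to the lowest training row index. All are
  arbitrary but deterministic.

The inner training loop is compiled (Rcpp); one epoch over `n` molecules
costs `O(n * side^2 * n_features)`.

# The surrounding pipeline

**Preprocessing.** Near-constant descriptors are dropped, then the pairwise
correlation filter removes multicollinear descriptors: repeatedly find the
retained pair with the largest |r| above the cutoff (default 0.90) and
remove the member with the higher mean absolute correlation to all other
descriptors of the original table, so each correlated group is survived by
its least-redundant member. The iteration scheme (greedy worst-pair-first)
is a design choice; the survivor rule is what defines the result, and a
brute-force check that no retained pair exceeds the cutoff is part of the
test suite. Autoscaling uses sample (ddof = 1) standard deviations.

Two scaling protocols are available: `leak-free` (default) fits the scaler
on the training split only; `scale-first` fits it on the full table before
splitting, which replicates workflows that scale first and partition later
at the cost of leaking test statistics into the scaler. Both are recorded
in the run manifest.

**Descriptor selection.** A PLS2 model (NIPALS; one centred {0,1} column
for binary labels, one-hot columns for multiclass) yields Wold VIP scores

$$ VIP_j = \sqrt{\, p \sum_a SSY_a (w_{ja} / \lVert w_a \rVert)^2 \big/ \sum_a SSY_a \,} $$

whose squares average to 1 by construction. The component count is chosen
by venetian-blinds cross-validated PRESS, capped at 10. A model-size sweep
then trains a classifier on the top-k VIP descriptors for each candidate k
and keeps the k with the best cross-validated non-error rate (ties to the
smaller k). The reference workflow swept 14–35 candidate descriptors on a
450-descriptor matrix; on the bundled synthetic presets (36 descriptors, 10
informative) the sweeps in this package use 6–16, bracketing the planted
count.

**Validation.** Folds are venetian blinds — molecule `i` of the stored
order lands in fold `((i - 1) mod k) + 1` — with a seeded pre-shuffle (on
by default) so interleaving cannot alias a sorted input file. Metrics come
from the confusion matrix: per-class precision/sensitivity/specificity,
accuracy, non-error rate (mean per-class sensitivity, the imbalance-robust
sweep metric), and MCC (2x2 formula for binary; the generalised
multi-category form, which reduces to it, otherwise). Undefined ratios are
reported as `NA`, never as 0. Map side and epochs are chosen by exhaustive
grid CV (ties: smaller map, then fewer epochs). y-randomization refits the
identical configuration on label-permuted data — hyperparameters are not
re-selected, which matches the usual protocol and bounds runtime — and
reports training/CV/test error rates and AUC per iteration.

**Applicability domain and screening.** Leverage is
`h_i = x_i' (X'X)^{-1} x_i` on the scaled, VIP-selected training matrix
with no intercept augmentation, with threshold `h* = 3(p + 1)/n`;
rank-deficient `X'X` falls back to a pseudo-inverse with a warning. The
spike-in screen concatenates a background database with known actives,
ranks by the model's continuous positive-class score (ties resolved
conservatively: background ahead of spiked actives), and reports enrichment
factors over the top `ceiling(f * N)` molecules — the ceiling guarantees a
non-empty bin — plus ROC/AUC.

# The synthetic-data generator

Real descriptor matrices for this problem are proprietary (commercial
descriptor software over curated bioactivity databases), so the package
ships a generator that reproduces the statistical structure the pipeline
must handle, not the chemistry:

* *informative descriptors* — class-conditional Gaussians. In the default
  `pairwise` mode every pair of class means is `class_mean_shift` apart
  along random orthonormal directions, so individual descriptors carry
  unequal signal; in `per-descriptor` mode every informative descriptor
  separates consecutive classes by the stated shift, the layout used when
  each planted descriptor must be detectable on its own (the VIP-recovery
  checks use 1.5 scaled units per descriptor).
* *noise descriptors* — standard Gaussian, class-independent.
* *collinear blocks* — members share one latent draw plus calibrated
  jitter, so pairwise correlations land at the requested level (default
  0.95, above the 0.90 filter cutoff); the filter must prune each block to
  one survivor.
* *class sizes* — presets mirror the cleaned per-target counts of the
  reference dataset (e.g. 773 actives / 688 inactives for CDK1; five
  active classes 773/1440/875/650/1273 for the target-selectivity model),
  scaled by a `size_factor` for desk-scale runs.

A companion generator produces screening pairs: a background that mimics a
diverse public database (the inactive-class distribution with standard
deviations inflated twofold, optionally admixed with active-like molecules)
plus a set of true actives from the active-class distribution.

What the generator does **not** emulate: heavy-tailed and discrete
descriptor distributions (a t(5) option exists as a robustness probe),
realistic descriptor covariance learned from data, activity cliffs, or any
structure-derived relationship between columns. Passing the bundled checks
therefore demonstrates that the machinery is correct and well-calibrated on
its stated statistical model — not that any particular accuracy will be
reached on real descriptor tables.

# Benchmark problem sizes and expectations

The package's own acceptance checks run the full protocol — filter, scale,
70/30 split, VIP sweep (6–16), map-size selection over sides {6, 8, 10} at
300 epochs, final training and evaluation — on the two-class preset
(100/class, shift 4) over 20 seeds for both classifiers, and the five-class
preset at 0.1 scale (501 molecules) over 20 seeds for SKN. At these sizes a
run takes a few seconds per model; both binary classifiers reach
cross-validated and test accuracies around 0.92–0.97. The five-class
non-error rate averages about 0.85: with every pair of class means 4 scaled
units apart, misclassification into four competing neighbours accumulates,
and a nearest-centroid reference classifier on the same selected
descriptors tops out near 0.90 — a prototype-quantised map stays a few
points below that ceiling, which is worth knowing before reading the
five-class numbers as a deficiency of the implementation. Null checks
(zero shift, y-randomization) sit at chance,
and the spike-in screen (100 actives into 10,000 background) reaches
enrichment factors far above random. These sizes were chosen so the whole
battery stays interactive; they are stated here because every reported
number in the README is produced by these exact runs.

# Known limitations

* Online (sample-by-sample) training only; no batch-SOM variant.
* Square toroidal maps only — no hexagonal or planar topologies.
* Class imbalance is handled at evaluation (non-error rate), not by
  reweighting during training.
* The hydrophilic-factor descriptor `hy_descriptor()` takes its group
  counts as integers; deriving them from structures needs an external
  chemistry toolkit. Its atom-count convention is documented rather than
  resolved: the formula is evaluated with whatever `A` the caller supplies
  (`atom_count_convention` records the choice, since the descriptor
  literature is not unanimous).
* Probability calibration of membership scores is out of scope; scores are
  ranking devices, not probabilities.
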