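---
title: "Segmented profile features for structural class prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented profile features: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segstruct)
```

This vignette documents the model behind `segstruct`, the parameters
that matter, the numerical conventions adopted at points where more than
one reading was defensible, and what the synthetic test bed does and
does not establish.

## Inputs and the two profiles

A protein enters the pipeline as a pair of per-residue profiles.

The **evolutionary profile** is the log-odds block of a PSI-BLAST ASCII
PSSM: an `L × 20` integer matrix over the fixed column order
`A R N D C Q E G H I L K M F P S T W Y V`.  Before any feature is
computed it is min-max normalized, `(x − min)/(max − min)`, using the
global minimum and maximum of that protein's own matrix.  Per-protein
global scaling (rather than per-column or per-dataset) keeps the
relative magnitudes of columns intact — the segmented-distribution
features below are driven by how mass is shared along and across
columns — and makes each protein's descriptor independent of whatever
dataset it happens to be processed with.  A constant matrix normalizes
to all zeros rather than erroring.  The percentage block of the PSSM
file is parsed and discarded; only the log-odds block is used.

The **structural profile** is the `L × 3` helix/strand/coil probability
matrix of a SPINE-X-style predictor, in fixed (H, E, C) column order,
together with the predictor's own per-residue state string.  Where that
string disagrees with the row argmax we keep the predictor's call: it
is the predictor's output, not ours to second-guess.  When no state
string is supplied (e.g. for matrices built in code) the consensus is
the row argmax with ties resolved in H > E > C order.

## Feature groups

Eight groups, always concatenated in the same order (AAO, PSSM-AAC,
PSSM-SD, PSSM-SAC, SSEO, SPINE-SSEC, SPINE-SD, SPINE-SAC), form the
three schemes: PSSM-S (520 features at the defaults), SPINE-S (78) and
the combined PSSM-SPINE-S (598).  Widths depend only on the
configuration, never on `L`, so any mixture of protein lengths yields a
rectangular table.

**Occurrence (AAO, SSEO).**  Raw symbol counts — not frequencies —
along the evolutionary consensus sequence (per-row argmax of the
normalized PSSM, ties to the lowest column index) and along the
structural state string.  Counts are deliberately not divided by `L`:
occurrence retains length information that composition throws away.
Non-standard residues (B, Z, X, U) may appear in sequences; they are
never produced by the consensus (whose alphabet is the 20 columns) and
contribute no count when counting over a supplied sequence.

**Semi-composition (PSSM-AAC, SPINE-SSEC).**  Column sums
`Σᵢ M_ij`.  The "semi" is a warning label: despite the name there is
no division by `L`.  The operation is linear and its components sum to
the grand sum of the matrix — both properties are tested.

**Segmented distribution (PSSM-SD, SPINE-SD).**  For column `j` with
total mass `T_j`, and distribution factor `F` (percent), the boundary
index `I_k` is the *maximal* prefix length whose cumulative mass is
`≤ k·F/100 · T_j`, for `k = 1 … 50/F`, scanned once from the top of the
matrix and once from the bottom (bottom indices count rows from the
last row upward).  Conventions, each of which matters in edge cases:

* *Ties are included* — a prefix whose mass equals the threshold
  exactly counts, per the "less than or equal" definition.
* *No clamping* — if the first row alone already exceeds the 25 %
  threshold, the boundary is 0.  Maximality is taken literally.
* *Zero-mass columns* yield all-zero indices rather than an error;
  zero columns occur in real normalized PSSMs.
* The emitted feature is the **normalized** index `I_k / L ∈ [0, 1]`.
  The classical distribution-descriptor convention reports normalized
  positions, and normalization keeps features comparable across protein
  lengths.  `normalize = FALSE` exposes the raw counts for sensitivity
  checks.

The features are invariant to scaling a column by any positive
constant, and monotone in `k` — both property-tested against an
exhaustive oracle that tries every prefix length directly.

**Segmented auto covariance (PSSM-SAC, SPINE-SAC).**  Each column is
segmented with `F = 25` (fixed for this group): four nested segments —
first `I₁` rows, first `I₂` rows, last `I'₁` rows, last `I'₂` rows.  On
each segment, and on the whole column, the lagged auto covariance

$$AC(j, g) = \frac{1}{n-g} \sum_{i=1}^{n-g} (M_{ij} - \bar M_j)(M_{i+g,j} - \bar M_j), \qquad g = 1 \dots K$$

is computed **around the whole-column mean** `M̄_j`, not the segment's
own mean — a deliberate reading of the definition: the centering
quantity is the average over the column, and reusing it makes segment
coefficients commensurable with the global ones.  Two further
conventions: the normalizer is `1/(n−g)`, the conventional estimator in
the auto-covariance descriptor literature; and any segment with
`n ≤ g` (including empty segments from zero boundaries) contributes 0,
never NaN, so dimensionality is input-independent down to `L = 1`.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `fp`, `fs` | distribution factor (percent of cumulative mass per step) | 25 | supported values 5, 10, 25 (50/F must be integral).  F = 25 gives 4 segments per column; smaller F multiplies the SD width (20, 10 or 4 features per column per direction) |
| `kp`, `ks` | distance factor: maximum auto covariance lag | 4 | studied range 1–10; 5K features per column |
| `cost` | SVM soft margin C | 500 | adopted operating point |
| `gamma` | RBF width γ | 0.055 | adopted operating point |
| `k` | folds | 10 | k-fold; `jackknife` is leave-one-out |

The defaults reproduce the canonical widths 520 / 78 / 598.  The grid
search covers `C ∈ 2⁻⁵ … 2¹⁵`, `γ ∈ 2⁻¹⁵ … 2³` with exponent step 2,
ties broken toward smaller C then smaller γ.

## Classification and evaluation

The SVM is LIBSVM via e1071: C-classification, RBF kernel, one-vs-one
multi-class voting (LIBSVM's own decomposition).  Feature scaling is
**fold-local min-max to \[0, 1\]**: scaling ranges are fit on the
training rows of each fold and applied to its test rows, so no test
information leaks into training.  Range scaling rather than z-scoring
is a considered choice: it is the scaling convention of the LIBSVM
toolchain in which γ = 0.055 is a working operating point, and it keeps
squared distances between ~600-dimensional descriptors small enough
that the RBF kernel stays informative.  Z-scored descriptors of this
dimension have expected squared distances near `2 × 598`, which drives
every kernel entry to zero at this γ; the classifier then degenerates
to majority voting, which in leave-one-out evaluation is systematically
wrong.  Constant columns scale to zero.

Cross-validation is stratified by class with fold assignment drawn from
a user-supplied seed (the jackknife has no randomness); classes smaller
than `k` fall back to round-robin assignment with a warning.  Every
sample is predicted exactly once and the pooled out-of-fold predictions
form one confusion matrix, from which: overall accuracy
`Q = 100 · trace/N`; and per class, one-vs-rest sensitivity
`TP/(TP+FN)`, specificity `TN/(TN+FP)` and Matthews correlation, with
MCC defined as 0 whenever a factor of its denominator vanishes.  These
formulas are verified in tests against an oracle that expands the
matrix back into per-sample calls and recounts.

## The synthetic test bed

Real inputs require PSI-BLAST runs against NR and a secondary-structure
predictor, so the package carries a generator that emulates both file
formats with class-dependent statistics:

* **all-α**: helix at every position; **all-β**: strand everywhere;
* **α/β**: alternating helix/strand runs of length 8 (interleaved
  architecture) — helix fraction within \[0.4, 0.6\] by construction for
  the default length range;
* **α+β**: one helix block followed by one strand block (segregated).

Structural rows interpolate between the exact state indicator and a
flat Dirichlet draw, `(1−t)·onehot + t·Dir(1,1,1)` with
`t = noise/(1+noise)`; evolutionary rows do the same between a
state-specific residue-propensity row (helix formers A, L, E, M, Q, K
boosted under H; strand formers V, I, F, Y, W, T under E; G, P, S, N, D
under C) and a flat Dirichlet row, then are quantized to plausible
integer log-odds.  Noise 0 is fully deterministic class signal; noise
→ ∞ approaches exchangeable rows with no signal.  Defaults: lengths
uniform on 50–150, noise 0.3, 25 proteins per class, all reproducible
from one seed.  Matrices are quantized to the precision of their file
formats, so written fixtures re-read bit-identically.

The crucial design point: α/β and α+β have (near-)identical state and
residue *composition* and differ only in *arrangement*.  Occurrence and
semi-composition alone therefore cannot separate them; the segmented
distribution and segmented auto covariance groups can.  This mirrors,
qualitatively, why segmentation features help on real benchmarks — and
it is what the ablation test measures: mean 10-fold accuracy of
PSSM-AAC alone, then +SAC, then the full PSSM-S, averaged over five
generated datasets at moderate noise, must be non-decreasing.

What the generator does **not** emulate: PSI-BLAST's actual log-odds
statistics and column correlations, NR database composition, coil-rich
loop structure, domain boundaries, or class-imbalanced benchmarks.
Passing the end-to-end tests therefore demonstrates that the pipeline
is internally correct and that its features capture arrangement
information — not that any particular accuracy carries over to real
proteins, whose profiles are far noisier and whose classes overlap.

## Problem sizes in the test suite

The suite and the acceptance script run the end-to-end checks at sizes
chosen to estimate the relevant quantities stably: 10 proteins per
class for the noise-free jackknife and its label-permuted null; 8 per
class, 5 replicate datasets, at noise 0 / 1 / 8 for the noise sweep; 12
per class, 5 replicates, noise 1 for the ablation.  Oracle-equivalence
checks run on 200 random instances per operation at lengths up to ~25
rows, where the brute-force references are exact and fast.

## Known limitations

* The package parses PSI-BLAST's ASCII matrix and SPINE-X-style tables
  only; binary checkpoints and other predictors' dialects are out of
  scope.
* Feature selection / dimensionality reduction is not implemented; the
  598-dimensional combined vector goes to the SVM as-is.
* Min-max normalization of the PSSM is per protein.  A per-dataset
  variant would couple descriptors across proteins; it was rejected for
  that reason, but the choice is a candidate for sensitivity analysis
  on real data, as is the raw-vs-normalized distribution index
  (`normalize_distribution`).
* MCC is reported per class (one-vs-rest); no multi-class MCC is
  computed.
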