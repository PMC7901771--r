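---
title: "Identifying pseudouridine sites with multi-channel convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying pseudouridine sites with multi-channel convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiCNN)
```

## The problem

Pseudouridine (Ψ) is the most abundant internal RNA modification. Every Ψ is
an isomerized uridine, so the computational task is a binary decision over
candidate uridines: given the local sequence context of a U, is it a Ψ site?
psiCNN works on *uridine-centered windows* — strings of length $2\xi + 1$
over $\{A, C, G, U\}$ with the candidate U at the center, $\xi$ flanking
nucleotides on each side. Human and mouse data conventionally use $\xi = 10$
(21-nt windows) and yeast $\xi = 15$ (31-nt windows); the package accepts
any odd window length with a central U and rejects everything else (ambiguity
codes are refused rather than imputed, because the encodings below are
defined only for the four bases; DNA-alphabet input is silently normalized
T→U). Positions are 0-based internally and the central position is index
$\xi$.

## Encodings

Two binary representations feed the classifier.

**General one-hot.** Each base maps to a unit row vector in the fixed column
order A, U, C, G, so a window of length $N$ becomes an $N \times 4$ matrix.

**Merged-seq one-hot.** Each window is first paired position-by-position
with a dot-bracket secondary structure (`.` unpaired, `(`/`)` the 5'/3'
sides of a base pair). The 4 bases × 3 structure symbols give a 12-letter
pair alphabet, and one-hot encoding yields an $N \times 12$ matrix. The
12 columns are ordered base-major — `A.`, `A(`, `A)`, `U.`, … — reusing the
A, U, C, G base order of the 4-letter case with symbol order `.`, `(`, `)`.
Any fixed order produces an equivalent model (it permutes input columns,
and the first-layer weights are learned); this one is documented and
stable, and `decode_matrix()` inverts both encodings exactly.

## Where structures come from

The merged encoding needs a structure per window. Three sources are
supported:

* **Precomputed files** in the RNAfold plain-text dialect (sequence line,
  then the MFE dot-bracket line with an optional trailing energy, which is
  ignored; suboptimal structure lines are ignored too).
* **An external folder** (`fold_external()`), any RNAfold-compatible
  command. No options beyond defaults are assumed.
* **The built-in folder** (`fold_nussinov()`), a Nussinov maximum-pairing
  dynamic program over the canonical pairs AU/UA, GC/CG and the GU/UG
  wobble, with a minimum loop length of 3 (a pair $(i, j)$ requires
  $j - i > 3$). It maximizes the *number* of nested pairs and makes no
  thermodynamic claim; it exists so that merged-seq pipelines are fully
  reproducible and self-contained. Determinism is guaranteed by a fixed
  traceback rule: leaving $i$ unpaired is preferred over pairing it, and
  among equal-scoring partners the smallest index wins. The test suite
  checks its pair counts against exhaustive enumeration of all nested
  structures on short random sequences.

## The classifier

The network is a multi-channel 1-D convolutional model in the text-CNN
style:

```
input (N x 4 or N x 12)
  ├─ channel 1: conv(h1 x width, ReLU) → max-pool(pool) → flatten
  ├─ channel 2: conv(h2 x width, ReLU) → max-pool(pool) → flatten
  ┆
  └─ concatenate → dense(1024, ReLU) → dropout(p) → dense(2, softmax)
```

Choices that the architecture description leaves open, and how this package
resolves them:

* **Filter width equals the alphabet width** (4 or 12). A filter therefore
  scans positions only, the natural reading of "the width of the filters
  remained unchanged" for one-hot sequence input.
* **Pooling is local max pooling** over non-overlapping blocks of
  `pool_size = 2` positions (a trailing partial block is dropped; a channel
  whose convolution output is shorter than the block is pooled globally),
  and the pooled maps are flattened before concatenation. Flattening makes
  channels with different filter heights concatenate cleanly, and local
  pooling preserves coarse position information, which matters when the
  discriminative context sits at a fixed offset from the central U: with
  global max-over-positions pooling the model cannot distinguish a motif at
  the planted position from a chance match anywhere else in the window, and
  on the package's own synthetic recovery check this measurably caps
  held-out accuracy well below what a position-aware linear model attains.
  Local pooling also matches the observation that the concatenation
  "significantly increases" the parameter count, which is what motivates
  the wide dense layer plus dropout. Global pooling remains available as
  `pool_size = Inf` and is covered by the tests.
* **Filters per channel** is never specified in the source description;
  the default is 32, configurable — a standard choice for datasets of a few
  hundred sequences that keeps single-CPU training in the minutes range.
* **One filter height for all channels** is the default (`filter_heights`
  is recycled), matching the tuned single "height of filters" value; a
  per-channel height vector realizes the multi-size reading of the
  architecture and is fully supported.
* **Exactly two dense layers** follow the concatenation: 1024-unit ReLU,
  then the 2-unit softmax. Dropout is applied only after the 1024-unit
  layer.
* **Class order** is (negative, positive); the positive-class probability
  feeds ROC curves. Hard labels are the argmax, with an exact 0.5/0.5 tie
  resolved to the positive class so predictions are deterministic.

Training minimizes mean categorical cross-entropy with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), shuffled
minibatches, and inverted dropout. Early stopping monitors validation loss
with a default patience of 10 epochs (unspecified in the source; 10 is a
common default at these data sizes) and restores the best weights. Every
stochastic element — He/Glorot initialization, shuffling, dropout, the
internal validation split — derives from the configuration seed, so a seed
fixes the entire training history. The forward/backward passes are plain
matrix algebra (im2col convolution, argmax-routed pooling gradients), and
the test suite verifies the analytic gradients against central finite
differences on every parameter array.

Defaults follow the values selected by the staged search for the 21-nt
window sets: batch 16, up to 50 epochs, 9 channels, filter height 5,
learning rate $5 \times 10^{-4}$, dropout 0.5.

## Hyperparameter tuning

`staged_grid_search()` reproduces the three-stage protocol with stratified
5-fold cross-validation: stage 1 tunes batch size and epoch budget, stage 2
the channel count and filter height, stage 3 the learning rate and dropout
probability, each stage holding everything else at the base configuration
or at earlier winners and carrying its best mean CV accuracy forward.
Details the protocol leaves open, fixed here:

* Base values for not-yet-tuned hyperparameters: 7 channels, height 5,
  learning rate $5 \times 10^{-4}$, dropout 0.5 — mid-grid values.
* The held-out fold doubles as the early-stopping validation set, and the
  fold's accuracy at the early-stopped epoch is the CV accuracy.
* Folds are stratified by label, seeded, and shared across combinations.
* Ties go to the earlier combination in candidate-list order.
* Tuning is intended to run on the merged-seq encoding; both encodings are
  then trained with the tuned values.
* A combination whose training fails is excluded with a warning rather
  than aborting the search.

Grid candidates default to the full original ranges; the bundled tests use
restricted grids because a fit count of $k \cdot \sum_s \prod_j |C_{sj}|$
grows quickly (the full stage-2 grid alone is $16 \times 5$ fits).

## Evaluation

`compute_metrics()` gives sensitivity TP/(TP+FN), specificity TN/(TN+FP),
accuracy (TP+TN)/total, and the Matthews correlation coefficient in its
standard form
$(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$.
Any metric with a zero denominator is returned as an explicit `NA`
("undefined"), never a silent `NaN`, so degenerate cross-validation folds
cannot poison stage means. On balanced data, accuracy equals
(SN + SP)/2, which the suite checks.

`roc_auc()` builds the ROC point list by threshold sweeping (tied scores
collapse into single steps) and integrates by trapezoid, which equals the
rank statistic; it is cross-checked against an independent implementation
in the tests. `relative_improvement()` implements the
$100 (new - old)/old$ comparison arithmetic; its 2-decimal display rule
*truncates toward zero* because that is the convention the published
comparison tables follow (e.g. $11.24/68.76 = 16.3467\%$ is printed 16.34,
not 16.35). `comparison_table()` lays package results alongside the
published results of prior predictors, which are carried as constants.

## From kernels to motifs

`extract_motifs()` converts trained first-layer filters into position
frequency matrices: each filter's activation is scanned over a dataset, and
every position scoring at least `activation_frac` (default 0.5, the
half-max rule used by DeepBind-style visualizations) of that filter's
maximum contributes its filter-height subsequence; subsequences are stacked
into a PFM. All qualifying hits count, not just one per sequence. Filters
with no positive activation are omitted. For merged-seq models each
(base, symbol) pair is projected to its base, so logos are 4-letter
nucleotide logos under either encoding. Information content per column is
$2 + \sum_b p_b \log_2 p_b$ bits against a uniform background.
`autoplot()`/`render_logo()` draw probability or information-content logos
as stacked letter columns whose segment heights equal the probabilities
(or bit shares); `write_meme()` exports PFMs in MEME minimal format.

## The synthetic generator

`generate_windows()` emulates the *structure* of the benchmark sets:
balanced classes, one fixed window length, a central U in every window
(negatives too — all real candidates are uridines, so the center must carry
no signal), positives with an enriched motif context near the center.
A positive draws each motif position as the consensus base with probability
`strength` and uniformly from the other three bases otherwise; negatives
are pure background. At `strength = 0.25` the classes are exchangeable; at
`strength = 1` every positive carries the exact consensus.

`strong_preset()` is the fixed recovery fixture: 200 windows per class,
$\xi = 10$, consensus `GACUCG` planted at offset −3 (so its U lands on the
forced central U and the planted and effective consensus coincide),
`strength = 0.95`, uniform background, seed 1. The preset is hash-pinned in
the tests so it cannot drift between versions. The suite verifies that the
default network at the selected hyperparameters reaches at least 0.90
held-out accuracy on this preset and that at least one extracted kernel PFM
recovers the planted consensus, and that separability is monotone in
`strength` (checked at 0.25 / 0.6 / 0.95 with a small network).

What the generator does **not** emulate: real Ψ sequence context (there is
no biological motif model behind the consensus), RNAfold thermodynamics
(synthetic structures come from the maximum-pairing folder), species
composition biases, or label noise. Passing the recovery checks therefore
demonstrates that the pipeline can learn and report a planted signal
end-to-end — not that it attains any particular accuracy on real benchmark
data, which must be supplied by the user.

## Problem sizes and runtime

The bundled tests and the reproduction script train on the 400-window
preset (and smaller sets for unit tests) with the default network; one such
fit takes on the order of a minute on a single CPU, and the full suite runs
in a few minutes. These sizes are the package's chosen test fixtures;
real window sets of a few hundred to a few thousand sequences train in the
same minutes range.

## Known limitations

* The built-in folder maximizes pair counts, not free energy; merged-seq
  results on real data should use RNAfold (or shipped structures).
* Training is single-threaded dense linear algebra; it is sized for
  window-classification problems (hundreds to thousands of sequences), not
  genome-scale scans.
* The staged grid search evaluates the full Cartesian product within each
  stage; the full original grid is hours of compute, so restrict candidate
  lists when exploring.
* Model archives are R serializations; they are not interchangeable with
  other frameworks.
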