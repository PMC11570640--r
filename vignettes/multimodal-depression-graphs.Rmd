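---
title: "Multimodal graph networks for depression detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal graph networks for depression detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdgraph)
```

## The problem

Major depressive disorder (MDD) alters both brain electrophysiology and
speech: resting-state EEG shows hemispheric asymmetries in frontal and
temporal regions, and depressed speech tends to have lowered pitch, reduced
energy and a flattened spectral envelope. `mdgraph` implements a multimodal
classifier that represents each recording as a graph — EEG electrodes as
spatially connected nodes, audio time-slices as a temporal chain — and learns
a hierarchical graph-convolutional representation of each modality before
fusing them with attention for binary MDD vs healthy-control (HC)
classification.

## Graph construction

**EEG.** Each electrode of the montage is a node. Two binary edge sets are
combined:

* *local edges*: each electrode is linked to its `k` nearest neighbours
  (default `k = 4`) by Euclidean distance on the 2-D projected montage
  coordinates, symmetrized. The choice of a k-NN rule is ours: a spatial
  connectivity rule is needed that works for any montage, and k-NN on
  projected coordinates is reproducible and montage-agnostic.
* *hemispheric-symmetry edges*: homologous left/right electrode pairs are
  connected, reflecting the diagnostic value of inter-hemispheric asymmetry.
  Because no canonical pair list exists for an arbitrary montage, the default
  pairs are derived by mirroring each left electrode across the midline and
  matching it to the nearest right electrode (`default_symmetric_pairs()`);
  a user-supplied two-column pair file overrides this.

The union is clipped to `{0, 1}` — downstream degree normalization expects a
connectivity pattern, not edge multiplicities. Self-loops are never stored;
they are added inside the convolution.

**Audio.** The recording is cut into `n_a = 32` equal-duration slices
(trailing remainder samples dropped, so all nodes are statistically
comparable); slice `j` connects to slices `j - 1` and `j + 1`, giving a chain
with `2(n_a - 1)` directed entries.

## Initial node features

**EEG reduction.** Raw per-channel feature vectors (any dimension; the
synthetic fixture uses 16 band-power-like summaries) are reduced by a single
neighbour-aggregation step: node `v`'s feature is concatenated with the mean
of its neighbours' features and passed through one trained linear layer with
ReLU,

$$h'_v = \mathrm{ReLU}\!\left(W\,[x_v \,\|\, \mathrm{mean}_{u \in N(v)} x_u] + b\right).$$

One hop only; isolated nodes use a zero neighbour mean. The default output
dimension is 600, sized for real high-density EEG; see *Problem sizes* below
for the fixture-scale setting.

**Audio slice features.** Each slice yields a 580-dimensional row of
frame-aggregated statistics across seven families: MFCC (64 coefficients plus
deltas), log-mel band energies (128 bands), pitch (autocorrelation tracker,
0 as the unvoiced sentinel), RMS energy, chroma, spectral contrast
(per-octave peak/valley) and tonnetz. The decomposition of the 580 columns is
a package choice recorded in `feature_manifest()`; statistics are the
frame-wise mean and standard deviation (frames: 2048 samples, hop 512).
All spectral primitives are implemented directly on `stats::fft`.

## The hierarchical graph encoder

Each modality is encoded by `K = 3` stacked units; one unit is:

1. **Graph convolution.**
   $H' = \mathrm{ReLU}\!\left(D^{-1/2}(A + I)D^{-1/2} H W\right)$.
   The self-loop renormalization is a deliberate completion: normalizing a raw
   adjacency is degenerate for isolated nodes, and `A + I` is the standard
   remedy.
2. **Information-score top-k pooling.** Node scores are the row-wise L1 norm
   of $(I - D^{-1}A)H$ — the distance between a node's features and its
   neighbourhood average; redundant nodes score low. The top
   `ceiling(pool_ratio * n)` nodes are kept (`pool_ratio = 0.5`; the ceiling
   guarantees at least one node), ties broken toward the lower index, indices
   returned in ascending order. The L1 norm follows the hierarchical-pooling
   literature this scoring descends from; L2 is available by configuration.
   `D` here uses the degrees of the current connectivity *without*
   self-loops; a fully isolated node's score is the norm of its own feature
   row.
3. **Sparsemax structure learning.** Pooling can disconnect closely related
   nodes. Pairwise scores
   $E(p,q) = \sigma(\mathbf{a}\,[H(p,:)\,\|\,H(q,:)]^T) + \lambda A(p,q)$
   are re-normalized row-wise by **sparsemax** — the Euclidean projection onto
   the probability simplex — producing a sparse, row-stochastic connectivity
   that replaces `A` for the next unit. Unlike softmax, sparsemax assigns
   exact zeros, so the learned graph stays sparse. The output is deliberately
   not re-symmetrized: each row is a distribution over targets, and the next
   unit's normalization handles asymmetric input. The bounded sigmoid is used
   inside the score; $\lambda$ (default 1.0) balances learned similarity
   against surviving edges and is kept as a fixed hyperparameter while the
   attention vector $\mathbf{a}$ is trained.

Each unit's pooled subgraph is read out as column means concatenated with
column maxima (`2d` values), and the `K` readouts are summed into the graph
embedding `f_g`. A depth of `K = 0` is defined as reading out the initial
features directly — the convention used by the depth-ablation grid.

## Fusion and classification

A channel-level (EEG) and slice-level (audio) attention over the *initial*
features produces $\alpha = \mathrm{softmax}(V \tanh(W X_0 + b))$ and the
context vector $f_b = \sum_i \alpha_i X_0(i,:)$. The modality embedding is
$f_b \,\|\, f_g$. Each embedding is gated elementwise by
$\sigma(w_{\text{modality}})$ (a Hadamard product that shrinks but never
sign-flips coordinates), the gated embeddings are concatenated, and a single
affine layer with softmax yields the two class probabilities. The head depth
and the cross-entropy loss are package choices; nothing deeper is needed for
this head.

Attention export reports (i) the dataset-averaged per-channel $\alpha$ and
(ii) per-family audio scores obtained by averaging the sigmoid gate values of
the audio `f_b` block within each family's column span of the acoustic
manifest — the manifest is what makes the family aggregation well-defined.
Both are also reported baseline-subtracted (minimum subtracted), the usual
convention for attention rankings.

## Training

There is no automatic-differentiation framework in the package's dependency
set, so the backward pass is derived analytically per module — including the
sparsemax Jacobian (identity-minus-mean on the support) and the gradient of
the symmetric degree renormalization with respect to the learned adjacency —
and verified against central finite differences in the test suite. Top-k
index selection is treated as piecewise-constant (no gradient), the standard
treatment for top-k pooling. Training is minibatch Adam (default learning
rate `1e-3`, batch 32, at most 100 epochs) with early stopping once the
epoch-mean training loss plateaus. All parameter initialization and batch
shuffling derive from one seed, making every run bit-reproducible.

Feature standardization (per EEG channel-feature cell, per audio column) is
fit on the training split only and applied to validation data.

## Cross-validation and ablation

Evaluation uses stratified 10-fold cross-validation with **subject-level**
folds by default: all segments of one subject stay in one fold. Segments of
one subject are correlated (they share a subject random effect in the fixture
and subject idiosyncrasy in real data), so segment-level splitting would leak
identity information into validation; a `split_unit = "segment"` flag
preserves the alternative for comparison. The positive class for
precision/recall/F1 is MDD, and fold metrics are averaged with a plain mean
(confusion matrices are not pooled). The ablation grid fixes one modality's
unit count at 3 and varies the other over 0–4, one cross-validation per cell.

## The synthetic fixture

Real paired EEG/interview-audio depression corpora are access-controlled, so
the package ships a generator that emulates the *layout* of such a study: 22
depressed and 29 control subjects, 29 paired segments each (638 + 841 = 1479
samples), 128 EEG channels on a mirrored ring montage, 32 audio slices per
sample. Class structure is injected where the clinical literature and the
attention analyses place it:

* EEG: a mean shift of `effect_size * noise_sd` on a designated
  frontal/temporal channel subset, stronger on the left hemisphere and weaker
  on the right (`asym_frac = 0.5`), plus a per-subject, per-channel random
  effect (`subject_sd = 0.3`) shared across a subject's segments;
* audio: the shift applied to the pitch and energy feature families and, at
  half strength, to the mel band means — either directly in the slice-feature
  matrix or, in waveform mode, as a lowered fundamental (150 vs 210 Hz) and
  reduced amplitude of a tone-plus-noise signal.

Defaults `effect_size = 1.0` and `noise_sd = 1.0` are fixture parameters —
strong enough that a linear probe on pooled channel means separates the
classes, which is what makes the end-to-end learnability checks meaningful.
The named signal-channel subset lets the channel-attention export be tested
for enrichment on channels that actually carry class signal — a quantitative
stand-in for qualitative topographic attention maps.

What the fixture does **not** emulate: real EEG spectra and artifacts,
volume-conduction correlations between neighbouring channels, natural speech
(the waveform mode is a stationary tone plus noise), demographic covariates,
and any distribution shift between sites. Passing tests demonstrate that the
pipeline learns and localizes planted, well-conditioned signal; they do not
certify performance on clinical data.

## Problem sizes used by the package's evaluation runs

`fixture_model_config()` documents the desk-scale settings used by the test
suite and the acceptance script: reduced EEG dimension 64 (the fixture's 16
raw features per channel make a 600-dimensional projection pointless),
hidden width 16, attention width 16, two Adam epochs at learning rate
`3e-3`. On the strongly separable fixture the training loss reaches the
1e-4 scale within two epochs, so longer schedules only add runtime.

## Numerical choices and degenerate inputs

* Sparsemax uses the sorted-threshold algorithm; ties and one-element inputs
  are exact (`[1]` maps to `[1]`).
* Duplicate montage coordinates: k-NN ties resolve to the lower channel
  index, deterministically.
* Silent audio: RMS 0, pitch 0 (unvoiced sentinel), zero chroma/tonnetz,
  zero spectral contrast — never NaN.
* Single-node graphs: convolution reduces to the activated linear map,
  structure learning to the trivial simplex `[[1]]`, readout to the node
  itself.
* Zero-denominator metrics return 0 with an explicit flag rather than NaN.
* Fixture matrices are serialized with 17 significant digits so the
  write/read round trip is bitwise exact.

## Known limitations

* The graph encoder is dense; no sparse-matrix or GPU path. Intended problem
  sizes are hundreds of nodes, not tens of thousands.
* The analytic backward pass covers the shipped architecture; changing the
  readout or score definitions requires updating the corresponding gradient.
* The pitch tracker is a plain autocorrelation peak-picker; it is adequate
  for the fixture's tones and clean speech-like signals, not for noisy
  polyphonic audio.
* Real-data adapters (EEG preprocessing, artifact rejection, forced
  alignment of interview audio) are out of scope; the package consumes
  channel-by-feature and slice-by-feature matrices.
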