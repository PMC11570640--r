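# mdgraph

Multimodal graph neural networks for detecting major depressive disorder
(MDD) from paired EEG and speech recordings, implemented in pure R with
hand-derived gradients.

## Who this is for

Researchers in computational psychiatry and biomedical signal processing who
want a transparent, dependency-light reference implementation of
graph-based multimodal classification: every operation — graph construction,
graph convolution, hierarchical pooling, sparsemax structure learning,
attention fusion, backpropagation — is plain, tested R code that can be read,
modified and verified against the brute-force oracles shipped in the test
suite.

## The model

Each recording becomes a graph per modality:

* **EEG**: electrodes are nodes; edges combine k-nearest-neighbour spatial
  connectivity on the projected montage, `A_init`, with homologous
  left/right hemispheric-symmetry pairs, `A_sym`; the adjacency is the
  clipped union `A = min(A_init + A_sym, 1)`. Raw channel features are
  reduced by one neighbour-aggregation step
  `h'_v = ReLU(W [x_v ‖ mean_{u∈N(v)} x_u] + b)`.
* **Audio**: the waveform is cut into 32 equal slices, each a node in a
  temporal chain (`A[j,k] = 1` iff `|j−k| = 1`) with a 580-dimensional
  feature row per slice (MFCC, mel, pitch, energy, chroma, contrast,
  tonnetz).

Each modality is encoded by three stacked units of

1. graph convolution `H' = ReLU(D^{-1/2}(A+I)D^{-1/2} H W)`,
2. top-k pooling by the information score `‖(I − D^{-1}A)H‖₁` per node,
3. sparsemax structure learning
   `S(p,·) = sparsemax(σ(a[H(p,:)‖H(q,:)]ᵀ) + λA(p,·))`,

with a mean‖max readout per unit summed into the graph embedding `f_g`.
Channel/slice attention over the initial features yields a context vector
`f_b`; the gated concatenation of both modalities' `f_b ‖ f_g` embeddings
feeds a softmax classifier. Training is minibatch Adam on the cross-entropy
with analytically derived gradients (verified against finite differences —
there is no autodiff dependency).

Evaluation is stratified 10-fold cross-validation with subject-level folds
(all segments of a subject stay together), reporting ACC/PRE/REC/F1 with MDD
as the positive class, plus a depth-ablation grid and attention exports per
electrode channel and per acoustic feature family.

Because real paired EEG/audio depression corpora are access-controlled, the
package ships a fully seeded synthetic fixture emulating such a study's
layout (22 + 29 subjects × 29 segments = 1479 samples, 128 channels, 32
slices) with class signal planted in frontal/temporal channels
(left-stronger asymmetry) and in pitch/energy/mel features.

## Worked example

```r
library(mdgraph)

fx <- generate_dataset(fixture_config(n_mdd_subjects = 10, n_hc_subjects = 10,
                                      segments_per_subject = 12,
                                      n_eeg_channels = 64, n_audio_slices = 16,
                                      seed = 42))
fx
#> Synthetic paired EEG/audio fixture: 240 samples (120 MDD, 120 HC), 64 channels

cfg <- fixture_model_config(epochs = 3)   # desk-scale sizes, see the vignette
report <- run_cv(fx, cfg, k = 5, seed = 42)
report
#> 5-fold CV (subject split): ACC 98.75%  PRE 97.78%  REC 100.00%  F1 98.82%

model <- train_model(fx, cfg, seed = 42)
att <- export_attention(model$attention$channel, model$attention$channel_labels,
                        audio_gate = model$attention$audio_gate,
                        manifest = fx$acoustic_manifest)
head(att$features[order(-att$features$score), ], 3)
#>   feature_family     score baseline_subtracted
#> 3          pitch 0.5151182         0.018230876
#> 2            mel 0.5045825         0.007695198
#> 4         energy 0.5040221         0.007134834
```

The cross-validation means say the subject-held-out classifier separates the
two classes almost perfectly on this fixture; the feature-family table ranks
pitch, mel and energy highest — exactly the families in which the generator
plants the class signal. The channel attention is likewise enriched on the
signal-bearing frontal/temporal channels (0.020 vs 0.013 mean score in this
run).

Command-line wrappers for fixture generation, audio feature extraction,
cross-validation and the ablation grid live in `inst/scripts/`.

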