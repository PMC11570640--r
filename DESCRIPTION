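Package: mdgraph
Title: Multimodal Graph Neural Networks for Depression Detection from EEG and Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds graph representations of multichannel EEG recordings
    (montage-based local connectivity plus hemispheric-symmetry edges) and of
    sliced speech recordings (temporal chain graphs with MFCC, pitch, energy,
    mel-spectrum, chroma, contrast and tonnetz slice features), and classifies
    major depressive disorder versus healthy controls with a hierarchical
    graph-convolution model: stacked units of graph convolution, information-score
    top-k pooling and sparsemax structure learning, followed by channel/slice
    attention, modality gating and a softmax head. Includes a fully seeded
    synthetic fixture emulating a paired EEG/audio study layout, subject-level
    stratified cross-validation, ablation grids over graph-convolution depth,
    and attention-score export per electrode channel and acoustic feature family.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
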