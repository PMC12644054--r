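---
title: "Multimodal dynamic-graph monitoring of sleep pathology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal dynamic-graph monitoring of sleep pathology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepgraph)
```

## The monitoring problem

Laboratory polysomnography is the reference standard for diagnosing sleep
pathology, but it is expensive and intrusive. A contact-free alternative is
to observe two passive streams — ambient audio of breathing and a low-rate
facial camera — and classify each 30-second analysis window (50% overlap)
into one of `K` severity categories, while also localizing pathological
*episodes* in time. `sleepgraph` implements this pipeline end to end:
deterministic acoustic features, a facial attention encoder, a dynamic
heterogeneous graph over both modalities, attention-based message passing and
fusion, a causal temporal stack, a four-term training objective, and a
clinical-style evaluation suite. A synthetic session simulator with planted,
labeled episodes makes every stage testable without recordings.

## Acoustic features

Audio is framed (2048-sample frames, hop 512 at full scale; 64/32 at desk
scale) and each frame is summarized by

* cepstral coefficients: the orthonormal DCT-II of `log(max(PSD, 1e-10))`,
  truncated to the first `n_cepstra` (13 at full scale). An optional
  128-band mel filterbank can pool the PSD first (MFCC-style); the raw-PSD
  form is the default because it is the form the equations define,
* zero-crossing rate `(1/2N) * sum |sgn(a[n]) - sgn(a[n-1])|` with
  `sgn(0) = 0`, so a sample that touches zero contributes two half-crossings,
* RMS energy,
* the spectral centroid and the second central moment of the magnitude
  spectrum over bin index. Descriptions of this feature family sometimes
  label the second moment a "rolloff"; the implemented quantity is a spread,
  exposed as `sro` with the alias `spectral_spread`,
* per-band summaries (log-energy and population standard deviation) of a
  `J`-level periodic DWT. The mother wavelet (`db4` by default, Haar
  available for exact tests) and the reduction from band coefficients to
  features are open design choices; summaries keep the feature length fixed
  across frames.

The per-frame vector `a_t = [C; ZCR; RMS; SC; SRO; W]` is averaged over the
frames whose centers fall in each analysis window. Feature extraction is a
pure function: identical inputs give identical outputs.

## Facial encoding

Frames (images or precomputed per-frame feature vectors; the simulator uses
vectors by default) are encoded per window. In image mode a small residual
backbone with cardinality-grouped convolutions and global average pooling
produces per-frame features; the full-scale cardinality is 32, the desk
backbone uses 3 stages of width 16 on 32x32 grayscale frames. Within a
window, up to 16 frames (the context cap) act as tokens for multi-head
spatial self-attention; the pooled result is gated elementwise by a temporal
attention vector `softmax(W_t tanh(W_f f_raw + W_h h_prev))`. Combining a
`d_f`-vector gate with a spatial attention map admits several readings; we
apply the spatial attention to the values, average-pool over positions to a
`d_f` vector, and then gate elementwise — preserving both mechanisms with
the declared output shape. The hidden state carried across windows is the
previous window's output (`h_t := f_t`), the simplest recurrence with the
intended temporal-context effect.

## Dynamic heterogeneous graph

Each modality contributes one node per window; projections `W_f f + b_f`,
`W_a a + b_a` map both into a shared `d`-dimensional node space. The graph
over a trailing context of `temporal_radius` windows (trailing, so the whole
representation stays causal) connects intra-modal nodes within the radius and
cross-modal nodes that are co-windowed or radius-neighboring — a design
choice (denser wirings are subsumed by a larger radius). The "maximum
connectivity 85%" parameter caps the realized fraction of the complete pair
graph, enforced by deterministically dropping the longest-gap pairs first.

Edge weights mix three terms,
`w_ij = lambda1 * alpha_temp + lambda2 * alpha_cross + lambda3 * exp(-gamma |t_i - t_j|)`
with `lambda = (0.4, 0.4, 0.2)` and `gamma = 0.1`: a temporal attention
softmax over each origin node's full neighborhood (all edge types pooled —
a per-type softmax is a reasonable alternative and the neighborhood choice
is isolated in one function), a sigmoid gate on `[x_i || x_j || x_i * x_j]`,
and an exponential decay in the timestamp gap. The temporal attention is directional, so the stored graph is
directed; undirected consumers (the convolution) symmetrize by averaging.

## Message passing, fusion, temporal stack

The network alternates two layer types over the configured widths
(512/384/256/128 at full scale, 32/32 at desk scale):

* **multi-scale graph convolution** `H' = sigma(sum_s A_hat_s H W_s)` over
  `S = 4` scale adjacencies, realized as the weighted graph restricted to
  `|dt| <= s * stride` — each scale sees a progressively wider temporal
  band. Self-loops are added before the symmetric normalization
  `D^{-1/2} A D^{-1/2}` so isolated nodes keep unit degree (configurable
  off).
* **temporal-aware graph attention** with logits
  `LeakyReLU(a' [W h_i || W h_j || phi(t_i, t_j)])`, a softmax over
  `N_i` plus a mandatory self-loop, and interleaved sin/cos time encodings.
  Heads (4 at full scale) are concatenated and linearly mixed.

Layers of equal width add an identity skip — standard practice in this model
family and important here because a randomly-initialized deep stack otherwise
over-smooths the per-window signal (see *Training regime*).

Per-window modality summaries (mean-pooled node embeddings; each window has
one node per modality, so pooling is the identity here) are fused by
bidirectional cross-modal attention,
`h_fused = LayerNorm(h_f + Attn_{a->f}) + LayerNorm(h_a + Attn_{f->a})`.
In the unimodal ablations the fusion degenerates to the layer-normalized
single stream.

The fused sequence then passes a strictly causal temporal stack: a
graph-embedded GRU (standard gated recurrence on the fused states; states
provably stay in `[-1, 1]`), a hierarchical decomposition whose per-level
filter banks are
seeded from dilated wavelet taps over lookbacks `Delta_l = 2^l * base`
(the high-pass bank annihilates constant histories), a stack of dilated
causal convolutions (kernel 3, dilations 1/2/4/8), and dilated causal
self-attention with radius 16 and an additive positional table. The causal
mask sends future keys and keys beyond the radius to `-Inf` before the
softmax and combines additively with the logits (standard masked-softmax
semantics) — real-time monitoring forbids any dependence on later windows.
A bit-exact test verifies that perturbing all inputs after window `t`
leaves every output at or before `t` unchanged.

## Objective

Four terms, weighted `1.0 / 0.3 / 0.2 / 0.1`:

* **focal classification loss** with inverse-frequency class weights
  normalized to mean one (so balanced data recovers uniform weights) and
  focusing exponent `gamma = 2`,
* **temporal consistency**: squared prediction changes weighted by
  `exp(-beta * cos_sim(h_fused,t+1, h_fused,t))`, `beta = 0.5`, so
  transitions are cheap when the representation itself moved,
* **cross-modal contrastive (InfoNCE)** at temperature `tau = 0.1`, positives
  being all same-label facial/audio pairs in the batch, the denominator
  running over every audio embedding including the positive (the most common
  convention). `contrastive_loss()` returns the unreduced pair sum; the
  training objective uses the mean over positive pairs so the term's scale
  does not grow with batch size,
* **reconstruction**: squared error of single-hidden-layer decoders mapping
  the fused state back to both (standardized) feature streams.

## Training regime

Training uses AdamW (weight decay 1e-4, batch = 16 contiguous windows per
step), a cosine annealing schedule with warm restarts between 1e-6 and 1e-3
(cycle 20 epochs, doubling after each restart, the common convention),
gradient clipping at a threshold that adapts
to an exponential moving average (decay 0.99) of observed gradient norms,
early stopping with patience 10, and checkpoint averaging over the top-3
validation checkpoints (kept only when the average scores at least as well
as the single best).

The deep encoder — facial attention encoder, edge-weight model, graph
network, fusion, temporal stack — is **fixed at its seeded initialization**,
and the objective is optimized over the readout stack: the classification
head (a tanh-hidden MLP on the standardized concatenation of fused state,
temporal state and per-window modality summaries), linear projection heads
for the contrastive term (the usual projection-head construction), and the
reconstruction decoders. This reservoir-style regime is a deliberate design
choice: at the package's study sizes the seeded encoder already preserves the
discriminative structure (the skip connections above are what make that
true), gradients for the readout are small closed-form expressions that we
verify against numerical differentiation in the test suite, and encoding can
be cached so training cost is independent of encoder depth. Its limitation
is equally explicit: the encoder is not adapted to the data, so tasks whose
signal the random encoder destroys would need end-to-end gradients that the
package does not provide. Dropout (0.3) is applied to the head's hidden
layer at a constant rate.

Two floors are worth noting because they bound what "training loss goes to
zero" can mean. The InfoNCE term cannot drop below `log(n_same)` per positive
pair (collapsing same-class embeddings is optimal), and the reconstruction
term is bounded by what a lossy fused code retains. The memorization test
therefore asserts convergence on the classification term, which is the term
memorization concerns.

## The simulator and what passing tests mean

`simulate_session()` builds 915-second sessions (60 windows of 30 s at 50%
overlap) of breathing-band noise under a 0.7 + 0.3 sin(2 pi 0.25 t) envelope
plus Gaussian noise, paired with per-frame facial feature vectors (2 Hz,
16-dim at desk scale; rendered blob images exercise the conv backbone in
image mode). Episodes arrive as a homogeneous Poisson process per class
(8/hour in the desk study), with durations uniform on 60-150 s snapped to
the 15-s stride grid and kept non-overlapping; windows take an episode's
label when at least half the window overlaps it. Class signatures: apnea-like
episodes multiply the envelope by 0.25; restless episodes add facial burst
offsets; cardiovascular episodes double the envelope frequency; emergency
episodes combine suppression and bursts. With `crossmodal_xor` on, the
highest class instead flips the product of two binary latents — a facial
latent `u` (loading on the first half of the feature dims, carried by the
blob position in image mode) and an audio latent `v` (selecting one of two
carrier tones) — to `-1` inside episodes while both marginals stay symmetric.
By construction neither modality alone identifies that class; recovering it
is direct evidence that the cross-modal pathway carries information, which
is the qualitative analogue of a modality-ablation study.

The desk study (40 sessions, seed-derived session seeds, stratified 70/15/15
split by dominant pathological class) is sized to run on one CPU in minutes:
sessions use 100 Hz audio (so carrier tones sit at 10/20 Hz), model
dimensions are 32 or less, and training runs 30 epochs. These are the
problem sizes used by the test suite and the acceptance script.

What the simulator does **not** emulate: real breath acoustics, room
reverberation or device variation; facial appearance, pose, occlusion or
landmark noise; inter-patient variability; annotation noise. Passing the
planted-signal study shows the pipeline's computation recovers the signals
it is supposed to recover — it says nothing about clinical performance on
recordings, which the package has no data to assess.

## Numerical choices and degenerate inputs

* `sgn(0) = 0` in the zero-crossing rate; log floor `1e-10` before the
  cepstral DCT; InfoNCE and focal logs clamped at `1e-12`.
* An all-zero magnitude spectrum returns the sentinel `SC = SRO = 0` with a
  warning; an empty signal is an error by default (configurable to an empty
  output).
* Zero-norm vectors have cosine similarity 0 (temporal-consistency weights
  and contrastive similarities stay finite).
* A node with an empty neighborhood receives temporal attention 0; GAT
  always includes the self-loop, so an isolated node attends to itself.
* Queries whose radius excludes everything else attend to themselves (the
  self key is always in radius).
* The connectivity cap drops longest-gap pairs first with ties broken by
  node ids; all such tie-breaks are deterministic.
* Expected agreement 1 in Cohen's kappa returns 1 for perfect agreement and
  0 otherwise, with a warning; single-class truth makes AUCs `NA` with a
  warning. PR-AUC uses step interpolation (conservative), ROC-AUC the
  trapezoid rule. Macro averages exclude classes absent from both truth and
  prediction.
* Event matching is greedy one-to-one by descending IoU with `tau = 0.5`;
  overlapping same-label true spans are merged with a warning; detection
  delay is the first correctly-labeled window center at or after onset minus
  the onset.
* Features, head inputs and reconstruction targets are standardized with
  training-split statistics (stored on the fit); without this the tanh head
  saturates.

## Known limitations

* No end-to-end encoder gradients (see *Training regime*).
* The graph is rebuilt per window over a sliding context; there is no
  incremental streaming update.
* HDF5 interchange is not provided; facial streams and feature tables use
  CSV, audio uses 16/24-bit PCM WAV, labels and reports JSON, configs YAML.
* Window-level labels inherit the >= 50% overlap rule's ambiguity at episode
  boundaries; with 50% window overlap the boundary windows mix episode and
  background signal at half strength, which bounds achievable window accuracy
  below 1 even for a perfect detector.
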