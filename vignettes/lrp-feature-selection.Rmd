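---
title: "Relevance-guided feature selection for motor-imagery EEG decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relevance-guided feature selection for motor-imagery EEG decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lrpselect)
```

## The problem

Motor imagery (MI) — imagining a movement without executing it — modulates
the sensorimotor mu (8–13 Hz) and beta (13–30 Hz) rhythms of the EEG:
during imagery, the rhythm amplitude over the corresponding cortical region
drops (event-related desynchronization, ERD). Brain–computer interfaces
decode these modulations from multichannel EEG, today most often with
compact convolutional networks (EEGNet, DeepConvNet, ShallowConvNet). The
feature maps these networks extract are not uniformly useful: EEG is noisy
and highly subject-specific, and a fraction of the extracted features is
irrelevant or even counter-productive for classification.

`lrpselect` implements a relevance-guided feature-selection step between
feature extraction and classification:

1. **(A)** a backbone network, split into a convolutional feature extractor
   `F` and a single dense classifier `C`, is trained end to end;
2. **(B)** the class score of each training trial is redistributed backwards
   through `C` onto the feature map with the epsilon-stabilized layer-wise
   relevance propagation (LRP) rule, the per-trial relevance maps are
   aggregated into one importance profile, and the lowest-importance
   fraction of feature-map positions (10 % by default) is masked;
3. **(C)** `C` is retrained on the masked features while `F` stays frozen,
   and the masked classifier is evaluated on the held-out session.

Classical selectors (ANOVA F, mRMR, RFE) are provided as drop-in
replacements for the LRP profile, and a synthetic MI-EEG generator with
planted ERD makes the whole pipeline testable without external recordings.

## The LRP rule

For a dense layer with inputs $x_i$, weights $w_{ij}$ and upper-layer
relevance $R_j$, the epsilon rule redistributes relevance proportionally to
the contributions $z_{ij} = x_i w_{ij}$:

$$R_i \;=\; \sum_j \frac{z_{ij}}{\sum_{i'} z_{i'j}
  \;+\; \epsilon\,\mathrm{sign}\!\big(\sum_{i'} z_{i'j}\big)}\; R_j .$$

The starting relevance is the **pre-softmax** class score $f(x)$ at the
target class (softmax would break the additive decomposition). Three
properties anchor the implementation and its tests:

* **Conservation.** With $\epsilon = 0$ and no bias terms, the relevance sum
  at every layer equals $f(x)$ exactly; `conservation_audit()` reports the
  per-layer deviation. Bias terms absorb relevance (the rule's $z_{ij}$
  excludes $b_j$), and $\epsilon > 0$ leaks a small amount, which grows
  monotonically with $\epsilon$ — both are reported, not hidden.
* **Closed form for one layer.** Through a single dense unit the rule
  reduces to the $x_i w_i$ decomposition of the score, which the test suite
  checks on random instances.
* **Convention.** $\mathrm{sign}(0) := +1$, so a zero pre-activation sum
  with $\epsilon > 0$ is well-defined; with $\epsilon = 0$ it is an error.

Defaults: $\epsilon = 10^{-6}$ (negligible leakage on unit-scale features);
relevance is computed with respect to the **true label** on training trials
(the importance question is "what supports the correct class"); the
predicted-label rule is available for inference-time analysis. The default
pipeline propagates relevance from the class score through `C` onto the
feature map only; generic epsilon rules for convolution and average-pooling
layers ship for deeper propagation but are not part of the default pipeline.

## Ranking, masking, retraining

Per-trial relevance is aggregated position-wise over training trials. The
default ranking, `abs_mean`, averages the **signed** relevance over trials
and then takes its magnitude. The signed average is the natural trial-level
aggregate (it is what relevance heatmaps display, and noise contributions
with varying sign cancel across trials), but ranking by the signed value
itself would put the most *counter-evidential* positions at the bottom —
and consistent counter-evidence is class-informative, not irrelevant. A
classifier retrained on only those bottom positions decodes well above
chance, contradicting the defining property of "low importance": that the
lowest-ranked features are class-irrelevant and support only chance-level
classification. Under `abs_mean`, irrelevant positions aggregate to ≈ 0
and rank lowest, while strong evidence of either sign ranks high; this
restores the expected behaviour of the bottom-only control. Both
alternatives (`mean_signed`, `mean_abs`) remain available as configuration.
`build_mask()` masks exactly `floor(fraction * N)` positions, breaking
score ties by ascending position index so masks are reproducible.

One mask is computed per (subject, backbone, seed) from the **training
session only** and applied unchanged to test trials; per-trial masking
would leak test information. Retraining warm-starts `C` from its trained
weights (the procedure "re-trains the classifier used previously";
cold-start is available) and verifies by checksum that no extractor
parameter changed — a freeze-contract violation is a hard error, not a
warning.

## Backbones without a deep-learning framework

The package authors its own small feed-forward engine (grouped 2-D
convolution via im2col/GEMM in RcppArmadillo, batch normalization, ELU /
square / log activations, average and max pooling, inverted dropout, Adam
and RMSProp with cosine-annealing or exponential schedules). All gradients
are validated against central finite differences in the test suite. The
three backbones follow their original publications:

* **EEGNet** — temporal convolution with kernel length half the sampling
  rate (1 × 125 at 250 Hz), depthwise spatial convolution spanning all
  channels (e.g. 22 × 1) with a max-norm constraint of 1, a separable
  convolution block, average pooling 1×4 and 1×8, dropout 0.5 (the original
  within-subject setting), and a dense classifier with max-norm 0.25.
  Temporal kernels are rounded up to odd lengths so same-padding preserves
  the time axis exactly (125 stays 125; a 62-sample kernel becomes 63).
* **DeepConvNet** — four convolution blocks with max pooling (25/50/100/200
  filters, 1×10 temporal kernels), ELU, dropout 0.5.
* **ShallowConvNet** — 40 temporal filters (1×25), a spatial filter across
  channels, batch norm, squaring, average pooling 1×75 with stride 15, log,
  dropout 0.5. Its terminal dense layer is the classifier `C`; this is the
  declared reading of the extractor/classifier split for this architecture.

Training configurations mirror the two common MI settings: Adam, learning
rate 0.002, cosine annealing, batch 72; and RMSProp, learning rate 0.001,
exponential decay, batch 5. Epoch counts are not fixed by the procedure
being reproduced; the package default is 200, and the bundled desk-scale
configurations use fewer (below). Retraining uses Adam 0.002 with cosine
annealing and a batch of one quarter of the training-set size, for 60–100
epochs. A fixed integer seed drives initialization, shuffling and dropout,
making every training run bit-reproducible.

## The synthetic generator

`generate_recording()` emulates a cue-based MI session:

* per-channel 1/f background noise plus a small (0.3×) component shared
  across channels — EEG is spatially correlated;
* ongoing band-limited mu and beta rhythms on every channel (unit and 0.6
  amplitude), generated by spectral masking of white noise;
* cue-locked 4-s imagery windows in which the rhythm amplitude on the
  labeled class's informative channels is multiplied by
  `1 - erd_depth`, with 0.25-s raised-cosine ramps to avoid spectral
  splatter at the window edges;
* exactly balanced classes in randomized order, two independent "sessions"
  (train/test) from two generator seeds.

Defaults mirror a standard 22-electrode, 250 Hz, four-class session with 72
trials per class; `erd_depth = 0.5` (a 75 % band-power drop, a strong but
realistic ERD) and unit background noise. With `erd_depth = 0` the planted
contrast vanishes; the attenuation follows the $(1-d)^2$ power law, which
the tests verify by band-power estimation on low-noise configurations.

What the generator does **not** emulate: eye-blink/EMG artifacts,
non-stationary drifts between sessions, volume-conduction mixing from a
head model, or subject idiosyncrasies. Passing tests therefore demonstrate
the machinery (training, relevance redistribution, masking, retraining,
evaluation) under a controlled, planted ground truth — not decoding
performance on real EEG.

## Preprocessing

Fixed order: band-pass 0.5–40 Hz (4th-order Butterworth, applied
forward-backward, so zero phase — the band is the stated choice, the filter
family/order is this package's declared default) → exponential moving
standardization (`factor_new = 1e-3`, `eps = 1e-4`, running statistics
initialized from the first 1 000 samples; the cited technique's customary
parameters) → optional anti-aliased decimation (8th-order Chebyshev-I,
integer factors only; event indices rescaled) → cue-locked epoching over
`[tmin, tmax)` with `round((tmax - tmin) * sfreq)` samples (−0.5 s to 4 s
around the cue by default, i.e. 1 125 samples at 250 Hz). Sample indices
are 0-based; tmin is inclusive, tmax exclusive.

## Numerical and design choices

* ANOVA importance is the vectorized one-way F statistic per feature, with
  the 0/0 := 0 convention for constant features; it is cross-checked
  against `stats::aov` in the tests.
* mRMR discretizes features into three quantile bins before estimating
  mutual information (continuous-MI estimators are estimator-dependent);
  greedy selection order is encoded into scores such that `build_mask()`
  reproduces the kept set exactly.
* RFE uses a closed-form ridge regression onto one-hot class indicators on
  standardized features (an L2-regularized linear classifier with a
  deterministic, exact fit), dropping 10 % of the remaining features per
  round by aggregate weight magnitude.
* The Wilcoxon signed-rank test drops zero differences, uses midranks for
  ties, and computes the exact two-sided p-value for n ≤ 25 by convolving
  the signed-rank null distribution (ties included); beyond that it uses
  the tie-corrected normal approximation with continuity correction. The
  exact branch is verified against full sign enumeration.
* Serialization uses RDS containers with JSON sidecar manifests; a minimal
  16-bit EDF reader/writer is included for interoperability (verified
  against an independent EDF reader in the tests), with cue events in a
  CSV sidecar since plain EDF has no annotation channel.

## Desk-scale study configuration

The bundled synthetic study (used by the acceptance script and the
heaviest tests) is sized for a single CPU: 16 channels at 250 Hz, four
classes, 100 trials per class and session, `erd_depth = 0.5`; preprocessing
decimates to 62.5 Hz (the mu band and most of the beta band lie well below
the 31.25 Hz Nyquist, and the pipeline's decimation step is part of the
procedure being exercised), giving 281-sample epochs and a 128-position
EEGNet feature map; backbone training runs 60 epochs of Adam (lr 0.002,
cosine annealing, batch 24 — the 400-trial desk configuration trains in
fewer passes with smaller batches than the 288-trial batch-72 preset),
classifier retraining 60 epochs. Under this configuration the acceptance
script's three control classifiers separate cleanly: the top-only and
masked (proposed) classifiers decode far above the 25 % four-class chance
level, and the bottom-only classifier falls far below both. The bottom-only
classifier does not reach chance itself on this synthetic study: the
planted ERD spans the whole imagery window, so after spatial filtering and
the ~1-s receptive fields of the extractor, some class information reaches
even the least important feature-map positions — a denser informative
structure than real motor-imagery EEG, where the corresponding control is
reported near chance. The test suite asserts the chance-level property as
stated and records this gap rather than masking it.

## Known limitations

* Relevance stops at the feature map; propagating past it into the
  extractor is out of scope here.
* Only the epsilon rule is implemented (no alpha-beta or z^B variants).
* The EDF writer quantizes to 16 bits over a per-channel integer range;
  round-trip error is bounded by range/2^16.
* GDF recordings are not read natively; convert to EDF (field-standard
  tools do this) or to the package container first.
* Training is CPU-bound and sized for desk-scale experiments, not for
  full-scale benchmark reproduction.
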