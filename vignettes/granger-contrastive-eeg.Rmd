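---
title: "Granger-causal spatial-temporal contrastive learning for EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger-causal spatial-temporal contrastive learning for EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grangercl)
```

## The problem

Emotion recognition from multichannel EEG faces two structural obstacles:
the spatial topology of the electrode montage carries *directed*
information flow between channels that undirected distance- or
correlation-based graphs cannot express, and the signals have a low
signal-to-noise ratio that makes label-hungry supervised models overfit.
`grangercl` implements a self-supervised answer to both: pairwise
Granger-causality tests orient and prune the electrode graph before a
residual graph-convolutional encoder consumes it, a frequency-domain top-K
filter manufactures denoised positive pairs for a temporal encoder whose
attention scores are themselves Granger-causality values, and both branches
are pretrained with an InfoNCE contrastive objective before a light
classifier is fine-tuned on labels.

A segment is a baseline-corrected 1 s window $X \in \mathbb{R}^{L \times V}$
($L$ samples, $V$ channels). The model learns
$f_\theta : X \mapsto Z \in \mathbb{R}^{F_e}$ with $Z = Z_T + Z_S$, the sum
of the temporal and spatial branch embeddings.

## The Granger-causality core

For channels $i$ (target) and $j$ (source), two nested autoregressions of
order $P$ are fitted by through-the-origin conditional least squares on rows
$P{+}1..n$:

$$x_{i,t} = \sum_{p=1}^{P} \alpha_p\, x_{i,t-p} + \varepsilon_{1,t},
\qquad
x_{i,t} = \sum_{p=1}^{P} \alpha_{1,p}\, x_{i,t-p}
        + \sum_{p=1}^{P} \alpha_{2,p}\, x_{j,t-p} + \varepsilon_{3,t},$$

and the directed influence is the log residual-variance ratio
$GC_{j \to i} = \ln\left(\mathrm{var}\,\varepsilon_1 /
\mathrm{var}\,\varepsilon_3\right)$. No intercepts are fitted: the
autoregressive models are specified without one and every signal entering
them is baseline-corrected (the synthetic generator is zero-mean by
construction). Significance uses the exact nested-OLS F statistic with
$(P,\, n - 3P)$ degrees of freedom.

Two decisions here were genuinely open:

* **Edge gate.** In-sample least squares guarantees
  $\mathrm{var}\,\varepsilon_3 \le \mathrm{var}\,\varepsilon_1$, so a literal
  "$GC > 0$" gate admits essentially every pair and prunes nothing. The
  default gate is therefore the F test at $\alpha = 0.05$; `gate = "raw"`
  keeps the literal reading available.
* **Lag order.** The channel-level test uses a fixed configurable order
  (default $P = 2$), with `select_lag_bic()` available as an opt-in scan.
  Fixed order keeps runs deterministic and comparable.

No multiple-testing correction is applied across the $C(C-1)$ ordered pairs
by default — the graph augmentation is a feature construction step, not an
inferential claim — but `granger_matrix(p_adjust = "BH")` provides one.

## Graph construction

Channel affinity decays with the square of the Euclidean electrode
distance, normalised into $(0, 1]$ by the calibration constant $\theta$:
$\mathrm{dist}_{ij} = \min(1,\, \theta / d_{ij}^2)$, with $\theta = 6$ by
default. The symmetric base adjacency keeps pairs with affinity
$\ge \delta$ (default $0.1$, boundary inclusive). The Granger augmentation
then keeps the *directed* edge $j \to i$ only where the base edge exists and
the $j \to i$ test passes; the same affinity threshold gates both steps
(a "$\le$" reading of the augmentation gate would retain only *distant*
channel pairs under the reciprocal-distance affinity, contradicting the
pruning intent, so both gates use $\ge \delta$). The orientation convention
is **row = receiver**: `adjacency[i, j] = 1` means information flows
$j \to i$, and every consumer (the GCN normalisation, `degree_flow()`)
honours it. Self-loops are excluded from the adjacencies; the encoder adds
them explicitly.

The scope of the estimated graph is configurable (`gc_scope`): the default
fits one graph per trial by re-stacking the trial's consecutive windows,
because a single 1 s window (128 samples) is short for stable VAR fits,
while a trial provides 60 s of data.

## Spatial branch: residual GCN

Node features are each electrode's raw baseline-corrected series (length
$L$); nothing about the architecture presumes hand-crafted features. One
graph convolution computes
$\mathrm{ReLU}\!\left(\hat{D}^{-1}_{\mathrm{in}} (A + I)\, X\, W\right)$,
where $\hat{D}_{\mathrm{in}}$ is the in-degree diagonal of $A + I$ — row
normalisation is the natural choice for a directed adjacency, for which the
usual symmetric normalisation is undefined, and the self-loop guarantees
every in-degree is at least one. Nine residual blocks of two convolutions
each follow ($G_{l+1} = F(G_l, W_l) + G_l$); the nine block outputs are
concatenated along the feature axis, mixed by a 1x1 convolution, and
max-pooled over nodes into a single vector, which a three-stage
1x1-convolution + batch-norm projector maps to $Z_S$. Zeroing a block's
weights makes it an exact identity, and the node pooling makes the fused
representation invariant to channel permutations (both are tested
properties).

## Temporal branch: Granger-Former

Every time point $t$ is expanded into the forward window
$x_t..x_{t+P-1}$ (zero-padded at the end), giving
$X_P \in \mathbb{R}^{L \times P \times V}$; linear maps produce
$Q, K, V \in \mathbb{R}^{L \times P \times F_e}$. The attention score
between positions $t$ and $s$ is the mean over a seeded subset of feature
dimensions of the Granger value of key-window $s$ onto query-window $t$
(source = key, target = query, lag `att_lag = 1`), so score$(t,s)$ reads
"position $s$ Granger-causes position $t$" — matching attention's
query-attends-to-key semantics. Scores pass ReLU then a row softmax; values
are collapsed over the window axis by their mean $\bar{V}$, and row $t$ of
the attention output is $\sum_s w_{ts} \bar{V}_s$. A residual addition of
$\bar{V}$, layer normalisation, mean pooling over time and a two-layer MLP
produce $Z_T$.

Three numerical decisions deserve a note:

* **Score contraction.** Mapping two $[L \times P \times F_e]$ arrays to an
  $[L \times L]$ matrix requires choosing a contraction; per-feature GC on
  the window series averaged over features is the one implemented, and it is
  isolated in `granger_attention_scores()` so alternatives can be swapped.
* **Differentiability.** GC scores are outputs of OLS fits; gradients
  through the F-ratio are ill-conditioned. Attention weights are therefore
  treated as constants in the backward pass — gradients flow through the
  value path, the layer norm and the projector. A corollary exploited
  throughout: since the query/key maps receive no gradient, the raw score
  matrix of a segment never changes during training and is cached.
* **Cost.** Scores cost $O(L^2 F_{\mathrm{sub}})$ tiny OLS fits per segment;
  they are computed in compiled code and the default
  `feature_subsample = 8` keeps a 64-sample segment's forward pass well
  under a second.

## Contrastive objective

Both branches share the InfoNCE loss at temperature $\tau = 0.1$:

$$\mathcal{L} = \frac{1}{N}\sum_{i=1}^{N} -\log
\frac{\exp(\mathrm{sim}(z_i, z_i^{+})/\tau)}
     {\exp(\mathrm{sim}(z_i, z_i^{+})/\tau)
      + \sum_{z^- \in D_i}\exp(\mathrm{sim}(z_i, z^-)/\tau)},$$

with cosine similarity and $\mathcal{L} = \mathcal{L}_S + \mathcal{L}_T$
unweighted. Spatial positives are segments of the *same video* from a
*different subject*, additionally aligned to the same within-video window
(`align_window = TRUE`) so positives are stimulus-aligned; spatial negatives
come from other videos. Temporal positives are the segment's top-K denoised
copy; temporal negatives are the other batch members. Negatives are
in-batch by default; a fixed-size FIFO queue of past embeddings
(`queue_size`) is available but off by default, because a momentum-encoder
machinery would be speculative where a plain in-batch InfoNCE is exactly
specified.

## Frequency-domain top-K denoising

A one-sided real FFT ($E = \lfloor L/2 \rfloor + 1$ bins) is taken per
channel, the $K$ bins with the largest amplitude
$\sqrt{\mathrm{Re}^2 + \mathrm{Im}^2}$ keep their complex values (phases
preserved), all others are zeroed, and the transform is inverted. The
default $K = 20$. Selection is per channel, preserving channel-specific
rhythms; ties at the $K$-th rank break toward the lower bin index so the
operation is deterministic and idempotent; the DC bin competes like any
other (baseline subtraction upstream makes it near zero anyway), with
`keep_dc = TRUE` reserving it a slot. Keeping bins can only remove energy
(Parseval), and $K = E$ recovers the input to numerical precision — both
are tested invariants.

## The synthetic generator

No real recordings ship with the package; all validation runs on sessions
the generator emulates after the structure of public EEG emotion protocols:
every subject watches the same ordered videos; each trial is a 3 s
pre-stimulus baseline followed by the emotion period; the signal is cut
into 1 s windows and the *average of the baseline windows* (a per-channel
window-length vector — the only reading under which the shapes match) is
subtracted from every emotion window. A 32-subject x 40-video session with
63 s trials yields 60 emotion windows per trial and 76,800 segments, which
the bookkeeping study verifies.

Class identity modulates two things, so that both branches carry label
information: per-channel band amplitudes (each class concentrates power at
class-specific frequencies on a class-specific channel block) and directed
VAR coupling (each class plants a different edge set, stationarity enforced
through the companion-matrix spectral radius, burn-in of 10 lags). Class
oscillations are *stimulus-evoked* — present only after the baseline —
because a tonic oscillation at an integer frequency is identical in every
1 s window and would be annihilated by baseline subtraction. Random phases
per trial and channel make the classes invisible to a plain linear readout
of the raw waveform, so the encoders must genuinely learn rectifying
features.

What the generator does *not* emulate: volume conduction and realistic
forward-model mixing, ocular/muscular artefacts, non-stationary drifts, and
inter-subject amplitude variability. Passing tests therefore demonstrate
that the machinery learns the structures it claims to exploit (directed
coupling, spectral class signatures, noise), not that it reaches any
particular accuracy on real recordings.

## Training protocol and frozen study designs

Pretraining uses Adam at learning rate $10^{-3}$, batch size 32, for a
configurable number of iterations (reference protocol: 3000); fine-tuning
adds a single linear softmax classifier on $Z = Z_T + Z_S$ and unfreezes
both encoders (batch size 256 and 100 epochs in the reference protocol).
Evaluation uses stratified five-fold cross-validation; the default
`split_unit = "trial"` keeps all windows of a trial in one fold to prevent
segment-level leakage, with `"segment"` available where a segment-level
protocol is wanted. The label-shuffle null permutes labels at the
split-unit level — under trial-level folds a segment-level shuffle would
place differently-relabelled windows of one trial on both sides of a fold
and systematically *anti*-predict.

The shipped studies run at reduced dimensions chosen as the package's
validation scale:

* *Classification*: 6 subjects x 6 videos x 3 classes, 8 channels at 64 Hz,
  11 s trials; encoders at `hidden_dim = 32`, `embed_dim = 32`; 150
  pretraining iterations, 30 fine-tuning epochs, five folds. Mean CV
  accuracy above 0.80 against a chance level of 1/3, with the shuffled
  control at chance, is the tested claim.
* *Robustness*: 4 subjects x 6 videos x 3 classes, 6 channels at 32 Hz,
  9 s trials, `top_k = 10` (the shorter window has only 17 one-sided bins).
  For five seeds, the full model and its mask-augmentation ablation are
  trained on identical sessions and evaluated under 20% additive Gaussian
  noise scaled to each channel's within-segment SD; the tested claim is that
  the denoising-pretrained model's accuracy drop is no worse (median over
  seeds) than the mask-pretrained one's.
* *Bookkeeping*: the full 32 x 40 protocol at 2 channels and 16 Hz —
  segment counts depend only on the trial structure, not on channel count
  or sampling rate.

Ablation switches mirror the framework's component analysis: either branch
can be disabled, the denoiser replaced by a random contiguous 10% zero-mask,
the Granger attention by scaled dot-product attention, and the GC
augmentation by random edge dropping at rate 0.2 per iteration (mask
coverage and drop rate are package choices; no reference values exist for
them).

## Known limitations

* Gradients deliberately do not flow into the query/key maps; those remain
  at their initialisation. If a trainable score path is wanted, a smooth
  surrogate for the GC statistic would be needed.
* One GC graph per trial assumes within-trial stationarity of the directed
  structure.
* The InfoNCE implementation loops over anchors; batch sizes in the
  hundreds are comfortable, but the implementation is not tuned for
  thousands.
* `simulate_session()` materialises the whole session in memory
  (~630 MB/channel-hour at 128 Hz in doubles); the bookkeeping study runs
  at 2 channels for exactly this reason.
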