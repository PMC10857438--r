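---
title: "Contrastive representation learning for ambient smart-home activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive representation learning for ambient smart-home activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorclr)
```

## The problem

Smart homes instrumented with ambient binary sensors — passive-infrared
motion detectors that report `ON`/`OFF` and door contacts that report
`OPEN`/`CLOSE` — produce long streams of timestamped events. Recognizing
activities of daily living (meal preparation, sleeping, bathing, ...)
from these streams is the basis of telemonitoring applications for older
adults living independently. The bottleneck is annotation: event logs
accumulate by the million while labeled activity episodes are scarce,
because a human must mark where each activity begins and ends.

`sensorclr` addresses this with self-supervised contrastive learning.
An encoder is pre-trained on *unlabeled* windows of sensor-derived
features so that two stochastically augmented views of the same window
map to nearby embeddings while views of different windows are pushed
apart. The labeled data, however little of it exists, is then spent only
on a small downstream classifier — either a linear probe on the frozen
encoder or a full fine-tune of the unfrozen encoder.

## From raw events to model inputs

Event logs are whitespace-delimited lines — date, time (microsecond
precision), sensor id, state, and optionally an activity name with a
`begin`/`end` marker on the first and last event of an episode
(`parse_casas_log()`, `propagate_activity_labels()`). Cleaning drops
records with missing fields, duplicate (timestamp, sensor, state)
triples, and temperature-sensor (`T*`) events; only motion and door
sensors feed the features (`clean_events()`). Equal timestamps keep file
order — logs are near-sorted and a stable sort preserves the semantics
of marker placement.

Each consecutive non-overlapping block of 30 events becomes one summary
vector (`featurize()`): 14 window-level features (clock and calendar of
the last event, block duration, inter-event gap, dominant sensors of the
two preceding blocks, last sensor and locations, entropy of the
sensor-count distribution, the change in event rate between the block's
halves, location transitions, distinct sensors) plus a per-sensor count
and a per-sensor recency, giving `2*S + 14` features for `S` sensors
(84 features for a 35-sensor home, 80 for 33). Design choices the
layout forces or leaves open:

* Categorical quantities (sensors, locations, weekday) are encoded as
  integer indices, not one-hot blocks — one-hot would break the
  `2*S + 14` dimensionality.
* "Time of the last event in seconds" is read as seconds-of-day (the
  alternative, seconds within the hour, duplicates no calendar
  information but is redundant with the hour feature).
* "Change in activity level" is implemented as the difference in event
  rate (events/s) between the second and first half of a block, with
  half-durations floored at 1 ms so bursty blocks cannot divide by zero.
* A sensor that has never fired yet gets a recency sentinel capped at
  the dataset's time span.
* Entropy uses the natural log; any base differs only by a scale that
  standardization removes.

Vectors are sliced into sliding windows of 10 at 50% overlap (stride 5),
giving the 3-D model input; a window inherits the label of its last
vector, and a 30-event block takes the majority label of its events with
ties broken by the latest event. Windows may span activity boundaries —
the label rule above decides them. Standardization to zero mean and unit
variance is fit **on the training split only** and reused for validation
and test; fitting on all data would leak test statistics into training.

## The encoder and the contrastive objective

The encoder stacks two 1-D convolutions over the feature axis (32 and 64
filters, kernel 3, ReLU, dropout 0.1 after each, L2 `1e-4` on the
kernels), a 64-unit LSTM returning all 10 hidden states, and
multiplicative self-attention over the hidden-state sequence:

$$e_{t,t'} = h_t^\top W_a h_{t'} + b_a,\qquad
  \alpha_{t,\cdot} = \mathrm{softmax}(e_{t,\cdot}),\qquad
  c_t = \sum_{t'} \alpha_{t,t'} h_{t'},$$

followed by a global max-pool over the time axis of the context
sequence. A three-layer projection head (256, 128, 64; ReLU on the
first two) maps the pooled embedding into the space where the loss is
computed, and is discarded after pre-training. For a batch of `N`
windows, two augmented views of each are interleaved into `2N`
embeddings and scored with the NT-Xent loss at temperature 0.1: each
anchor's positive is its sibling view, every other embedding in the
batch is a negative, similarities are cosine, and the softmax inside the
loss is stabilized by row-max subtraction.

Two details of the attention layer are forced by the parameter
accounting rather than free choices: the bias $b_a$ is a single scalar
and the layer has no output projection — together with standard LSTM
gates (bias included, no peepholes, forget-gate bias initialized to 1)
this yields exactly 109,217 trainable parameters for 84-feature input
and 108,833 for 80, and the two totals differ only in the first
convolution (384 parameters). The test suite pins this decomposition,
which identifies the architecture bit-exactly. Convolutions pad so the
10-step time axis is preserved (parameter counts are padding-invariant;
preserving length keeps attention over all 10 steps). Dropout is not
applied to the LSTM output — the regularization list names it only
after the convolutions.

The default augmentation is channel-wise scaling: one factor per window
and feature channel drawn from Normal(1, 0.1), shared across the 10
timesteps. Per-element factors at this magnitude would degenerate into
additive noise; channel-wise factors are what the time-series
augmentation literature uses. Four alternatives are available
(`augmentation_spec()`): sign inversion applied with probability 0.5 per
window (a deterministic flip of both views would cancel in the
contrastive objective), time reversal, additive Gaussian jitter, and a
smooth monotone time warp (4 interior knots, piecewise-linear, linearly
interpolated back to the grid — the parameterization is configurable
since nothing pins it). Both views are augmented; using the clean sample
as one view is a known alternative, but symmetric augmentation is the
standard formulation and is what `make_views()` does.

## Optimization

Pre-training runs SGD with cosine decay (initial rate 0.1, decay
horizon 1000 steps, floor 0) for 100 epochs at batch 512; linear
evaluation trains the probe 300 epochs at batch 128 under Adam `1e-3`;
fine-tuning runs 200 epochs at batch 128 under Adam `1e-3` with
cross-entropy. All of these are `train_config()` defaults and every one
is overridable.

Updates can be wrapped in sharpness-aware minimization (SAM): from the
current weights $w$, climb to the first-order worst case
$w + \rho\, g/\lVert g\rVert_2$ within an $L_2$ ball (the norm is taken
over *all* trainable parameters jointly, treating $w$ as one vector),
re-evaluate the gradient there, and let the base optimizer descend with
that gradient; an optional $\lambda \lVert w\rVert_2^2$ term adds
$2\lambda w$ to the descent gradient. $\rho$ defaults to 0.05, the
canonical choice when none is stated. With $\rho = 0$ the update is
bit-identical to the base optimizer, which the tests assert. SAM is
enabled by default in pre-training *and* in both downstream phases, with
a per-phase switch; together with the encoder's `attention` flag this
expresses the four model variants (plain contrastive learning, +SAM,
+attention, and both).

## Evaluation protocols

* **Linear evaluation** (`linear_evaluate()`): freeze the encoder, drop
  the projection head, train a single dense softmax classifier on
  embeddings of the labeled training windows. The suite verifies the
  encoder is bit-identical before and after probing.
* **Semi-supervised fine-tuning** (`fine_tune()`): unfreeze the encoder,
  attach a two-layer MLP head (ReLU hidden layer, softmax output), train
  end-to-end on a revealed label fraction (1–50% in the experiment
  grids). The discarded projection head takes no part.
* **Transfer** (`transfer_protocol()`): pre-train on one home's
  unlabeled stream, probe and fine-tune on another home that shares the
  feature dimensionality; both downstream runs reuse the single
  pre-trained encoder.

Metrics are accuracy plus precision, recall and F1 per class and as
support-weighted averages (`compute_metrics()`). The weighted (rather
than macro) average is a deliberate inference: under heavy class
imbalance weighted F1 tracks accuracy closely, which is the observed
behavior of the quantities this package mirrors; a macro average is one
argument away. No class weighting or oversampling is applied, and no
early stopping — the validation split is for monitoring only.

## The synthetic data generator

`synthetic_home_config()` / `generate_home()` / `simulate_events()`
define the study conditions under which every protocol property is
tested without any external download. The simulated resident follows a
semi-Markov process: an activity is drawn from a Gaussian time-of-day
prior combined with a transition weight, holds for a log-normal
duration, and emits ON/OFF firings from the motion sensors of its
affine rooms at an exponential inter-event rate; idle gaps between
episodes emit sparse unlabeled firings; begin/end annotations are
written exactly as an annotated CASAS log would carry them, and the
generator keeps a per-event ground-truth column so label propagation
can be checked exactly. Episode durations own the clock until their
last OFF event, so episodes never interleave and no two events collide
on the (timestamp, sensor, state) triple.

The defaults — five activities in disjoint rooms with distinct rates —
are deliberately well-separated: a fully supervised run reaches
near-perfect F1, which makes the generator a *sanity ceiling*, not a
realism claim. What it does not emulate: cross-activity sensor overlap
(real kitchens serve several activities), annotation errors beyond
omitted episodes, sensor failures, visitors and pets, or long-range
schedule drift. Passing the protocol tests therefore shows the
machinery is correct and the representations carry signal, not that
real-home accuracy is reproduced.

## Reduced problem sizes in the test suite

The packaged tests run the full pipeline at sizes a laptop CPU handles
comfortably, chosen once as the package's study conditions: a 3-day
simulated log (~90,000 events, ~3,000 feature vectors, ~600 windows of
shape 10 x 52), 20 pre-training epochs at batch 128 with the cosine
decay horizon set to the actual optimization length (80 steps),
100-epoch probes and 30-epoch fine-tuning, five seeds. The
probe-quality comparison (pre-trained vs. random frozen encoder) is run
at a 10% label fraction: with abundant labels a linear probe on random
CNN-LSTM features is a strong baseline and the value of pre-training
concentrates in exactly the low-annotation regime the method targets.
Gradient correctness is established separately by central
finite-difference checks on a miniature configuration of the same code
path (4 timesteps, 5 features, 6 LSTM units), for the contrastive loss,
the classification loss, and both attention variants.

## Numerical choices and degenerate inputs

* Softmaxes (attention, NT-Xent, classifiers) subtract the row maximum
  before exponentiating.
* Standard deviations in standardization are floored at `1e-8`;
  constant channels standardize to zero with a warning.
* A zero gradient makes the SAM perturbation zero (plain step);
  a zero embedding vector is an error in cosine similarity.
* `N = 1` contrastive batches (one positive pair, no negatives) have
  loss exactly zero; batches smaller than 2 windows are skipped.
* Sliding windows over fewer vectors than the window size produce an
  empty dataset with a warning; trailing partial feature blocks are
  dropped with a message.
* Nested or interleaved annotation brackets resolve innermost-wins with
  a warning; an unmatched `begin` closes at the last event; a stray
  `end` leaves its event unlabeled. Tie-broken majority labels fall to
  the latest event in the block.

## Known limitations

The implementation is plain R; a pre-training epoch over hundreds of
thousands of windows at batch 512 is feasible but slow compared to a
GPU framework, and the package's purpose is faithful, testable
methodology rather than throughput. The simulator provides structure,
not realism (see above). Class imbalance handling is deliberately out
of scope, as is any alternative windowing scheme (pure time-based
windows), transformer encoders, and clustering-based negative
selection.
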