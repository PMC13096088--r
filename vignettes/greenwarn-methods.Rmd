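---
title: "greenwarn: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{greenwarn: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the perception model and its assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic world does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made.

## The problem

Greenhouse fungal and oomycete diseases incubate under sustained high
humidity. During incubation and the earliest symptomatic phase, lesions
cover under 5% of the visible plant surface, are low-contrast, and are
easily confused with physiological stress; only retrospective tracking
(did the plant become clearly symptomatic within 1–3 days?) confirms an
"early" label. Meanwhile the climate record around the plant carries the
risk signal days before the camera does. The package's model treats that
record as an active prior on visual feature learning rather than a feature
appended at the end.

## Preprocessing model

Sensor streams are minute-resolution; images arrive 2–4 times a day. Per
image, the stream is reduced by a **centred closed-window mean** over
$[\tau - \Delta t, \tau + \Delta t]$ with $\Delta t$ = 30 min. Boundary
observations are included; a 0.1 ms numeric slack guards the closed
interval against POSIX double rounding. If a window is empty the aligner
falls back to the nearest observation within $2\Delta t$ and otherwise
raises a typed error — continuous sensing is an assumption of the method,
not something we silently repair.

The per-image aggregated sequence is then smoothed with an EWMA
($\alpha = 0.2$, initialised at the first observation) and z-normalised.
Three decisions here were open and are pinned by tests rather than
asserted as the only reading:

* **Order**: aggregate → smooth → normalise, with smoothing applied to the
  per-image aggregated sequence (one value per frame), not the raw 1-min
  stream. Smoothing the aggregated sequence gives the environmental
  feature a multi-day memory (at 3 images/day and $\alpha=0.2$ the weight
  half-life is roughly one day), which is what lets climate history from a
  humid episode persist into the frames where early symptoms appear.
  Smoothing is applied per event, since each event is one plant's
  trajectory.
* **Standard deviation convention**: population (divide-by-N). Tests pin
  it; normalising a training split with its own statistics yields exactly
  unit population sd.
* **Leakage**: statistics are fitted on training events only; the
  cross-validation driver refits them per fold.

Augmentation follows a minimal-perturbation policy (±10% brightness and
contrast, crops keeping ≥95% of area, nearest-neighbour resize). Crop
sides are rounded *up* so the area bound holds for every draw. Stage
labels and lesion masks are never touched.

## The network

The visual branch is a hierarchical windowed-attention encoder: 4×4 patch
embedding, window self-attention, and three patch-merging stages giving
feature maps at 1/8, 1/16, 1/32 resolution with (96, 192, 384) channels.
Three stages are implemented (the printed resolution scheme has three
entries; one source figure also shows three). The sensor branch projects
the aligned 4-vector linearly and refines it with one linear+ReLU layer
per stage, sized to the stage's channel count — the minimal hierarchy
consistent with a channel-aligned gate; its depth was unspecified in the
source and is flagged as such.

**Environment-guided attention** at each stage computes a visual channel
gate $a_c = \sigma(W_c[f_{avg}; f_{max}])$ from pooled channel
descriptors and an environmental gate $m_c = \sigma(W_e s)$, multiplies
both into the features (so the pre-residual branch is strictly shrunk:
$|\tilde F| \le |F|$), refines spatially with a 1×1-conv sigmoid map, and
re-enters the main stream through a 1×1-conv residual. The vision-only
ablation replaces $m_c$ by 1, which provably severs every path from the
environmental input to the stage probabilities.

**Spatial–temporal attention** first reweights each frame by
$A_t = \sigma(3{\times}3\,\mathrm{conv}([f^{avg}_t; f^{max}_t]))$, then
mean-pools each frame's tokens to a single $d$-vector and runs forward and
backward encoders of six attention blocks (8 heads, FFN width $4d$,
$d=256$), concatenated and fused linearly. Pooling before temporal
attention makes the attention strictly $T \times T$, matching the
single-time-subscript form of the governing equation; full $HW \cdot T$
joint attention would contradict that indexing and is quadratically more
expensive. Attention logits are scaled by $1/\sqrt{d_{head}}$ (the printed
form's missing radical is treated as a typesetting artifact; the choice is
pinned by the loop-oracle tests). The classification head takes the final
fused step concatenated with the final frame's pooled stage-3 features
(the combination operator was unstated; concatenation is assumed).

Two engineering choices depart from a naive reading and matter in
practice:

* **Pre-norm blocks with LayerScale.** Blocks are
  $x + g\,\mathrm{MSA}(\mathrm{LN}(x))$ with the residual-branch scale $g$
  initialised to 0.1. With post-norm blocks (or unit-scale branches) the
  untrained encoder destroys the class-relevant input statistics, and at
  the few-hundred-sample scale this package trains at, the model never
  recovers; LayerScale makes the untrained encoder near-identity. This is
  standard practice in modern vision transformers and is documented here
  because it was load-bearing.
* **Frame stacking.** All $T$ frames pass through the backbone as one
  token matrix with block-diagonal window masks and constant-matrix
  segment pooling, which keeps the autodiff tape short enough for CPU
  training. The equations are unchanged; tests compare against per-frame
  loop oracles.

The engine itself is a ~300-line tape-based reverse-mode autodiff over
dense matrices; every operator's backward pass is verified against central
differences in the test suite.

## The objective

$L = L_{sup} + 0.5\,L_{early} + 0.1\,L_{align} + 0.3\,L_{ds}$, with:
cross-entropy (log clamped at $\varepsilon = 10^{-8}$) plus an optional
$\beta$-weighted BCE (or Dice) mask term; early-weighted cross-entropy
with $w_j = 1 + \gamma\,\mathbb 1(g_j = early)$; cosine misalignment
$1 - \langle z_{env}, z_{vis}\rangle / (\|z_{env}\|\|z_{vis}\| +
\varepsilon)$, bounded in $[0,2]$; and $\sum_\ell \alpha_\ell
L_{sup}^{(\ell)}$ over auxiliary scales. $\beta = 0.5$, $\gamma = 1$ and
uniform $\alpha_\ell$ are artifact defaults — the source introduces the
symbols without values — and are exposed in `loss_config()`. All terms are
non-negative, so the total is bounded below by zero for non-negative
weights; the invariant `total = sup + 0.5 early + 0.1 align + 0.3 ds` is
asserted to $10^{-9}$.

## The synthetic world

The simulator exists so that every mechanism is testable without any
download. It emulates: one continuous climate stream (diurnal temperature
and CO₂ sinusoids with Gaussian noise, anti-phase humidity, VPD computed
from the Magnus form $e_s(T) = 0.6108\,e^{17.27T/(T+237.3)}$ kPa);
events staggered along the stream, each owning a `days_per_event` block;
multi-hour high-humidity episodes injected into a random subset of blocks;
a discrete monotone hazard $1 - e^{-(r\,h_{above} + b)}$ in cumulative
above-threshold hours; onset lagging the episode end by ~2 days; 1–3-day
early-to-symptomatic progression; daylight-window image acquisitions; and
procedural leaf renders whose lesion pixel fraction matches the labelled
fraction exactly, with deliberately faint chlorotic colouring for early
frames (the stated world is one where incubation symptoms are barely
visible) and high-contrast necrosis for symptomatic ones.

Two world-structure choices deserve emphasis:

* **Staggered events.** With a single shared stream and simultaneous
  events, climate would carry no event-discriminative information and the
  premise "environmental risk precedes visual symptoms" would be
  untestable. Staggering gives each event its own exposure history.
* **Persistent humid microclimate.** After an episode, the block's
  humidity stays elevated (+8% RH) until the block ends, emulating the
  poorly ventilated zones where greenhouse disease pressure persists. The
  super-threshold episode remains the hazard trigger and always precedes
  onset (a tested invariant). Without this persistence the climate signal
  decays before symptoms appear and the guidance mechanism has nothing to
  exploit — the world would fail to embody the causal structure it is
  specified to have.

What the simulator does **not** emulate: photorealistic plants, occlusion
and illumination structure of real canopies, sensor drift or dropouts,
pathogen-specific epidemiology, spatial correlation between neighbouring
plants. A green end-to-end test therefore establishes that the
*mechanisms* work and interlock — alignment, gating, temporal attention,
loss, splitting, lead-time accounting — and that environmental guidance
helps *in a world whose causal structure matches the method's premise*.
It does not establish field performance, and the reference study's
headline numbers are deliberately not used as targets anywhere.

## Evaluation semantics

Detection requires the disease probability $1 - P(\text{healthy})$ to
*strictly* exceed 0.5 on three consecutive observations; the detection
instant is the third observation of the first such run. Lead time is
$t_{ref} - t_{det}$ in days, positive when the warning precedes the
reference onset — the printed formula has the opposite sign but is
reported alongside positive values for earlier warnings, so the
narrative's convention is implemented. $t_{ref}$ is the event's latent
onset instant (the simulator's stand-in for expert annotation; the first
early-labelled frame follows it within one acquisition gap, and the
symptomatic transition instant is also exposed if the other reading is
wanted). Lead time averages over detected, truly diseased events only;
undetected events are counted separately, and undefined ratios are
reported as NA, never as 0. Cross-validation deals whole events into
folds, stratified by diseased status, so no frames of one event ever cross
a fold boundary.

## Numerical and degenerate-input policy

Logs are clamped at $10^{-8}$ with zero gradient below the clamp; the
alignment denominator carries its own $\varepsilon$; layer normalisation
uses $10^{-5}$; zero-σ normalisation variables raise an error naming the
variable; empty aggregation windows raise a typed condition carrying the
timestamp; ties in max-pooling take the first index deterministically.
All randomness flows from explicit seeds: a dataset is a pure function of
its `sim_config`, a model of its `model_config`, a training run of
(model seed, train seed, data).

## Known limitations

CPU-scale training uses the reduced-width desk profile; the
reference-width profile is exercised forward-only in tests. The desk
profile's final stage is a single token, so that one block's query/key
projections receive no gradient (attention over one token is constant) —
the gradient-coverage check therefore runs on the reference profile, where
every group is live. Trajectory evaluation assumes prediction at every
acquisition; irregular schedules are supported by the hysteresis rule but
quantise lead time by the acquisition gap. The spatial head is off by
default because the simulator does not persist per-frame masks to disk.
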