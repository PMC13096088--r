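# greenwarn

Early disease warning for greenhouse crops from joint visual–environmental
perception.

In protected horticulture, fungal and oomycete diseases incubate under
sustained high humidity for days before lesions become clearly visible.
Vision-only classifiers therefore detect outbreaks late; climate sensors
alone cannot localise them. `greenwarn` implements a dual-branch framework
in which continuous greenhouse climate streams (air temperature, relative
humidity, vapour pressure deficit, CO₂) actively *guide* visual feature
learning, so that weak early symptoms are amplified exactly when the
environment indicates elevated disease risk. It is aimed at researchers in
plant phenotyping and precision protection who need a tested, CPU-runnable
reference implementation of this class of model, together with the
evaluation machinery (lead time, event-isolated cross-validation) that
early-warning claims require.

## The model

For each image frame $I_j$ at time $\tau_j$, the sensor stream
$E = \{(e_i, t_i)\}$ is aligned by a centred window mean

$$\tilde e_j = \frac{1}{|W_j|}\sum_{t_i \in W_j} e_i,\qquad
W_j = [\tau_j - \Delta t,\ \tau_j + \Delta t],\ \Delta t = 30\text{ min},$$

smoothed by an EWMA $\hat e(t) = \alpha e(t) + (1-\alpha)\hat e(t-1)$
($\alpha = 0.2$) and z-normalised with training-set statistics. A
hierarchical windowed-attention visual backbone produces feature maps at
1/8, 1/16 and 1/32 resolution with (96, 192, 384) channels; a linear+ReLU
sensor hierarchy produces per-stage environmental representations. At every
stage, channel gates

$$a_c = \sigma(W_c[f_{avg}; f_{max}]),\qquad m_c = \sigma(W_e s),\qquad
\tilde F_c(x,y) = F_c(x,y)\, a_c\, m_c$$

modulate the visual features (environment-guided attention), a spatial map
$A_t = \sigma(\phi([f^{avg}_t; f^{max}_t]))$ reweights each frame, and a
bidirectional temporal encoder (6 blocks per direction, 8 heads, $d = 256$,
FFN width $4d$) attends across the $T$-frame sequence with
$h_t = \sum_\tau \mathrm{softmax}_\tau(Q_t K_\tau^\top/\sqrt d)\, V_\tau$.
Training minimises the four-term objective

$$L = L_{sup} + \lambda_{early} L_{early} + \lambda_{align} L_{align}
      + \lambda_{ds} L_{ds},\qquad
(\lambda_{early}, \lambda_{align}, \lambda_{ds}) = (0.5,\ 0.1,\ 0.3),$$

combining cross-entropy, early-stage-upweighted cross-entropy, a cosine
alignment between environmental and visual embeddings, and deep
supervision at intermediate scales. Evaluation reports accuracy / recall /
precision / F1 on the diseased-vs-healthy reduction, one-vs-rest early
metrics, and a **lead time** $t_{ref} - t_{det}$ (positive = earlier
warning), where $t_{det}$ requires the disease probability to exceed 0.5
on three consecutive observations (hysteresis).

The network and its reverse-mode autodiff engine are written in base R
matrix algebra — no Python or GPU runtime is needed. A built-in simulator
generates complete synthetic greenhouse campaigns (minute-resolution
climate, procedural leaf images with staged lesions, onset lagging
high-humidity episodes by a configurable number of days) so the whole
pipeline is testable offline.

## Worked example

```r
library(greenwarn)

cfg <- sim_config(n_events = 8, days_per_event = 8,
                  env_sample_interval = 5, seed = 7)
ds  <- generate_dataset(cfg, "demo_data")
ds
#> <synthetic_dataset> 8 events (7 diseased), 192 frames, 18432 environmental records

aligned <- align_dataset(ds)
seqs    <- build_sequences(aligned, T = 6)
model   <- build_model(model_config("desk", T = 6, seed = 100))
model
#> <gw_model> profile=desk stages=(16,32,64) d=64 heads=2 blocks=2 params=322069

out <- model_forward(model, seqs[[10]])
round(out$stage_probs, 3)
#>     healthy       early symptomatic
#>       0.358       0.245       0.397
```

The three numbers are the predicted probabilities that the sequence's
final frame is healthy, in the early (sub-5%-lesion) stage, or
symptomatic; `1 - P(healthy)` is the disease probability that the
hysteresis detector thresholds. Training and evaluation:

```r
fit <- train_model(model, seqs, train_config("desk"), loss_config())
rep <- evaluate_run(fit$model, seqs, ds$events)
c(accuracy = rep$accuracy, early_recall = rep$early_recall,
  lead_days = rep$lead_time_days)
```

From the command line:

```sh
Rscript -e 'greenwarn::greenwarn_cli()' simulate --out data/ --seed 1
Rscript -e 'greenwarn::greenwarn_cli()' train    --data data/ --out run1/ --seed 1
Rscript -e 'greenwarn::greenwarn_cli()' train    --data data/ --out run0/ --seed 1 --no-env-guidance
Rscript -e 'greenwarn::greenwarn_cli()' evaluate --run run1/ --data data/
Rscript -e 'greenwarn::greenwarn_cli()' crossval --data data/ --out cv/ --seed 1
```

`--no-env-guidance` removes the environmental gate `m_c` (vision-only
ablation); with it, the predicted probabilities carry exactly zero gradient
with respect to the environmental input.

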