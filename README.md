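# vitalattn

Predicting an impending medical intervention from multichannel vital-sign
monitoring, with interpretable two-level attention.

## The problem

Patients under continuous monitoring (ICU/CCU) produce high-frequency
waveforms such as ECG (125 Hz) alongside 1 Hz numeric vitals (heart rate,
pulse, respiration, SpO2). Clinically interesting deterioration shows up in
two ways: *localized fluctuation bursts* — a minute or two of elevated
signal variance — and *sustained trends* — a level shift in one channel.
`vitalattn` trains a binary classifier that flags whether an intravenous
rescue intervention is imminent within a short observation window, and
reports *where* it looked: per-minute segment attention weights α and
per-channel attention weights β.

It is written for researchers studying multivariate physiological time
series who want a fully inspectable, dependency-light implementation:
the network, its backpropagation and the optimizers are implemented in
R/Rcpp, and every stage (ingestion, imputation, windowing, features,
model, training, evaluation, attention export) is an exported function.

## The model

A window `S(t-W, t]` is cut into `M` one-minute segments per channel.
Per channel:

* a 1-D CNN encodes each segment (3 layers, kernels 10/5/3 for waveforms;
  2 layers, kernels 5/2 for numeric channels; `U = 8` filters; batch norm,
  ReLU, max pooling), and positions are summed: `o = Σ_j p(j)`, giving
  `O ∈ R^{U×M}`;
* **fluctuant attention**: the per-segment population SD `A_fl` is appended
  to `O` and scored, `α = softmax(V_fl' (W_fl' [O; A_fl] ⊕ b_fl))`, then
  `of_k = α_k o_k`;
* a 3-layer bidirectional LSTM (16 hidden units/direction) encodes the
  attended sequence; per-step outputs are concatenated and summed over
  time to `z ∈ R^J`, `J = 32`.

Channels are stacked (`Z ∈ R^{J×CH}`), transformed (`X = W_z' Z ⊕ b_z`),
and fused by **trend attention**: each channel's knowledge feature is the
range of its min–max-scaled segment means; `β = softmax(V_tr' (W_tr'
[X; A_tr] ⊕ b_tr))` and `d = Σ_c β_c x_c`. The head predicts
`ŷ = softmax(W_hy d + W_tr_y tr + b_y)`, where `tr` collects the absolute
consecutive-segment mean differences of every channel; training minimizes
cross-entropy with Adam (lr 0.002, dropout 0.5 on the prediction layer).
Five ablation variants (`CNN (ECG)`, `CNN-LSTM`, `CNN-FAttn`,
`CLSTM-FAttn`, `CLSTM-TAttn`) remove parts of this pipeline.

## Worked example

Generate a small synthetic study (two channels, 10-minute events, variance
bursts in minutes 4–5 of each positive window, a half-range level shift in
HR), train the full model, and inspect what the attention found:

```r
library(vitalattn)

cfg <- synth_config(
  n_events = 40,
  channels = list(channel_spec("ECG", "high_frequency", 5),
                  channel_spec("HR", "numeric", 1)),
  baseline = list(ECG = list(mean = 0, drift_amp = 0.05, noise_sd = 0.08,
                             spike_amp = 1.1, spike_rate = 1.2),
                  HR  = list(mean = 80, drift_amp = 1.5, noise_sd = 2)),
  fluct_anomaly = list(segments = 4:5, m_f = 4, channels = NULL),
  trend_anomaly = list(channel = "HR", m_t = 0.5),
  pre_event_seconds = 600, step_seconds = 60, seed = 11)
ds <- generate_dataset(cfg)

tc  <- train_config(epochs = 20, batch_size = 8, seed = 1)
sp  <- split_dataset(ds$windows, tc)
mod <- build_model(model_config(seed = 1), ds$windows[[1]]$channels,
                   M = 5, step_seconds = 60)
fit <- train_model(mod, sp$train, sp$val, tc)

evaluate_model(fit$model, sp$test)
#> ACC 1.0000  ROC-AUC 1.0000  F1 1.0000

rec <- attention_recovery(fit$model, sp$test, ds$truth)
rec$localization_rate     # fraction of held-out positive windows whose
#> [1] 0.875               # segment-attention argmax hits minutes 4-5
round(rec$beta_means, 3)  # mean channel attention: the shifted channel wins
#>    HR   ECG
#> 0.992 0.008
```

The held-out metrics say the classifier separates positive from negative
windows perfectly at this (easy) synthetic scale; the recovery numbers say
the attention is looking at the right places — in 87.5% of positive test
windows the largest segment weight sits inside the injected burst minutes,
and the channel carrying the injected level shift receives 99% of the mean
channel attention. Per-window weights with the display categories
(`high` > 0.15, `medium` 0.1–0.15) come from `export_attention()`:

```r
att <- export_attention(fit$model, sp$test[1])
subset(att$alpha_table, channel == "ECG")
#>  window_id channel k        alpha category
#>  e0008_pos     ECG 1 4.486668e-05      low
#>  e0008_pos     ECG 2 3.777383e-06      low
#>  e0008_pos     ECG 3 3.675640e-06      low
#>  e0008_pos     ECG 4 2.639332e-02      low
#>  e0008_pos     ECG 5 9.735544e-01     high
```

The knowledge features themselves are plain statistics and can be checked
by hand on the shipped worked example (two channels, three segments):

```r
we <- generate_worked_example()
fluct_knowledge(we$window)   # per-segment population SD
#>      s1  s2 s3
#> ECG 0.5 1.5  0
#> HR  1.0 1.0  6
trend_knowledge(we$window)   # range of min-max-scaled segment means
#>       ECG        HR
#> 0.5000000 0.3333333
```

Records on disk use a small YAML manifest plus one `time,value` CSV per
channel (`read_record()`, `impute_missing()`, `extract_labeled_windows()`,
`segment_window()`); a command-line front end is installed as
`exec/vitalattn` with `synth`, `train`, `evaluate`, `ablate` and `explain`
subcommands.

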