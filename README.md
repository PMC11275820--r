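# grangercl

Self-supervised spatial–temporal contrastive learning for multichannel EEG
emotion recognition, built around pairwise **Granger-causality** tests.

EEG electrodes record signals whose inter-channel influence is *directed*:
undirected graphs built from electrode distance or correlation discard the
direction of information flow, and the low signal-to-noise ratio of EEG
makes purely supervised models overfit. `grangercl` addresses both with two
contrastively pretrained branches whose fused embedding `Z = Z_T + Z_S`
feeds a light classifier:

* **Spatial branch.** The electrode montage becomes a graph with affinity
  `min(1, θ/d²)` (θ = 6) thresholded at δ = 0.1; a Granger-causality test on
  every ordered channel pair then orients and prunes it into a directed
  adjacency, consumed by a residual GCN (9 blocks × 2 layers, multi-layer
  fusion, max-pool over nodes, 1×1-conv + batch-norm projector). Positive
  pairs are same-video segments from different subjects.
* **Temporal branch.** Each time point is expanded into a forward window;
  attention scores are Granger-causality values between key and query
  window series (`Granger–Former`), and positives are frequency-domain
  **top-K denoised** copies (K = 20 one-sided FFT bins kept, phases
  preserved).
* **Objective.** InfoNCE at temperature τ = 0.1 on cosine similarities,
  `L = L_S + L_T`, Adam at learning rate 0.001.

The directed influence of channel *j* on channel *i* is the log ratio of
nested autoregression residual variances,

```
GC(j→i) = ln( var ε₁ / var ε₃ ),
```

where ε₁ comes from regressing `x_i` on its own `P` lags and ε₃ from the
bivariate regression that adds `x_j`'s lags; edges are gated by the exact
nested-OLS F test on `(P, n − 3P)` degrees of freedom.

No real recordings ship with the package: a first-class synthetic module
generates labelled multi-subject sessions (shared videos, 3 s baselines,
1 s windows, baseline-average subtraction, class-specific band power and
directed VAR coupling with verified stationarity) so that every quantitative
claim is testable against planted ground truth.

## Worked example

Detect a planted directed coupling (`y_t = 0.9·x_{t−1} + ε`):

```r
library(grangercl)
sp <- var_spec(2, 1, coupling = data.frame(source = 1, target = 2,
                                           lag = 1, coefficient = 0.9))
x <- simulate_var(sp, 2000)
granger_pair(x[, 2], x[, 1], lag_order = 1, names = c("y", "x"))
#> # A tibble: 2 × 10
#>   source target lag_order var_uni var_bi gc_value  f_stat   p_value significant
#>   <chr>  <chr>      <dbl>   <dbl>  <dbl>    <dbl>   <dbl>     <dbl> <lgl>
#> 1 x      y              1    1.98   1.07  0.617   1703.   8.73e-270 TRUE
#> 2 y      x              1    1.08   1.08  0.00106    2.12 1.45e-  1 FALSE
```

The x→y direction shows a large residual-variance drop (GC = 0.617,
significant); the reverse direction does not — the test recovers both the
existence and the direction of the influence.

Build the directed channel graph for an 8-electrode montage with two
planted edges (1→2 and 5→6):

```r
lay <- ring_layout(8)
sp8 <- var_spec(8, 1, coupling = data.frame(source = c(1, 5), target = c(2, 6),
                                            lag = 1, coefficient = 0.5))
x8 <- simulate_var(sp8, 2000)
colnames(x8) <- lay$name
g <- channel_graph(lay, gc = granger_matrix(x8, lag_order = 2))
g
#> <channel_graph> 8 channels, theta = 6, delta = 0.1
#>   base edges (undirected pairs): 8
#>   directed GC edges: 2
gc_edge_list(g)
#> # A tibble: 2 × 4
#>   source target gc_value   p_value
#> 1 ch1    ch2       0.241 5.56e-105
#> 2 ch5    ch6       0.203 1.88e- 88
```

Exactly the two planted edges survive, correctly oriented; `degree_flow(g$gc_adjacency)`
then ranks ch1 and ch5 as information sources and ch2/ch6 as sinks.
Top-K denoising of a noisy three-tone mixture raises its correlation with
the clean signal from 0.941 to 0.996 (`denoise_topk(noisy, top_k = 3)`).

The full pipeline at validation scale:

```r
ses <- simulate_session(benchmark_session_spec("classification", seed = 1))
cfg <- benchmark_run_config("classification", seed = 1)
ck  <- pretrain(ses, cfg)                 # L_S + L_T InfoNCE, Adam
rep <- finetune_and_evaluate(ses, ck, cfg) # 5-fold CV, linear head on Z_T + Z_S
rep$mean_accuracy
#> [1] 0.8986111
```

0.899 mean five-fold accuracy against a chance level of 1/3 on a 3-class
synthetic session (288 segments); the label-shuffled control of the same
study lands at 0.357, i.e. chance. `tidy()`,
`glance()`, `tidy_confusion()` and `autoplot()` expose trajectories,
per-fold accuracies and confusion matrices as tibbles and ggplots.

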