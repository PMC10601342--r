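# veloscope

Tools for dissecting the RNA velocity workflow on data with known ground
truth.

RNA velocity estimates, for every gene in every cell, the instantaneous
rate of change of spliced expression, v = ds/dt = βu − γs, from the balance
of unspliced (u) and spliced (s) transcripts under the two-state
transcription model

    du/dt = α⁽ᵏ⁾ − βu,      ds/dt = βu − γs,

with transcription rate α during induction (0 during repression), splicing
rate β and degradation rate γ. In practice the estimates pass through a
long workflow — k-nearest-neighbor smoothing of the count matrices,
per-gene model fitting, and mapping of the high-dimensional velocity
vectors onto a 2-D embedding — and each stage shapes the result at least
as much as the model does. veloscope implements every stage on simulated
data where the truth is known, so the contribution of each stage to errors
in *direction* and *speed* can be measured, and provides a quality-control
statistic for deciding when a velocity vector field should not be trusted.

For: computational biologists who use RNA velocity and want to know when
its arrows mean something, and methodologists studying the workflow itself.

What is in the box:

- `simulate_dataset()` — spliced/unspliced counts from the closed-form
  kinetics with per-gene latent-time windows, known true velocities, and a
  Gaussian noise model (σ = noise_level · 99th percentile / 10);
- `build_knn_graph()` / `true_knn()` / `smooth_moments()` — exact weighted
  k-NN graphs from the noisy or the pre-noise data, column-stochastic
  smoothing;
- `fit_steady_state()` / `fit_dynamical()` — extreme-quantile regression,
  and full kinetic-parameter + latent-time estimation by alternating
  phase-curve projection;
- `project_pca()` / `transition_probabilities()` /
  `map_via_embedding_transform()` / `grid_vector_field()` — three mapping
  routes into 2-D and grid summarization;
- `cosine_similarity()`, `speed()`, `pcc()`, `nrmse()`,
  `evaluation_sweep()` — direction/speed scoring against the gold standard
  (PCA projection of the true velocities) across noise levels and graph
  choices;
- `loess_r2()` / `velocity_qc()` — explained variance of Ms and Mu over
  latent time (periodic and standard variants) and trustworthy/suspect
  flagging;
- tidyverse surface throughout: tibble-valued fields and reports,
  `tidy()`/`glance()` methods, `autoplot()` for fields, phase portraits
  and QC reports; `run_experiment()` writes a reproducible directory of
  Matrix-Market/TSV artifacts with a manifest.

## A worked example

```r
library(veloscope)

sim <- simulate_dataset(n_cells = 300, n_genes = 10, noise_level = 1, seed = 1)
sim
#> <velocity_sim>  10 genes x 300 cells  (noise_level = 1 , seed = 1 )
#>   rates: alpha = 5  beta = 0.3  gamma = 0.5  t_max = 25

graph <- build_knn_graph(sim$spliced, k = 30)
sm    <- smooth_moments(sim, graph)
fit   <- fit_dynamical(sm, force_velocity_genes = TRUE)
glance(fit)
#> # A tibble: 1 × 5
#>   model     n_genes n_fitted n_velocity_genes median_fit_r2
#>   <chr>       <int>    <int>            <int>         <dbl>
#> 1 dynamical      10       10               10         0.998

head(tidy(fit), 3)
#> # A tibble: 3 × 8
#>   gene    gamma_hat fit_r2 velocity_gene alpha_hat beta_hat t_switch_hat
#>   <chr>       <dbl>  <dbl> <lgl>             <dbl>    <dbl>        <dbl>
#> 1 gene001     0.347  0.998 TRUE               3.76    0.214         12.5
#> 2 gene002     0.523  0.997 TRUE               5.22    0.313         12.5
#> 3 gene003     0.526  0.998 TRUE               5.17    0.311         12.5
```

The fits explain >99% of the phase-portrait variance. Kinetic rates are
identifiable only up to a common rate/time rescaling, so compare ratios:
the medians α̂/β̂ ≈ 16.6 and α̂/γ̂ ≈ 9.8 sit next to the true steady states
α/β = 16.7 and α/γ = 10 (see the vignette for the scale convention).

```r
emb  <- pca_embedding(sim$spliced, n_pcs = 2)
gold <- project_pca(sim$true_velocity, emb)   # gold standard field
est  <- project_pca(fit$velocity, emb)
cs <- sapply(seq_len(300), function(i)
  cosine_similarity(c(est$dx[i], est$dy[i]), c(gold$dx[i], gold$dy[i])))
median(cs)
#> [1] 0.996
```

At this low noise level the estimated field is essentially collinear with
the truth (median cosine similarity 0.996; 1 would be perfect agreement,
0 orthogonal). The QC measure agrees that the fit is sound:

```r
glance(velocity_qc(sm, fit))
#> # A tibble: 1 × 6
#>   n_top_genes time_kind median_r2_ms median_r2_mu      gap flag
#>         <int> <chr>            <dbl>        <dbl>    <dbl> <chr>
#> 1          10 linear           0.994        0.999 -0.00508 trustworthy
```

High explained variance for the *unspliced* matrix and a near-zero Ms−Mu
gap are the signature of a trustworthy fit; a suspect dataset shows median
Mu R² below 0.1 or a gap above 0.5. `autoplot()` on the field, the
simulation, or the QC report draws the standard displays.

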