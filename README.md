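# plateletSPT

Single-particle tracking (SPT) analysis of membrane receptor mobility on
spreading platelets, with a ground-truth synthetic-data generator.

Platelets spreading on a surface form filopodia, a lamellipodial rim, and a
central body, and the lateral mobility of immunoreceptors such as FcγRIIA
differs sharply between these regions: directional transport along
filopodia and toward the lamellipodial edge, confined motion on the body,
with the contrast collapsing when F-actin assembly or myosin II is
inhibited. `plateletSPT` implements the quantitative pipeline behind such
measurements:

* **Simulation** — 2D receptor trajectories under directed, Brownian and
  confined subdiffusive regimes (exact fractional-Gaussian-noise generator,
  reflecting corral, quantum-dot blinking), rendered as diffraction-limited
  emitters in noisy TIRF-like movies (78 ms/frame, 75-frame windows), with
  platelet-like region masks and serialized ground truth.
* **Tracking** — Laplacian-of-Gaussian spot detection with subpixel
  localization, Fourier cross-correlation drift estimation, and greedy
  gap-closing nearest-neighbour linking; TrackMate-dialect CSV in and out.
* **Mobility** — per-track time-averaged MSD and weighted nonlinear fits of

  $$\mathrm{MSD}(t) = 4 D_\alpha t^{\alpha} + v^2 t^2$$

  (generalized diffusion coefficient *D*, anomalous exponent *α*, drift
  speed *v*), track length *L* = Σ√(Dx²+Dy²), MSD-shape motion
  classification (directed / confined / brownian), and region assignment.
* **Morphometrics** — percent micropattern coverage, spread-area and
  mean-intensity time series, protrusion (filopodia-like) counting and
  length measurement on binary shapes.
* **Statistics** — mean ± SD, 10–90 percentile box summaries,
  Kruskal–Wallis (ANOVA on ranks) with tie-corrected Dunn's multiple
  comparisons, parametric ANOVA/Tukey alternative, and a deterministic
  end-to-end pipeline (`run_pipeline()`) producing tidy CSVs and a JSON
  run manifest.

## Worked example

```r
library(plateletSPT)

acq <- acq_config()                                   # 75 frames @ 78 ms/frame
tracks  <- simulate_tracks(motion_presets()$filopodium, 50, acq, seed = 1)
metrics <- analyze_tracks(tracks, acq$frame_interval_s)

summarize_sample(metrics$D)
#> $mean 0.0391  $sd 0.0192  $p10 0.0175  $p50 0.0344  $p90 0.0671
table(metrics$motion_class)
#> brownian confined directed
#>        5        2       43

body <- analyze_tracks(simulate_tracks(motion_presets()$body, 50, acq, seed = 2),
                       acq$frame_interval_s)
kruskal_dunn(c(metrics$D, body$D),
             rep(c("filopodium", "body"), c(nrow(metrics), nrow(body))))
#> Kruskal-Wallis: H = 62.42, df = 1, p = 2.78e-15
#> Dunn pairwise (two-sided, bonferroni-adjusted):
#>  group_i    group_j    z         p p_adjusted
#>     body filopodium -7.9 2.782e-15  2.782e-15
```

The filopodium preset simulates ground-truth D = 0.035 µm²/s with directed
transport; 50 fitted tracks give a mean D of 0.039 µm²/s with 86% of tracks
classified directed, and the filopodium-vs-body contrast is decisive. The
`motion_presets()` family covers the three platelet regions and their
cytochalasin-D / blebbistatin variants; see the vignette
(`vignettes/receptor-mobility.Rmd`) for the model, parameter choices and
their rationale.

A thin CLI over the same functions is installed at
`inst/cli/plateletspt` (subcommands `simulate`, `track`, `analyze`,
`report`).

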