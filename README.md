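# scnphase

Spatiotemporal circadian phase mapping for suprachiasmatic nucleus (SCN)
slice imaging.

Organotypic SCN slices oscillate autonomously for weeks, and co-expressed
reporters (clock-gene bioluminescence, neuronal/astrocytic calcium
indicators, extracellular transmitter sensors) can be imaged together every
30 minutes. `scnphase` answers the spatial question those movies pose: does
the tissue share one phase, or does a multi-hour phase wave sweep across
it? Neuronal activity typically forms a dorsomedial-to-ventrolateral wave
spanning ~3 h; astrocytic signals can be phase-uniform. The package takes
registered movie stacks (or pre-extracted time-series tables) through
preprocessing, 3×3-pixel ROI extraction, rhythm fitting, rhythmicity
testing, phase clustering and circular statistics, and ships a synthetic
slice generator with planted ground truth so every stage is verifiable.

## The statistic at the core

Synchrony is quantified by the circular variance of phases. With phases
converted to angles `x_i = 2π(φ_i mod T)/T`,

    V = 1 − sqrt((Σ sin x)² + (Σ cos x)²) / n

is 0 for perfect synchrony and 1 for complete dispersal. Applied to the
phases of the k = 5 Lloyd k-means clusters of a slice it is the
**inter-cluster phase dispersal**; applied to wave-vector angles across
slices it measures directionality consistency. Supporting machinery:
FFT-NLLS rhythm fits with relative amplitude error (RAE), an empirical
JTK_CYCLE-style rhythmicity test (exact Kendall τ against asymmetric cosine
templates, empirical p from noise nulls), phase-wave vectors from
center-of-mass-on-phase regression, Rayleigh tests, wrapped kernel
densities, and per-cell phase-distance distributions.

## Worked example

Simulate a two-channel slice — a neuron-like channel carrying a 3 h phase
wave and an astrocyte-like channel with uniform phase (0.25 h jitter) —
then run the full phase-mapping pipeline on both channels:

```r
library(scnphase)

cfg <- synth_config(channels = list(
  channel_spec("neuro", phase_mode = "wave", wave_span_h = 3,
               wave_direction_deg = 0),
  channel_spec("astro", phase_mode = "uniform", phase_jitter_h = 0.25)
), seed = 7)

sim <- simulate_movie(cfg)
res <- run_phasemap(sim$stacks, alpha = 1e-3, n_null = 999, seed = 7)
res$summary
#> # A tibble: 2 × 10
#>   channel     k n_roi n_rhythmic common_period_h dispersal_V angle_deg
#>   <chr>   <dbl> <int>      <int>           <dbl>       <dbl>     <dbl>
#> 1 neuro       5   580          5            24.0     0.0228      360. 
#> 2 astro       5   580          5            24.0     0.00172      NA  
#>   speed_px_per_h     r2 defined
#>            <dbl>  <dbl> <lgl>  
#> 1           34.1  0.999 TRUE   
#> 2           NA   NA     FALSE
```

Reading the output: both channels cluster into 5 rhythmic spatial clusters
at a common period of ~24 h. The wave channel's cluster phases disperse
(V ≈ 0.023, phases spanning ~2.5 h) and its wave vector points along the
planted +column axis (360° ≈ 0°, ~34 px/h, `defined = TRUE`); the uniform
channel's clusters are nearly synchronous (V ≈ 0.002) and its direction
vector is flagged `defined = FALSE` — exactly the neuronal-wave vs
astrocyte-uniform contrast the pipeline is built to detect.

Per-cluster detail, SD-across-clusters profiles and label images are in
`res$cluster_summary`, `res$sd_profiles` and `res$cluster_maps` (with
`autoplot()` for the phase map and `plot_cluster_series()` for the
traces). `run_cells()` produces the single-cell analysis (fraction
rhythmic, RAE, phase distances from the slice mean, pre/post-perturbation
comparisons), and `simulate_cells()` is a fast series-only route for
statistics-level work. `inst/cli/scnphase.R` wraps simulate / phasemap /
cells as a command-line tool.

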