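# smti

Analysis of **single-molecule translation imaging (SMTI)** movies, for
labs measuring local protein synthesis in live cells — e.g. β-actin
translation in retinal growth cones. In SMTI, existing fluorescence is
photobleached and each newly synthesized fast-folding reporter (Venus)
emits one brief (~400 ms) diffraction-limited flash before bleaching; every
flash is one translation event with a position and a time.

The package covers the full chain from raw EMCCD movies to spatial
statistics:

- **Localization** — per-frame spot detection (difference-of-Gaussians
  band-pass, non-maximum suppression) and sub-pixel Gaussian fitting by
  Poisson maximum likelihood: photon-equivalent counts $y_i$ are fitted
  under $\mu_i = b + N\,\mathrm{IG}_i(x_0, y_0, \sigma)$, where
  $\mathrm{IG}$ is the pixel-integrated 2-D Gaussian PSF.
- **Events** — photon thresholding (calibrated as the mean budget of
  hand-picked flashes, ~500 photons ≈ 6700 ADC at 13.4 ADC/photon),
  greedy frame-linking to recombine flashes spanning multiple 200 ms
  frames, rectangular/mask cropping.
- **Quantification** — translation density maps (events/s per bin),
  sliding-window instantaneous rate and cumulative event curves,
  area-normalized rate densities (events/s/µm²), pre/post-stimulus fold
  changes.
- **Sholl arcs** — five equidistant concentric arcs from the growth-cone
  base point (A1 central … A5 circumscribing the furthest boundary),
  per-arc event counts/percentages/areas, and exact-permutation
  Mann–Whitney U comparisons between treatment groups.
- **Simulator** — inhomogeneous Poisson events over a synthetic
  growth-cone mask, stochastic flash kinetics, integrated-Gaussian PSF, and
  the EMCCD noise chain (Poisson shot noise, Gamma electron-multiplication
  excess noise with $\mathrm{Var} \approx 2\mu c^2$, Gaussian read noise),
  providing ground truth for end-to-end validation.

Tables in and out are tibbles; results plot via `autoplot()` and tidy via
`tidy()`/`glance()`. See `vignettes/smti-methods.Rmd` for the models,
defaults, and design decisions.

## Worked example

Simulate a full growth-cone acquisition (180 s at 200 ms exposure, stimulus
at 60 s), run the pipeline, and score it against ground truth:

```r
library(smti)

cfg <- default_config()          # paper-protocol defaults
cfg$seed <- 1L
out <- run_pipeline(cfg, "smti_run")
#> simulate: 58 events over 900 frames
#> localize: 900 frames, 452 candidates, 0 fit failures, 452 localizations
#> events: 55 events after event-level threshold of 30 photons
jsonlite::read_json("smti_run/validation.json")[c("recall", "precision")]
#> $recall    0.931
#> $precision 0.982
```

58 events were synthesized by the simulator; 55 survive localization,
linking, the 30-photon threshold and the mask crop, 54 of them matching a
true event within 250 nm / 0.6 s (the three misses are sub-30-photon
flashes below the physical noise floor). Downstream:

```r
ev <- read_events("smti_run/events.csv")
rc <- rate_time_course(ev, window_s = 10, step_s = 1, t_span = c(0, 180),
                       stimulus_time_s = 60)
pre_post_comparison(rc, baseline_window = c(0, 60),
                    response_window = c(60, 120))
#> <smti_pre_post> baseline 0.186 /s, response 0.467 /s, fold change 2.51
autoplot(rc)                      # rate curve with stimulus marker
```

The baseline ~0.19 events/s (~11 events/min of the programmed 15; small-n
Poisson scatter) roughly doubles after the cue, as programmed. Sholl
statistics per growth cone:

```r
g  <- make_growth_cone_mask(1)    # or cell_geometry(read_mask(...), ...)
sh <- assign_events_to_arcs(ev, g, sholl_radii(g))
compare_arc_distributions(group_a, group_b, arc = 5)  # lists of such results
```

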