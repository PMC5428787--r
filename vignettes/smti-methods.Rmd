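---
title: "Methods: single-molecule translation imaging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule translation imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement

Single-molecule translation imaging (SMTI) detects individual protein
synthesis events in live cells. A fast-folding, fast-bleaching fluorescent
reporter (Venus) is fused to the protein of interest; after pre-bleaching all
existing fluorophores, each newly synthesized reporter folds, emits a brief
(~400 ms) diffraction-limited burst of fluorescence, and photobleaches.
Every flash therefore marks one synthesis event with a position and a time.
The raw data are EMCCD movies (16-bit ADC counts); the deliverables are
localization tables, translation density maps, event-rate time courses, and
spatial (Sholl arc) statistics over growth cones.

This package implements the full analysis chain plus a physics-based
simulator that generates movies with known ground truth, which is how every
stage is validated.

## Simulator

**Event times.** Translation events follow an inhomogeneous Poisson process
with a piecewise rate $\lambda(t)$: a constant baseline (default 15
events/min), stepping to a stimulated rate (default 30 events/min) at an
onset delay (default 20 s) after the stimulus time, optionally relaxing back
toward baseline exponentially (default time constant 30 s). Sampling uses
thinning against the peak rate, so any piecewise profile of this family is
exact. These defaults encode the experimental protocol the package targets:
60 s of baseline imaging at 200 ms exposure followed by 120 s after cue
addition, with a rapid (~20 s latency) doubling of the translation rate that
declines over tens of seconds.

**Positions.** Event positions are drawn over a segmented cell mask
proportional to a non-negative spatial weight (uniform by default), jittered
uniformly within the chosen pixel. The bundled growth-cone mask generator
produces a fan-shaped, star-convex (hence connected) lamellipodium with
filopodia-like protrusions and a base point on the proximal boundary; it is
deterministic per seed.

**Flash kinetics.** Burst durations are exponential (single-step
photobleaching) with mean 0.4 s, truncated at five times the mean; the
photon budget of a flash is `photon_rate_per_s * duration` with a default
rate of 1250 detected photons/s, so a full flash carries ~500 photons —
matching the calibrated "average photon budget" of a single reporter.
Note the consequence: budgets are roughly exponentially distributed, so a
non-negligible fraction of genuine events (about 6% below ~30 photons) is
physically indistinguishable from background at realistic noise levels. A
maturation delay between synthesis and emission is supported (default 0; the
in-vivo folding-time dispersion of the reporter is not well characterized,
so it is left to the user).

**Optics and camera.** Each flash renders as an integrated 2-D Gaussian
(error-function differences per pixel) with $\sigma$ = 130 nm (~1.1 px at
118 nm pixels, consistent with a 1.49 NA objective at ~525 nm emission),
split across frames proportionally to the overlap of the emission interval
with each 200 ms frame. The EMCCD chain is, per pixel and frame, in
photon-equivalent units:

1. shot noise: $n \sim \text{Pois}(\mu)$;
2. electron-multiplication excess noise: $a \sim \Gamma(n, 1)$
   (the Gamma approximation of the multiplication cascade; the gain itself
   cancels into the ADC conversion);
3. ADC counts: $\text{offset} + c\,a + \mathcal{N}(0, \sigma_r^2)$,
   rounded and clipped to $[0, 65535]$,

with $c$ = 13.4 ADC/photon (so ~500 photons integrate to ~6700 ADC at EM
gain 200) — giving the characteristic excess-noise law
$\mathrm{Var} \approx 2\mu c^2 + \sigma_r^2$, which the test suite verifies
to 10% on $\ge 10^4$ pixels. Camera offset (100 ADC) and read noise (10 ADC)
are free parameters chosen as typical for a back-illuminated EMCCD at high
gain; a uniform autofluorescence background of 0.5 photons/px/frame
represents the residual cellular background after pre-bleaching under
epifluorescence. These were fixed once as the package's reference conditions.

**What the simulator does not emulate:** fluorophore blinking or
re-activation, sample drift, the TIRF evanescent depth profile, filopodial
motion of the mask during acquisition, diffusing pre-bleached proteins
entering the field, and spatially structured autofluorescence. Passing
end-to-end tests therefore demonstrate correctness of the analysis under an
idealized (static-geometry, uniform-background) acquisition, not performance
on arbitrary real movies.

## Localization

**Detection.** Each frame is band-passed with a difference of Gaussians
($\sigma$ and $2.5\sigma$, $\sigma$ = 1.1 px matched to the PSF), which
removes the offset and slow background. Local maxima above
`detect_threshold_adc` survive greedy non-maximum suppression within the
fitting window; equal-height adjacent maxima resolve to the
lexicographically smallest pixel. The default threshold (20 ADC, roughly
6 times the band-passed background noise) was calibrated on simulated
acquisitions by the same procedure the field applies to real data —
maximize recovered flashes while keeping false positives workable — with
the important twist that the detector is deliberately sensitive
(over-detecting) and final specificity is enforced downstream by the photon
threshold and cell-mask crop. The heavy single-photon amplification tail of
an EMCCD makes a detector that is simultaneously sensitive to ~40-photon
flashes and specific at the candidate level impossible; splitting the roles
resolves the conflict and mirrors the localize-then-threshold workflow of
standard SMLM software.

**Fitting.** Candidate windows (7×7 px) are converted to photon equivalents
($\max((\text{ADC} - \text{offset})/c,\, 0)$) and fitted by maximum
likelihood under a Poisson model
$\mu_i = b + N \cdot \text{IntegratedGaussian}(x_0, y_0, \sigma)$ using
bounded quasi-Newton iterations (analytic gradient; position bounded to the
window, $\sigma \in [0.5, 3]$ px fitted freely, iteration cap and gradient
tolerance from `detection_params()`). Initialization: background from the
window-border median, position from the background-subtracted centroid,
photons from the residual sum. Non-converged or non-positive-photon fits
are discarded and counted. Two deliberate approximations are documented:
the EM excess-noise factor is ignored in the likelihood (standard practice;
it inflates localization errors by ~$\sqrt{2}$ without biasing positions),
and $\sigma$ is fitted per spot rather than fixed.

Correctness is established against an exhaustive grid-search oracle
(0.01 px position grid with profiled $N$ and $b$ at the generating PSF
width): on random noisy patches with $N \in [200, 2000]$ photons the
iterative optimizer agrees within 0.05 px and 2% photons. Precision follows
the expected $1/\sqrt{N}$ scaling (log–log slope $-0.5 \pm 0.1$ over
$N \in \{250, 500, 1000, 2000\}$, 200 replicates each).

## Events

**Photon threshold.** `calibrate_threshold()` reproduces the manual
calibration: the mean photon budget of hand-picked flashes becomes the
threshold (with its s.d. for reporting); on real data this lands near
~500 photons (~6700 ADC). Filtering is inclusive (`photons >= threshold`)
and can be applied per localization (before linking, the classical
workflow) or per linked event (default; a flash split across two frames is
then judged on its recombined budget). The default pipeline threshold is
30 photons: in the simulator's world the only false positives are camera
noise, whose fitted photon equivalents fall almost entirely below 30,
whereas a threshold at the full calibrated mean would by construction
discard the ~40% of genuine flashes whose exponential budget falls below
the mean. On real data containing non-reporter blinking contaminants the
calibrated value is the appropriate setting.

**Linking.** Greedy chronological nearest-neighbour linking recombines
photons a single reporter emits across consecutive frames: a localization
joins an open track when within `search_radius_nm` (default 236 nm = 2 px)
of the track's photon-weighted position and within `max_gap_frames`
(default 1, i.e. no skipped frames) of its last frame; conflicts resolve by
distance. Event density in SMTI is sparse enough that greedy assignment is
essentially always unambiguous; linking conserves photons exactly and
partitions localizations. 400 ms flashes imaged at 200 ms exposure
recombine into a single event in ≥95% of simulated replicates.

**Cropping.** `crop_to_roi()` keeps events in a half-open rectangle
(low edge in, high edge out), the tight growth-cone windows used on real
data. The pipeline additionally crops events to the cell mask with a
one-pixel tolerance: localization error (~20 nm, but up to a pixel for dim
flashes) can push an event sitting on a one-pixel-wide filopodium just
across a pixel border, and dropping such events would bias recall at the
periphery.

## Quantification

Rates use event start times only — an event is one synthesis, regardless of
how many frames its flash spanned. The instantaneous rate at grid time $t$
counts starts in $[t - w/2, t + w/2)$ divided by the overlap of that window
with the analyzed span (edge-corrected, so boundary estimates are unbiased);
defaults $w$ = 10 s on a 1 s grid. The cumulative curve shares the grid.
The windowed estimator's integral over the span equals the event count to
within discretization (~1%).

Density maps are 2-D histograms of event positions (default bin = 1 camera
pixel) optionally smoothed with a mass-conserving Gaussian kernel (default
$\sigma$ = 2 px; the kernel is column-normalized so truncation at the grid
edge never loses mass), normalized by duration to events/s per bin.
Area-normalized rates divide the in-mask event rate by the mask area in
µm², for comparability across differently sized cells.
`pre_post_comparison()` reports mean windowed rates over two disjoint
windows and their ratio; a zero baseline flags the fold change as
undefined rather than returning infinity.

One statistical caveat worth stating plainly: with ~15 events per window,
the fold change of two Poisson-counted windows carries ~30% relative
standard error from counting statistics alone. Single-replicate fold
changes therefore scatter widely around the programmed value even for a
perfect detector; only their average (or pooling across cones) is tightly
constrained.

## Sholl arcs

Five equidistant concentric arcs are anchored at the growth-cone base
point; the outermost radius is the maximum base-to-mask distance, so arc A5
circumscribes the cone. Events outside the mask are excluded (the mask is
the authority; border events count as inside). Arc intervals are half-open
on the inner edge and closed on the outer edge — the furthest event falls
exactly in A5 — with an epsilon guard so distances computed exactly on an
edge stay in the inner arc despite floating-point rounding. Per-arc counts,
percentages and mask-intersected annulus areas are returned; with uniform
events the percentages track the area fractions (verified to 1.5 points at
$10^4$ events). Percentages can be summarized per cone then averaged, or
pooled across cones (`pool_sholl()` reports both, since the two answers
differ when cones contribute unequal event counts).

Group comparisons use the Mann–Whitney U test on per-cone arc percentages.
For combined $n \le 12$ the two-sided p-value comes from full enumeration
of the permutation distribution of U (exact even under ties, handled by
mid-ranks); larger samples use the tie-corrected normal approximation with
continuity correction, which matches `stats::wilcox.test` on that path. The
test is implemented in-package because the exact-with-ties small-sample
path is not available in base R; the base implementation serves as an
independent cross-check in the test suite. (The experimental literature
this package serves names a "Mann-Whitney Houston test"; no standard test
of that name exists, and it is treated as Mann–Whitney U without guessing
further intent.)

## Reproducibility and numerical choices

- One master seed drives each pipeline run; per-stage seeds are derived
  deterministically, and identical config + seed reproduce byte-identical
  tables. The run manifest records config hash, seeds, versions, per-stage
  counts, and md5 hashes of every artifact.
- Coordinates are nanometres with the origin at the outer corner of pixel
  (0,0) and pixel centers at half-integer multiples of the pixel size;
  frames are 0-based and an event in frame $k$ is assigned the frame start
  time $k \cdot \text{exposure}$.
- Localization tables are plain CSV
  (`frame,x_nm,y_nm,photons,adc_sum,background,sigma_nm,loglik`); movies
  and masks are single-channel 16-bit TIFF; configs are YAML; the pipeline
  emits the density grid as CSV (lossless and text-based).
- Validation matches detected events to ground truth one-to-one, greedily
  by combined spatiotemporal distance with gates of 250 nm and 0.6 s.

Validation problem sizes (chosen for stable statistics at desk-run times):
oracle equivalence on 100 random patches; precision scaling with 200
replicates per photon level; end-to-end recovery pooled over ten 300-frame
(60 s) growth-cone movies at 15 events/min; rate and step-response
recovery over 500 replicate event streams; flash-splitting over 200
rendered replicates; noise-law checks on $\ge 10^4$ pixels.

## Known limitations

- Overlapping emitters are not multi-fitted; simultaneous flashes closer
  than ~2 px merge or mis-fit. At SMTI event densities this is rare.
- Flashes below ~30 detected photons (very short bursts) are below the
  noise floor at realistic EMCCD settings and are unrecoverable by any
  detector; recall is quoted against all ground truth, including these.
- The detector's ADC threshold and the photon threshold were calibrated on
  the simulator's reference conditions; other cameras (different gain,
  background, pixel size) warrant recalibration via the same
  simulate-and-score procedure.
- Masks are static; real filopodia move during acquisition, which the
  rectangular-crop analysis tolerates but the mask-based Sholl assignment
  inherits as position uncertainty at the periphery.
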