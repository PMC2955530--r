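# patchspot

Detection and counting of sudden appearing and vanishing fluorescent
spots in 2D+time fluorescence microscopy — the signature of transient
membrane events such as exocytosis and endocytosis — while ignoring the
lateral vesicle traffic that confounds simpler change detectors. It
handles TIRF sequences and 3D+time wide-field acquisitions reduced to
2D+time by maximum intensity projection.

## The method

Raw intensities follow an affine Poisson-Gaussian sensor model,
`z = g·N + ε` with `N ~ Poisson(λ)` and `ε ~ N(m, σ²)`. The generalized
Anscombe transform

    t(z) = (2/g) · sqrt(g·z + 3/8·g² + σ² − g·m)

stabilizes the noise to unit variance; wide-field sequences are
additionally corrected for photobleaching by fitting the exponential
decay `A·exp(−t/τ) + B` of the in-cell mean (Gauss-Newton) and
multiplying frame `t` by `c(t) = sqrt((A+B)/(A·exp(−t/τ)+B))`.

Detection compares image patches across a frame pair. For each site, the
normalized SSD

    d(x, x') = Σ_u [f(x+u, t) − f(x'+u, t+Δ)]² / (2σ̂²)

is computed against every candidate in a small search window, in both
temporal directions (2W²−1 distances; 17 for a 3×3 window). Under no
change each distance is χ² with `P_w²` degrees of freedom; the *minimum*
distance is calibrated against a generalized extreme value (GEV) null
fitted by a mixed L-moments/maximum-likelihood method with outlier
preselection, initialized from a Monte-Carlo white-noise simulation. A
large minimum means even the best match fails — a sudden event — and its
upper-tail p-value enters a multiple-testing control over all sites of
the pair: Bonferroni-Šidák (family-wise error rate) or
Benjamini-Hochberg (false discovery rate). Lateral motion inside the
search window is matched and therefore silent, which is the method's
advantage over the frame-difference baseline (also provided, with a
Logistic null and the same controls).

Detected pixels are grouped into 8-connected regions, tagged as
appearing or vanishing by the sign of the temporal difference, clustered
in space-time by mean-shift, and filtered for motion artifacts (an
appearing/vanishing pair or a balanced ± "dipole" region is a moving
spot, not an event). Each surviving cluster counts once; the event rate
is events per frame. Batch processing applies one shared configuration
to a whole manifest and a pairwise ANOVA on Anscombe-stabilized rates
quantifies perturbation effects against a reference condition.

A fully specified synthetic benchmark (`generate_sequence`, `snr_sweep`)
provides ground truth for true-positive/false-alarm scoring across spot
intensities.

## Worked example

Simulate a benchmark sequence, run the full pipeline, and score it
against the generator's ground truth:

```r
library(patchspot)

cfg <- sim_config(n_frames = 40, height = 128, width = 128,
                  n_event_spots = 25, spot_intensity = 120, n_movers = 5)
sim <- generate_sequence(cfg, seed = 7)
sim
#> sim_sequence (seed 7): 25 event spots (12 appear / 13 vanish), 5 movers
#> spot_sequence: 40 frames of 128 x 128 px, 1 s/frame, TIRF

norm <- normalize_pipeline(sim$sequence)   # segment, estimate noise, stabilize
norm$noise
#> noise_params: gain 0.1314, dark mean 2499.2, dark sd 7.926

det <- detect(norm, patch_config(control = "fdr"), seed = 1)
events <- extract_events(det, norm)
clusters <- meanshift_cluster(events)
clusters
#> event_clusters: 99 clusters from 167 events (47 discarded as motion)

round(event_rate(clusters, 40), 4)
#> appearing vanishing     total
#>     0.575     0.725     1.300

score <- match_detections(clusters$clusters[!clusters$clusters$discarded, ], sim)
#> true positives 22, false alarms 30, misses 3
```

The estimated gain (0.131) and dark noise (7.9) recover the simulated
sensor; 22 of the 25 ground-truth events are found at this mid-range
spot intensity under FDR control, with the discarded clusters absorbing
the moving dummy spots. `snr_sweep()` repeats this over a grid of spot
intensities for both detectors and both controls; the frame-difference
baseline's false alarms overtake the patch method's at high
signal-to-noise ratios, where moving spots become individually
significant.

A thin command-line front end is installed with the package
(`exec/patchspot`): `patchspot simulate`, `run`, `batch`, `sweep`, and
`compare` expose the same pipeline for shell use.

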