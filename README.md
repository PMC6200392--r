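# kymoslide

Quantitative analysis and simulation of relative sliding and stalling of
antiparallel microtubule pairs crosslinked by the PRC1–Kif4A system.

In the reconstituted assay, a surface-immobilized microtubule is
crosslinked to a second, "moving" microtubule by the antiparallel
crosslinker PRC1; the plus-end-directed kinesin Kif4A, recruited through
PRC1, slides the moving filament toward the immobilized plus-end. Both
plus-ends accumulate micron-scale, near-saturated protein "end-tags" whose
length scales with microtubule length. Two-channel kymographs (rhodamine
for the filaments, GFP for the protein) show a stereotyped three-phase
velocity profile: (1) constant-velocity sliding while the overlap shrinks,
(2) slowdown as the two end-tags approach, (3) a permanent stall when they
collide, leaving a stable antiparallel overlap.

The package implements, as tested code:

* **Mechanistic simulator** (`simulate_pair()`, `simulate_ensemble()`):
  1-D sliding with the motor-ensemble velocity law
  `v = v0 (1 − (1 − S)^N)`, molecule number `N = a·L_untagged/δ`
  conserved from initial recruitment, length-scaled end-tags, and
  roadblock stalling so that the final overlap satisfies
  `L_FO = L_ET1 + L_ET2` exactly.
* **Renderer** (`render_kymograph()`): noisy two-channel TIRF-like
  kymographs (Gaussian PSF in closed form, Poisson counts, configurable
  SNR), with the ground truth embedded.
* **Quantification** (`detect_edges()`, `segment_end_tags()`,
  `measure_frame()`, `track_event()`): sub-pixel edge localization at
  plateau-midpoint crossings, end-tag segmentation with a bimodality
  guard, the overlap intensity partition
  `I_overlap = I_untagged + I_ET1 + I_ET2`, and event-level summaries
  (`L0`, `L_FO`, `ML1`, `ML2`, end-tag lengths, `ρ_untagged`).
* **Phase kinetics** (`instantaneous_velocity()`, `segment_phases()`):
  the three-phase changepoint model (constant → linear decay → stall)
  fitted by least squares, plus the transition-density diagnostic.
* **Overlap model** (`mm_velocity()`, `fit_mm()`, `ensemble_velocity()`,
  `n_from_overlap()`, `efficiency()`, `predict_final_overlap()`): the
  saturating velocity–overlap relation `v/v0 = L/(L + K_L)`, and the
  sliding efficiency `S = 1 − 2^(−1/N)` with `N = a·K_L/δ`, `δ = 8 nm`.
* **Ensemble statistics** (`filter_events()`, `gaussian_fit()`,
  `pearson()`, `linear_fit()`, `binned_means()`,
  `molecules_per_micron()`): the event-exclusion screen (including the
  5 µm initial-overlap rule), histogram Gaussian fits, correlations and
  regressions, and single-molecule intensity calibration.
* **Pipeline** (`run_pipeline()`): simulate → render → track → segment →
  filter → fit, deterministic under one seed, with CSV/JSON outputs and
  TIFF round-trip I/O (`write_kymograph()`, `read_kymograph()`).

## Worked example

```r
library(kymoslide)

# one sliding event with saturated, length-scaled end-tags
p <- simulation_params(ML1 = 8000, ML2 = 8000, s0 = 500,
                       endtag_fraction = 0.4, endtag_growth_rate = Inf,
                       duration = 200)
truth <- simulate_pair(p)
kymo  <- render_kymograph(truth, optics_at_snr(optics_params(), 5))
event <- track_event(kymo)
event
#> Sliding event trace
#>   601 frames (601 measured), trackable: TRUE
#>   L0 = 7458 nm, ML1 = 8006 nm, ML2 = 8006 nm
#>   stalled at frame 535; L_FO = 6399 nm; LET1+LET2 = 6348 nm

phases <- segment_phases(event$velocity)
phases
#> Three-phase velocity segmentation (three_phase model)
#>   t12 = 23.17 s, t23 = 56.50 s, v_phase1 = 28.06 nm/s (n = 601)

event$L_FO_nm / (event$LET1_nm + event$LET2_nm)
#> [1] 1.0081
```

The simulated pair starts with a 7.5 µm overlap; its two 3.2 µm end-tags
leave a 1.1 µm untagged overlap, so only a handful of sliding-competent
complexes drive movement (phase-1 velocity ≈ 28 nm/s here). Sliding is
constant for ~23 s, slows as the tags approach, and stalls at ~57 s; the
measured final overlap agrees with the summed measured end-tag lengths to
within 1 % — the roadblock prediction.

Sliding efficiency from the velocity–overlap relation:

```r
fit <- fit_mm(L = c(1500, 2500, 3500, 4500),
              v = mm_velocity(c(1500, 2500, 3500, 4500), v0 = 69, KL = 1460))
efficiency_table(fit$KL)[c(1, 10), ]
#>       a      N          S
#> 1  0.01  1.825 0.31600637
#> 10 0.10 18.250 0.03726845
```

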