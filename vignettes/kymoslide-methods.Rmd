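---
title: "Models and measurement conventions for antiparallel sliding kymographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement conventions for antiparallel sliding kymographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoslide)
```

## The system and the model

A surface-immobilized microtubule (length `ML1`, spanning `[0, ML1]` with
its plus-end at `ML1`) is crosslinked to a moving microtubule (length
`ML2`, spanning `[s, s + ML2]` with its plus-end at `s`) by PRC1, a
non-motor crosslinker selective for antiparallel overlaps. Kif4A, a
plus-end-directed kinesin recruited via PRC1, transports the moving
filament toward the immobilized plus-end, so sliding increases `s`. Both
plus-ends accumulate dense PRC1–Kif4A *end-tags* whose saturated length
is proportional to the filament length (`endtag_fraction`, default 0.3
per filament). The simulator integrates this geometry in 1-D:

* **Motor-ensemble velocity.** A complex contributes to sliding only
  while it is dual-bound (PRC1 on the moving lattice, Kif4A stepping on
  the immobilized one). With `N` available complexes, each
  sliding-competent for a fraction `S` of the time, the probability that
  at least one drives the filament gives
  `v = v0 (1 − (1 − S)^N)`. `N` may be non-integer: it is estimated from
  lengths as `N = a·L/δ`, with `a` the fractional occupancy of
  sliding-competent complexes and `δ = 8 nm` the tubulin-dimer binding
  site.
* **Conserved motor number.** The total protein content of the overlap
  reaches a constant level early in an event and stays constant while
  the overlap shrinks (the density rises instead). The simulator
  therefore sets `N` from the *initial* untagged overlap and holds it
  fixed, which makes the phase-1 velocity exactly constant even as the
  overlap shortens — the signature behaviour of the assay. (Recomputing
  `N` from the instantaneous untagged length would make phase-1 velocity
  decay and contradicts the observed constancy; we follow the
  conserved-number interpretation.)
* **Slowdown and roadblock stall.** End-tags are dense enough to block
  stepping. Once the gap between the two inner end-tag boundaries falls
  below `slowdown_width` (default 500 nm), the velocity is attenuated by
  `sqrt(gap / slowdown_width)`. No functional form for the slowdown is
  established experimentally; the square-root ramp is chosen because it
  makes the velocity decay *linearly in time* and close the gap in the
  finite time `2·slowdown_width/v` — consistent with the piecewise-linear
  three-phase description used for analysis, where a proportional (linear)
  ramp would decay exponentially and never stall. When an integration
  step would overshoot contact, the moving filament is snapped to contact
  and sliding halts permanently; end-tag lengths are frozen at collision.
  By construction the final overlap then equals `L_ET1 + L_ET2` exactly,
  which is the roadblock prediction the measurement pipeline is tested
  against. The simulator also reports the continuous-time phase
  boundaries (`t12_true`, `t23_true`), which are the correct truth
  anchors for changepoint recovery (frame labels are quantized to the
  time step).
* **End-tag growth.** Tags start at zero length and elongate at a
  constant `endtag_growth_rate` (default 20 nm/s) to their length-scaled
  plateau; growth kinetics are not established quantitatively, so the
  rate is a placeholder with the right order of magnitude (tags form
  over tens of seconds). `endtag_growth_rate = Inf` starts the tags
  saturated, the configuration used for roadblock-statistic studies.

### Condition calibration

`sliding_conditions()` provides two presets emulating the flagship assay
conditions. The low-crosslinker condition (0.2 nM PRC1 + 6 nM Kif4A-GFP)
uses `a = 0.01`, `S = 0.4`, `v0 = 55 nm/s`, untagged GFP density
3.5 A.U./nm and end-tag fraction 0.3. These values are calibrated so that
the *measured* relation between phase-1 velocity and initial overlap
matches the published characterization of that condition: mean phase-1
velocity ≈ 46 nm/s over initial overlaps of 1.5–5 µm, and a saturating
fit `v/v0 = L/(L + K_L)` with `K_L ≈ 1.5 µm`, whose efficiency image
under `S = 1 − 2^{−1/N}`, `N = a·K_L/δ` spans ≈ 0.3 (at `a` = 1 %) down
to ≈ 0.03 (at `a` = 10 %). Note the deliberate distinction: the
generative efficiency (0.4) is not the value the `K_L`-based estimator
returns (≈ 0.3), because the ensemble law and the saturating fit have
different shapes over the experimentally accessible overlap range — the
estimator is an approximation by its authors' own account, and the
package reproduces the estimate, not the generative constant. The 1 nM
PRC1 condition differs in a denser, slower overlap (density
6.5 A.U./nm, `v0 = 11.5 nm/s`, `a = 0.02`) and longer end-tags
(fraction 0.45; the per-filament fraction is capped below 0.5 because a
stable stall requires the two saturated tags to fit inside the partner
filament).

## Rendering

The renderer produces one kymograph row per frame (default 3 frames/s).
Each channel is a sum of piecewise-constant photon-flux profiles — two
box profiles for the rhodamine channel; single-filament, untagged-overlap
and end-tag fluxes (`rho_single < rho_untagged < rho_endtag`, matching
the three observed intensity plateaus) for the GFP channel — convolved
with a Gaussian PSF in closed form via the normal CDF and sampled at
pixel centres (100 nm pixels, PSF sigma 150 nm by default). Poisson shot
noise is drawn per pixel on top of a constant camera background;
`optics_at_snr()` sets the background so the untagged plateau sits at a
target SNR `s/√(s+b)` without touching the fluxes (so intensity
calibrations in A.U. are unchanged across SNR levels). Rendering is
deterministic given the optics seed.

What the synthetic data do *not* emulate: filament dynamics and
flexural fluctuations, stage drift, photobleaching, read noise,
non-uniform illumination, diffusing unbound protein, and multi-filament
bundles. Passing round-trip tests therefore demonstrates correctness of
the measurement chain under the stated image model, not robustness to
every artifact of real TIRF data.

## Measurement conventions

* Pixels are half-open 100 nm bins; pixel `j` spans
  `origin + [(j−1)·px, j·px)` and measurements are reported in nm.
* Background is the per-frame median of off-structure pixels; per-pixel
  noise is estimated as `mad(diff(profile))/√2`, which cancels structure
  except at the few step pixels.
* Every boundary is localized at the crossing of the midpoint between
  the two adjacent plateaus, linearly interpolated between pixels. For a
  step blurred by a symmetric PSF this crossing is unbiased. The
  single/double threshold of the microtubule channel uses the physical
  constraint that the two-filament excess is twice the single-filament
  excess (`bg + 0.75 × double-excess`), which stays unbiased when the
  single-filament stretches are short.
* End-tags are the maximal contiguous regions at the overlap ends above
  the midpoint between the untagged and end-tag plateaus. A two-level
  split must separate the plateaus by more than six noise standard
  deviations (a uniform noisy plateau splits at two to three), otherwise
  the tags are reported unresolved; tags whose inner boundaries come
  within four pixels are likewise unresolved, since the PSF fills the
  dip. Event-level end-tag lengths are per-tag medians over all
  pre-stall resolved frames: frames at the edge of resolvability are
  noise-selected toward wider apparent gaps, so "last resolved frame
  only" summaries are biased short for plateaued tags.
* The intensity partition `I_overlap = I_untagged + I_ET1 + I_ET2` holds
  by construction on the pixel partition of the overlap.
* The moving edge is the GFP step at the moving plus-end (the end-tag
  outer edge once a tag exists), localized at the midpoint between the
  single-filament level measured just left of the overlap and the local
  plateau just inside it; this keeps the estimator's bias and variance
  constant across all three phases. While a growing end-tag is still
  narrower than the PSF, its blurred bump drags any GFP crossing inward
  as it grows, so the microtubule-channel overlap bound is used until
  the tag has a genuine plateau (at least 7 pixels).
* Stall: the moving edge's displacement-based velocity over a 10 s
  window below 2 nm/s, sustained to the end of the record. `L_FO` is the
  median microtubule-channel overlap over the stalled frames; `L0` is
  the overlap at the first measured frame.

## Phase segmentation

`instantaneous_velocity()` differentiates the moving-average-smoothed
edge (default window 5 frames ≈ 1.7 s) by central differences, using the
effective sample time of each (possibly partial) smoothing window so a
linear trace differentiates exactly everywhere. `segment_phases()` fits
the continuous three-phase model — constant `v1` to `t12`, linear decay
to zero at `t23`, zero afterwards — and compares it by BIC against the
degenerate constant-velocity and all-stalled models; ties in the
residual sum of squares break toward the earliest `t12`.

Two fitting domains are implemented. The velocity-domain grid fit uses
prefix sums (O(1) per changepoint pair) and, near the optimum, an exact
refinement whose model basis is convolved with the measurement kernel
(boxcar smoothing composed with the central difference), since fitting a
sharp-cornered model to a kernel-rounded trace biases short phases late.
When the velocity trace carries its source edge (as every
`instantaneous_velocity()` result does), the same model is instead
fitted in the position domain — `x(t)` piecewise
linear/quadratic/constant with iid localization noise — which needs no
kernel correction and roughly halves the changepoint error (median ≈ 2
frames at SNR 5); this is the default path in the pipeline. In the
position domain the reported `v_phase1` is the fitted phase-1 slope
(computed over `[0, t12 − 3 s]` so changepoint error cannot mix slowdown
frames in); the velocity-domain path reports the arithmetic mean of the
observed velocities over `[0, t12]`.

## Problem sizes and numerical choices

Simulated study conditions: filament lengths uniform on 4–10 µm,
end-tag fraction 0.4 with saturated tags for roadblock-statistic
ensembles (50 events, SNR 5, 300 s records); the flagship growth
condition with initial overlaps uniform on 1.5–5 µm for velocity–overlap
ensembles (40 events). Starting positions are sampled so both plus-ends
lie inside the partner filament (the configuration a sliding event
requires) with at least `slowdown_width + 500 nm` of clearance between
saturated inner tag boundaries; incompatible geometries are resampled
with a capped retry count. The time step equals the frame interval
(1/3 s). The saturating-relation fit uses `minpack.lm` with a small
multi-start ladder and parameter bounds at ten times the data range;
histogram Gaussian fits bound `mu` to the data range and `sigma` to
twice it, which prevents the flat-Gaussian escape on degenerate
histograms. Note that `K_L` is weakly identified when the sampled
overlaps stop near the bend of the curve: its Cramér–Rao relative
standard deviation is ≈ 20–25 % at n = 60 events with 10 nm/s velocity
noise, so recovery claims for `K_L` must be read against that limit.

## Known limitations

* The 1-D geometry ignores attachment angle, filament flexibility and
  multi-filament bundles; events that encounter bundles are modelled
  only as an exclusion flag.
* End-tag growth kinetics and the slowdown profile are placeholder
  parameterizations constrained only in order of magnitude.
* The analysis assumes the immobilized filament is on the left with its
  plus-end at the overlap's right edge, matching the simulator's
  convention; real data in the mirrored orientation must be flipped
  before analysis.
* Unresolved end-tags (merged, or never separated from the untagged
  plateau) yield `NA` lengths rather than guesses; events without a
  stall in the record have no `L_FO`.
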