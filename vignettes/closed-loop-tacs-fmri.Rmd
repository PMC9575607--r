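---
title: "Simulating closed-loop tACS-fMRI optimization of frontoparietal connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop tACS-fMRI optimization of frontoparietal connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacsloop)
```

## The problem

Dual-site transcranial alternating current stimulation (tACS) can, in
principle, entrain synchronization between two nodes of a cortical network —
here the right frontal (F4) and right parietal (P4) nodes of the
frontoparietal executive-control network — but the stimulation frequency and
the inter-site phase difference that best modulate a given individual's
network are unknown, and the space of device settings (integer 1–150 Hz ×
integer 0–359°) is far too large for exhaustive testing inside a scanner.
A closed-loop protocol addresses this by measuring frontoparietal BOLD
connectivity in real time during stimulation blocks and letting a
derivative-free optimizer choose the next setting.

`tacsloop` implements that protocol as a fully simulatable desk-scale
system: every component — montage, field model, schedule, BOLD generator,
online connectivity engine, optimizer, loop — is ordinary R code, so the
whole closed loop can be run, traced and tested without a scanner.

## Montage and analytic field model

The montage is two high-definition 4×1 rings: one centre electrode per site
carrying 1 mA (peak) and four return electrodes at a nominal 3 cm from the
centre, each carrying 0.25 mA of the opposite sign, so each site is
current-neutral (Kirchhoff constraint). `build_dual_site_montage()` ships
the ten reference electrode coordinates; `validate_montage()` checks the
current budget, the centre–return spacing (±20%, since a nominal 3 cm is
laid out on a curved scalp), and the inter-site separation rules.

The field model is deliberately analytic rather than finite-element: each
electrode is a point current source on a homogeneous conductive half-space,

$$E(p) = \frac{I}{2\pi\sigma r^2}\,\hat r,$$

and the montage field is the vector superposition over the ten electrodes
(`montage_field()`), linear in all currents. The *shunt* question — how much
field leaks into the tissue midway between the sites — is answered on an
idealized flat version of the montage (`flat_dual_site_montage()`): both
sites on a plane, centres 13 cm apart, in-line returns at 3.5 and 9.5 cm
from the midpoint and a lateral return pair 3 cm off-axis
($2d_2 = d_1 + d_3 = 13$ cm).

`midpoint_shunt_field()` reports the component of the field *along the
frontal–parietal axis* at a gray-matter point below the scalp midpoint.
That component is the physically meaningful shunt quantity — it is what
drives current from one site toward the other — and it behaves exactly as
the two phase conditions demand: under in-phase stimulation the montage is
mirror-symmetric about the midplane, so the tangential component cancels
identically; under anti-phase the normal component cancels instead and the
tangential component *is* the full midplane field magnitude. (The full
vector magnitude would not vanish in-phase at depth — the two sites' own
radial fields have a non-zero normal resultant there — which is why the
shunt metric is defined on the tangential component.)

With gray-matter conductivity $\sigma = 0.275$ S/m and an evaluation depth
of 2 cm — a standard adult scalp-to-cortex distance, fixed once as the
package default — the model gives:

```{r shunt}
g <- shunt_geometry()   # d1 = 3.5, d2 = 6.5, d3 = 9.5 cm; sigma 0.275; depth 2 cm
c(anti_phase = midpoint_shunt_field(g, condition = "anti_phase"),
  in_phase   = midpoint_shunt_field(g, condition = "in_phase"))
```

about 0.04 V/m anti-phase (well below the ≈0.1 V/m threshold usually quoted
for measurable physiological effects) and numerically zero in-phase. The
value is insensitive to the exact depth: anywhere between 1.8 and 2.2 cm
rounds to 0.04 V/m.

Focality is summarized by `focality_volume()`: the volume of voxels at or
above 75% of the peak field, with the peak defined as the 99.9th percentile
so single outlier voxels cannot set it. The percentile uses the
nearest-rank convention (sorted value at rank $\lceil 0.999\,n\rceil$) —
an explicit choice, made for reproducible integer semantics where an
interpolation rule was not prescribed. An all-zero grid degenerates to the
whole grid volume and warns rather than erroring, which keeps scale-invariance
property tests simple.

## Session schedule

A run is 15 blocks of 20 s stimulation + 10 s rest at TR = 2 s (450 s, 225
volumes), tiled continuously with 4-s working-memory task trials (2.5 s
stimulus/response + 1.5 s feedback); a 450-s run holds exactly 112 complete
trials. Connectivity for a block is computed over the block's stimulation
period shifted 6 s for the hemodynamic delay — samples
$[\,\mathrm{onset}+6, \mathrm{onset}+26\,)$ s, i.e. 10 samples, extending
6 s into the rest period. All sample indexing is 0-based and half-open.
Durations are computed from the block structure only; a published
whole-training duration of "17 min 8 s" is not derivable from two 450-s
runs and is deliberately not reproduced.

## The synthetic brain

`surface_model()` stands in for the unknown individual parameter–outcome
relationship: the population correlation between the two ROI signals is a
Gaussian bump over (frequency, phase) space,

$$r(f, \phi) = r_{base} + (r_{max} - r_{base})\,
  e^{-(\Delta f / w_f)^2 - (\Delta\phi_{circ} / w_\phi)^2},$$

with phase distance measured on the circle. The default optimum (6 Hz, 0°)
mirrors the theta-band literature prior that also centres the optimizer's
initial triangle; default $r_{max} = 0.8$, $r_{base} = 0$, widths 20 Hz /
60°, and unit-variance measurement noise (`noise_sd = 1`) describe a
plausibly wide, noisy individual response.

`simulate_run()` draws, within each block's hemodynamically lagged window,
sample pairs with *exact* population correlation $r$ by shared-latent
mixing ($x = \sqrt r\,s + \sqrt{1-r}\,e_1$, $y = \sqrt r\,s +
\sqrt{1-r}\,e_2$), and $r_{base}$-coupled samples elsewhere. The
hemodynamic delay is modelled as a pure 6-s onset lag of the coupling —
matching how the protocol operationalizes the delay (a shifted scoring
window) — rather than a full HRF convolution, because the loop's only
observable is the windowed correlation. On top of the coupled signal the
generator adds: polynomial drift, linear leakage of six random-walk motion
channels, white-matter/CSF compartment signals, sinusoids of the cardiac and
respiratory phases, and white measurement noise (`noise_sd`), so the online
nuisance regression has real work to do. Additive noise attenuates the
*observed* correlation to $r/(1 + \sigma_n^2)$; the generative $r$ is
recovered exactly as `noise_sd` → 0.

Two reproducibility choices matter. All randomness flows from one seed;
run-level nuisance structure is drawn first and per-block signal substreams
are derived by counter, so a block's data are identical whether the run is
generated in one pass or block-by-block inside the closed loop. And the
default physiological rates are 1.13 Hz cardiac / 0.31 Hz respiratory:
rates commensurate with the 0.5 Hz sampling rate would alias their
RETROICOR harmonics onto each other (at TR 2 s, 1.1 and 0.3 Hz fold onto
the same 0.1 Hz grid) and make the nuisance design rank-deficient.

What the generator does *not* emulate: spatial image formation (volumes,
smoothing, registration), scanner artifacts, temporal autocorrelation of
BOLD noise, aftereffects of stimulation carrying across blocks, or
multi-subject variability. Passing tests therefore demonstrate the
correctness of the loop's machinery under a known response surface — not
that a scanner experiment would behave this way.

## Online connectivity engine

`build_nuisance_regressors()` assembles, in fixed column order: Legendre
polynomials of order 0–3 on time rescaled to $[-1, 1]$ (high-pass/drift),
the six motion channels, WM and CSF means, and RETROICOR Fourier pairs
$\{\cos k\phi, \sin k\phi\}$, $k \le 2$, for each physiological trace.
Orders 3 and 2 are standard practice; the regressor families are named by
the protocol but their orders are package choices.

Scoring is causal (`evaluate_block_online()`): for block $b$ only samples
acquired before the block's window end are used; the design matrix expands
with the run, mimicking the real-time constraint (the conservative causal
choice where the regression window was not prescribed). Early in a run,
when fewer samples than regressors exist, the design is truncated to its
leading columns so at least 5 residual degrees of freedom remain —
regressors are phased in as data accumulate, as online GLM systems do.
Residualization is ordinary least squares (QR), dropping dependent columns
with a warning; residualize-then-correlate is the implemented order, with
the correlation clipped at $|r| = 1 - 10^{-7}$ before Fisher's
$z = \operatorname{atanh}(r)$ so degenerate windows yield a finite
$z \approx 8.4$. Zero-variance windows return an invalid outcome, which the
loop counts as a failed block.

## The optimizer

The search is Nelder–Mead over the continuous (frequency, phase) plane with
the two axes treated as equal units, driven one evaluation at a time:
`propose_next()` yields a candidate, `round_to_device()` rounds it
half-away-from-zero to integers (the rule that maps the exact equilateral
vertices (6, 5), (1.67, −2.5), (10.33, −2.5) to the published triangle
(6, 5), (2, −3), (10, −3)), clips frequency to [1, 150], and `update()`
feeds the measured z back. Phase is optimized unwrapped (negative values
are meaningful to the search) and wrapped into [0, 359] only at the device
boundary. Standard coefficients α = 1, γ = 2, ρ = 0.5, σ = 0.5; ties rank
the earlier-evaluated vertex better, making proposals fully deterministic.
Both published initial-vertex sets ship as presets
(`simplex_preset("figure12")`, the construction-consistent default, and
`simplex_preset("section44")`); the "5 unit distance to each edge" phrase is
implemented as the circumradius, which is what the published numbers match.

Overlaid on the moves is the protocol's failure rule: a block *succeeds*
only if its z strictly improves on the best-so-far under the arm's mode
(comparison against the immediately preceding block is available via
`failure_reference = "previous"`); two consecutive failures abandon the
triangle and seed a new one centred on the incumbent with the circumradius
halved (floored at 1 unit). Restart construction is not prescribed by the
protocol; centring on the incumbent with shrinkage is this package's
choice, and each restart also rotates the vertex angles by 90° — without
rotation, a restart at the radius floor rebuilds the identical triangle and
the search re-evaluates the same two points until the budget is exhausted.
Invalid outcomes enter the simplex as worst-possible values so the
machinery always progresses. A zero-area triangle raises a typed condition
and is restarted.

## The closed loop

`run_training()` plays the full online protocol — propose, round, simulate
the block, score the window causally, update — across two 15-block runs
(a 30-evaluation budget carried over the run boundary), for either arm:
*experimental* maximizes connectivity, *control* minimizes it (the
min-optimization control condition; sham and fixed-parameter controls are
out of scope). `run_test()` then stimulates 15 blocks at the selected
parameters; `run_protocol()` chains training, a washout rest marker (the
simulated brain carries no aftereffect state, so washout is a protocol
marker only — test outcomes depend on training only through the selected
parameters, which the tests verify by rebuilding the test run directly),
and the test run. `compare_arms()` applies the pooled two-sample t test to
the arms' per-block test z values; on the published summary statistics
(0.70 ± 0.29 vs 0.42 ± 0.33, n = 15 each) the pooled formula gives
t(28) = 2.47 — the value this package reports and asserts, computed from
the published summaries; published block-level data could legitimately give a
slightly different value.

## Test design: what the recovery benchmarks can and cannot show

A hard constraint shapes every end-to-end test: a 20-s window at TR 2 s has
10 samples, so a single block's Fisher z estimate has standard error
$1/\sqrt{n-3} \approx 0.38$ *regardless of measurement noise*. Across the
region a circumradius-5 triangle can reach in 30 evaluations on the default
surface (widths 20 Hz / 60°), the true z varies by well under 0.05 — an
order of magnitude below that noise floor. Under those conditions the two
arms are statistically indistinguishable: in 50 paired simulated protocols
the experimental arm beat the control arm 28 times, i.e. chance. This is a
property of the protocol's information budget, not of any particular
optimizer, and it is consistent with the observation that a single pilot
pair cannot establish efficacy.

The recovery benchmarks therefore use conditions chosen by an explicit
signal-to-noise rule — parameter points outside the acceptance
neighbourhood must be deficient by at least ~5 per-window SEs, and each
integer step near the optimum must move z by at least ~2 SEs: a sharply
peaked noise-free surface ($r_{max} = 0.9$, widths 2 Hz / 5°) evaluated
with 100-sample windows (15 blocks of 200 s stimulation + 20 s rest per
run, per-window SE ≈ 0.10). Under these conditions, measured at 50 seeds
each: the experimental arm's mean test z beat the control arm's in 50/50
paired protocols; the experimental selection landed within Chebyshev
distance 2 of the optimum in 48/50; the control selection reached coupling
≤ 0.05 in 48/50. One comparison was redefined: the natural "selected
coupling below the full-grid median" check is degenerate for any compact
bump (almost the whole 150 × 360 grid is many widths from the optimum, so
the grid median underflows to ~0); the absolute bound 0.05 — far below
every initial-vertex coupling — captures the intent. Similarly, the
optimizer-vs-random-sampling comparison draws its optima from the region
the theta-band initialization is designed for (1–30 Hz, ±45°): a local
simplex search with a two-failure restart rule is not, and is not meant to
be, a global optimizer over the full device space.

## Problem sizes and runtimes

Chosen so the full suite and the acceptance script run comfortably on one
CPU: 500 seeds × 15 windows for the null-coupling Monte Carlo; 200 block
windows for Fisher-z recovery; 50 paired protocols (benchmark schedule)
for arm separation; 25 seeds per selection benchmark in the unit tests;
100 paired trials for the random-sampling comparison. The complete test
suite runs in well under a minute.

## Known limitations

* The analytic field model is a homogeneous half-space: no skull/CSF
  layering, no realistic cortical geometry. It reproduces the reference
  midpoint shunt arithmetic, not finite-element field maps.
* The supplementary derivation the shunt formula transcribes was published
  as external material; the implementation was validated against the
  published 0.04 V/m value and the in-phase symmetry argument, and the
  2-cm evaluation depth is a package default, not a published constant.
* The frontal/parietal ROI centres ship exactly as published
  ([−45, 49, 27] and [−45, −75, 46]) although they lie in the left
  hemisphere while the stimulation sites are right-hemisphere; the
  discrepancy is shipped, not resolved.
* Fisher-z estimates at 10-sample windows carry an upward bias of
  $r/2(n-1) \approx 0.03$; tests account for it where it matters.
* The simulator's white measurement noise attenuates observed correlations;
  real BOLD noise is autocorrelated and would additionally bias the
  effective degrees of freedom of windowed correlations.
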