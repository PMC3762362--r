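---
title: "Kinetics of diVCA-triggered Arp2/3 branch nucleation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of diVCA-triggered Arp2/3 branch nucleation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmosbranch)
```

## The kinetic scheme

WASP-family VCA domains activate the Arp2/3 complex to nucleate daughter
actin filaments from the sides of mother filaments. In single-molecule
colocalization (CoSMoS) experiments, a dimeric VCA (diVCA) and the Arp2/3
complex are followed as separately labeled spots on immobilized
filaments. The package models the pathway as a continuous-time Markov
chain:

1. A diVCA-Arp2/3 complex (diVCA bound with probability `f_AV_truth`)
   binds a filament site as a Poisson process with per-site rate
   `k_A+ x [Arp2/3] x subunits_per_site`.
2. The filament-bound complex (the *nascent branch*) resolves by two
   competing exponential clocks: intact dissociation from the filament at
   rate `k_A-`, releasing both labels together (*co-release*), or diVCA
   release at rate `k_V-*`, leaving an *activated* filament-bound Arp2/3
   complex.
3. An activated complex nucleates a daughter filament with probability
   `p_nuc`; either way it remains filament-bound for the rest of the
   record, so the long tail of the Arp2/3 dwell distribution is set by
   photobleaching, not dissociation.

Competing exponentials give the two identities that anchor the analysis:
the mean nascent-branch lifetime `tau_V* = 1/(k_A- + k_V-*)` and the
release fraction `f_V- = k_V-*/(k_A- + k_V-*)`, hence
`k_V-* = f_V-/tau_V*` (`compute_kv_star()`). The overall second-order
branch-formation rate composes the two arrival classes:
`k_B = k_A+ [f_AV f_B(+diVCA) + (1 - f_AV) f_B(-diVCA)]`
(`compute_kB()`).

Off filament, diVCA binds tethered Arp2/3 complexes at rate
`k_V+ x [diVCA]` and dwells according to a two-exponential mixture
(`A_V1`, `tau_V1`, `tau_V2`), reflecting at least two bound
conformations.

## Ground-truth parameters

`divca_constructs()` carries the published per-construct measurements
(wild type and the V*, C*, A* mutants). `kinetic_params("wt")` converts a
column into scheme rates: `k_V-* = f_V-/tau_V* = 0.037 s^-1`,
`k_A- = 1/tau_V* - k_V-* = 1.39 s^-1`, and
`p_nuc = f_B/f_V- = 0.31` — the fraction of activated complexes that go
on to form a branch, a modeling choice since the fate of non-nucleating
activated complexes is not identified kinetically. Concentrations default
to the imaging conditions (5 nM Arp2/3, 5 nM diVCA on filaments; the
tethered-molecule analyses use 0.5 nM diVCA, inside the 0.1-1 nM range
those experiments used). Per-subunit association rates are converted to
per-site rates with 370 actin subunits per micrometer (2.7 nm rise) and
0.4 um resolvable segments, i.e. 148 subunits per site.

## The observation model

`apply_observation_model()` degrades true events the way the camera
does, in this order:

* **Photobleaching** — an independent exponential clock at
  `bleach_rate_per_power x laser_power` (default 0.005 s^-1 per power
  unit at power 1) can end an event early. At this rate the bleaching
  lifetime (200 s) matches the scale of the long Arp2/3 dwell component.
* **Detection limit** — events shorter than `t_min = 0.1` s are missed.
  The cut is applied to the continuous (pre-snap) duration so that the
  surviving fraction of an exponential population is exactly
  `exp(-t_min/tau)`.
* **Frame snapping** — onsets are floored and offsets ceiled to the
  0.05 s frame grid, which inflates every measured dwell by one frame
  interval in expectation.
* **Localization jitter** — Gaussian, `loc_sigma = 0.05` um, typical
  single-molecule localization precision.
* **Non-specific surface binding** — a spatial Poisson process per
  channel (default 0.005 um^-2 s^-1, the scale implied by the published
  non-specific rate constant of about 1e6 M^-1 s^-1 at 5 nM over a
  diffraction-limited area), with short exponential dwells (0.1 s mean).

The generator emulates spot-level streams only. It does not render
images, model camera noise beyond jitter, track filament geometry (the
70-degree branch angle, polarity), or let daughters elongate
mechanically; daughter appearance is an actin-channel event at the site.
Passing tests therefore validate the event-level analysis chain, not
pixel-level detection.

## Classification and corrections

`match_channels()` scores coincident arrival within 0.27 um (2 pixels)
and 0.15 s (3 frames), the published windows; ambiguous matches resolve
nearest-in-time, then nearest-in-space, and are flagged.
`classify_departures()` partitions pairs into co-release (|dt| <= 0.15 s),
diVCA release (Arp2/3 persists > 0.15 s after diVCA leaves), and
anomalous (diVCA outlives Arp2/3), which is excluded from fractions.

Two corrections mirror the published analysis:

* **Detection efficiency** — `p0 = sum_i A_i exp(-t_min/tau_i)` from
  mixture fits to each arrival class's dwell distribution, applied as
  `1/p0` separately to the +diVCA and -diVCA classes, and to the
  association rate `k_A+` (undetected transients thin the observed
  arrival process by `p0`).
* **Non-specific binding** — per-category counts at control regions of
  the field that contain no filament are subtracted, scaled by area.

Departure fractions and `f_B` are raw ratios within the coincident
class: numerator and denominator events share one dwell distribution, so
detection thinning cancels and no `1/p0` is applied there.

The standard error of the corrected `f_AV` propagates the Poisson
variance of both the category counts and the subtracted control counts
(delta method). The bare counting error `sqrt(f(1-f)/N)` is reported
alongside (`f_AV_counting_se`); it is the published formula but
understates the error of a corrected fraction, which is consistent with
published errors exceeding it.

`estimate_tau_star()` pools the diVCA dwells of all classified nascent
branches, not only the productive ones: under the scheme both resolve
with the same exponential lifetime, and pooling replaces a ~5-observation
mean with a ~700-observation one. Truncation is removed by memorylessness
(subtract `t_min`) and frame snapping by subtracting one frame interval.

## Dwell-time inference

`fit_exp_mixture()` maximizes the likelihood of a 1-3 component
exponential mixture, left-truncated at `t_min` *in the likelihood*
(density divided by mixture survival at `t_min`; data are never shifted)
with optional right-censoring terms for dwells cut by the record end —
the conservative treatment, since the experimental records are finite.
Optimization is multi-start (moment-, quantile-based and randomized
initializations; 10 starts by default) on log time constants and softmax
weights, with a Nelder-Mead search polished by BFGS; ties resolve toward
fewer effective components and amplitudes below 1e-3 collapse with a
warning. The component count is user-fixed (two for diVCA, three for
Arp2/3 on filaments), never selected automatically. Standard errors come
from a seeded nonparametric bootstrap over events (default B = 1000);
resampling is over events rather than sites, a documented choice.

`photobleach_correct()` regresses observed dissociation rates on laser
power with a slope shared across constructs, by weighted least squares
with known measurement variances; parameter errors use the
fixed-variance covariance `(X'WX)^-1`, which stays calibrated at the
handful of power levels these experiments use.
`estimate_offfilament()` assembles the full tethered-molecule analysis:
two-exponential fits per power, corrected `tau_V2` from the regression
intercept, short component from the weakest power, and `k_V+` from
first-appearance times (whose leading intervals are uncontaminated by
bleaching).

## Correlation test

`resampled_permutation_p()` implements the Gaussian-resampled
permutation test: each resample redraws every coordinate from the
anisotropic Gaussian defined by its error bars (not truncated at zero),
permutes the y assignment uniformly over all n! arrangements (identity
included), and computes r; p is the tail at or beyond the r of the
measured means, which is not redrawn. Resampled coefficients within
`tie_tol = 1e-9` of the observed value count as reaching it; without a
tie tolerance the vanishing-error limit cannot recover the exact
n!-enumeration answer, because the identity permutation's coefficient
concentrates *at* the observed value. One empirical caution: at four
points the permutation p is floored at 1/24, so shrinking error bars
moves p *up* toward the exact enumeration value; large errors push p
into the null tail, which for a near-perfect observed r lies far below
1/24. The test suite asserts this (verified) direction.

## Binding equilibria

The "at least one actin bound" occupancy uses the single-site isotherm
`L/(L + K_D)` — 77% at 1 uM actin and K_D 300 nM — matching the
published estimate even though the dimer has two V domains; the
two-independent-site alternative (94.7%) is available via
`n_sites = 2` but is not the default. Isotherm fits use exact mass
balance: the quadratic complex solution for direct titrations and, for
competition, the physical branch of the cubic in free receptor (Wang's
trigonometric solution polished by Newton iterations on the monotone
mass-balance function; the suite checks it against bisection to 1e-9
relative). Anisotropy is a mole-fraction-weighted average of free and
bound endpoints, with no intensity-change correction, and the
competition fit holds the probe K_D at the direct-fit value.

## Bulk pyrene traces

Traces are normalized with the mean of the first 2% of points as
baseline and the final 5% as plateau (plateau averaging is this
package's choice; the published scaling does not state its anchors), the
42-58% polymerization window is selected on a 5-point running median so
measurement noise cannot correlate with point selection (which would
bias the slope low), and barbed ends are mid-window slope over
10 subunits/s. The critical-concentration offset is ignored.
Fold-stimulation subtracts the actin-alone ends from both conditions
before taking the ratio.

## Problem sizes and reproducibility

Simulated experiments in the tests and scripts use the published scales:
877 filament-binding events and 758 nascent branches for the
classification checks, 600 s records, about 150 filament sites, 50
tethered molecules per laser power at three powers, and 100 replicate
experiments for the parameter-recovery study; bootstrap sizes in the
replicate study are 25-40 (1000 is the analysis default). Every
stochastic operation takes an explicit integer seed through one
restorable RNG scope, so identical seeds give byte-identical event
tables.

## Limitations

The single-nascent-state scheme predicts single-exponential nascent
dwells, whereas measured on-filament distributions are multi-exponential
(multiple filament-bound conformations); consequently simulated
detection efficiencies (about 0.87) are higher than the 0.5-0.6 typical
of the real distributions, and the detection-efficiency operation is
additionally exercised on representative short-dominated mixtures.
Arrivals without diVCA never nucleate in the simulator, so the
diVCA-free branching efficiency is exercised only through the published
numbers. Daughter elongation, filament geometry and image formation are
out of scope.
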