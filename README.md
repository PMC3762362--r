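# cosmosbranch

Kinetic analysis of actin filament branch nucleation by the Arp2/3
complex and dimeric WASP VCA (diVCA) activators, as measured by
colocalization single-molecule spectroscopy (CoSMoS). The package is for
single-molecule biophysicists who record two-channel appearance and
disappearance events of labeled diVCA and Arp2/3 complexes on actin
filaments and want to turn them into the rate constants of the
branch-formation pathway — and for anyone who wants to test such an
analysis chain end to end against a simulator with known ground truth.

## The model

A diVCA–Arp2/3 complex binds a filament site (rate `k_A+` per subunit);
the resulting *nascent branch* resolves by kinetic competition between
intact dissociation (rate `k_A−`, co-release of both labels) and release
of diVCA (rate `k_V−*`), which leaves an activated, filament-bound
Arp2/3 complex that can nucleate a daughter filament. Competing
exponentials give

    τ_V* = 1/(k_A− + k_V−*),   f_V− = k_V−*/(k_A− + k_V−*)
    ⇒  k_V−* = f_V− / τ_V*

and the overall second-order branch-formation rate constant

    k_B = k_A+ · [ f_AV · f_B(+diVCA) + (1 − f_AV) · f_B(−diVCA) ].

The package provides, per module:

* `simulate_filament_sites()`, `simulate_tethered_arp()`,
  `apply_observation_model()` — a continuous-time Markov chain simulator
  of both experiment geometries plus the camera model (frame grid,
  0.1 s detection limit, photobleaching, localization jitter,
  non-specific surface binding).
* `match_channels()`, `classify_departures()`, `summarize_fates()` —
  coincidence/co-release classification within 0.27 µm and 0.15 s, with
  detection-efficiency (`1/p0`) and non-specific-binding corrections.
* `fit_exp_mixture()`, `photobleach_correct()`,
  `estimate_offfilament()` — left-truncated, right-censored
  exponential-mixture maximum likelihood with bootstrap errors, and the
  laser-power regression separating photobleaching from dissociation.
* `compute_kv_star()`, `compute_kB()`, `counting_error()` — derived rate
  constants with first-order error propagation.
* `resampled_permutation_p()` — the Gaussian-resampled permutation test
  for the correlation between release rate and branching rate.
* `equilibrium_occupancy()`, `fit_direct_isotherm()`,
  `fit_competition_isotherm()` — exact mass-balance anisotropy binding
  isotherms.
* `barbed_ends_at_t50()`, `fold_stimulation()` — bulk pyrene-trace
  barbed-end estimation.

The numbered scripts under `analysis/` run the whole study in order
(simulate → classify → dwell fits → rates → correlation → binding →
bulk) and write their tables under `results/`.

## Worked example

```r
library(cosmosbranch)

p <- kinetic_params("wt")          # wild-type ground truth
ev  <- simulate_filament_sites(p, 137,
         observation_config(duration = 600, seed = 20260922))
rec <- apply_observation_model(ev,
         observation_config(duration = 600, seed = 20260923))
fs  <- summarize_fates(rec, attr(ev, "sites"),
                       max_arp_events = 877, seed = 11)
print(fs)
#> Fate summary: N_A = 877 Arp2/3 events (684 coincident, 193 alone)
#>   p0(+diVCA) = 0.878, p0(-diVCA) = 0.849
#>   f_AV = 0.812 +- 0.016 (raw 0.780)
#>   departures: 668 co-release, 14 diVCA release, 2 anomalous, 5 branches
#>   f_corelease = 0.9795 +- 0.0054, f_V- = 0.0205 +- 0.0054, f_B = 0.0073
```

Of 877 observed filament-binding Arp2/3 complexes, 81 ± 2% arrived
together with diVCA (the published experiment measured 83 ± 9%), 98% of
nascent branches released both labels together, about 2% released diVCA
first (truth 2.6%), and derived constants follow with
`compute_kv_star(0.026, 0.7)` → 0.037 s⁻¹ and
`compute_kB(2.1e4, 0.83, 0.008, 0.006)` → 161 M⁻¹s⁻¹. The per-construct
reference measurements ship as `divca_constructs()`, and

```r
tab <- subset(divca_constructs(), construct != "none")
resampled_permutation_p(tab$k_V_star, tab$k_B,
                        tab$k_V_star_se, tab$k_B_se,
                        n_resamples = 1e5, seed = 31)
#> r = 0.9990, resampled permutation p = 0.00045 (100000 resamples)
```

shows that the proportionality between diVCA release rate and branching
rate is very unlikely to be coincidental.

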