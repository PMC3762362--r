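# Shared recipes for simulated reference experiments.
# Study conditions mirror the published wild-type experiments: 0.05 s
# frames, 0.1 s minimum dwell, 600 s records, 5 nM Arp2/3 on filaments,
# sub-nanomolar diVCA on tethered complexes at the weakest laser power.

wt_params <- function(...) kinetic_params("wt", ...)

# one filament-side colocalization experiment truncated to n_arp events
run_filament_experiment <- function(seed, n_sites = 137, n_arp = 877,
                                    params = wt_params()) {
  ev <- simulate_filament_sites(
    params, n_sites, observation_config(duration = 600, seed = seed))
  o <- apply_observation_model(
    ev, observation_config(duration = 600, seed = seed + 1))
  estimate_rates(o, attr(ev, "sites"), conc_arp = params$conc_arp,
                 max_arp_events = n_arp, seed = seed + 2)
}

# one tethered-Arp2/3 experiment across three laser powers
run_tethered_experiment <- function(seed, n_molecules = 50,
                                    powers = c(0.1, 0.5, 1),
                                    n_boot = 25,
                                    params = wt_params(conc_diVCA = 5e-10)) {
  exps <- lapply(seq_along(powers), function(i) {
    ev <- simulate_tethered_arp(
      params, n_molecules,
      observation_config(duration = 600, laser_power = powers[i],
                         nonspecific_rate = 5e-4, seed = seed * 10 + i))
    o <- apply_observation_model(
      ev, observation_config(duration = 600, laser_power = powers[i],
                             nonspecific_rate = 5e-4,
                             seed = seed * 10 + i + 5))
    list(power = powers[i], events = o, sites = attr(ev, "sites"))
  })
  estimate_offfilament(exps, params$conc_diVCA, n_boot = n_boot,
                       seed = seed)
}

# classification of the first n nascent branches of a wild-type run in
# which every arrival carries diVCA
run_nascent_departures <- function(seed, n_branches = 758, n_sites = 155) {
  p <- wt_params(f_AV_truth = 1)
  ev <- simulate_filament_sites(
    p, n_sites, observation_config(duration = 600, seed = seed))
  o <- apply_observation_model(
    ev, observation_config(duration = 600, seed = seed + 1))
  oa <- assign_sites(o, attr(ev, "sites"), 0.3)
  arp <- oa[oa$channel == "arp" & oa$on_site, ]
  arp <- arp[order(arp$t_on_s), ]
  m <- match_channels(arp, oa[oa$channel == "vca", ])
  pairs <- utils::head(m[m$coincident, ], n_branches)
  classify_departures(pairs)
}

with_seed_rexp <- function(seed, n, rate) {
  set.seed(seed)
  stats::rexp(n, rate)
}

# brute-force bisection oracle for the competition mass balance
bisect_free_receptor <- function(R, L, C, K1, K2, tol = 1e-16) {
  g <- function(x) x + L * x / (K1 + x) + C * x / (K2 + x) - R
  lo <- 0; hi <- R
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * R) break
  }
  (lo + hi) / 2
}
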