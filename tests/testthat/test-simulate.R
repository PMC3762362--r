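test_that("nascent-branch fates follow the competing-clock scheme", {
  obs <- observation_config(duration = 600, seed = 101)

  # one clock only: no release pathway means every nascent branch ends in
  # co-release
  p0 <- wt_params(k_V_minus_star = 0, f_AV_truth = 1)
  ev <- simulate_filament_sites(p0, 40, obs)
  fates <- ev$fate[ev$channel == "vca"]
  expect_true(all(fates == "corelease"))

  # competing clocks: release fraction and mean dwell match the closed
  # forms k_V-*/(k_A- + k_V-*) and 1/(k_A- + k_V-*)
  p <- wt_params(k_A_minus = 1.3886, k_V_minus_star = 0.04,
                 f_AV_truth = 1, conc_arp = 5e-8)
  ev <- simulate_filament_sites(p, 900, observation_config(duration = 600,
                                                           seed = 102))
  vca <- ev[ev$channel == "vca", ]
  n <- nrow(vca)
  expect_gt(n, 2e4)
  f_rel <- mean(vca$fate %in% c("vca_release_branch",
                                "vca_release_no_branch"))
  f_true <- 0.04 / (1.3886 + 0.04)
  expect_equal(f_true, 0.0280, tolerance = 2e-3)
  expect_lt(abs(f_rel - f_true), 3 * sqrt(f_true * (1 - f_true) / n))

  dwell <- vca$t_off_s - vca$t_on_s
  dwell <- dwell[dwell < 500]  # drop record-end censored branch survivors
  tau_true <- 1 / (1.3886 + 0.04)
  # the printed mean nascent-branch lifetime is 0.7 +- 0.1 s
  expect_lt(abs(tau_true - 0.7), 0.1)
  expect_lt(abs(mean(dwell) - tau_true),
            3 * tau_true / sqrt(length(dwell)))
})

test_that("nascent dwells are exponential with the summed hazard", {
  p <- wt_params(f_AV_truth = 1, conc_arp = 2e-8)
  ev <- simulate_filament_sites(p, 300,
                                observation_config(duration = 600,
                                                   seed = 103))
  vca <- ev[ev$channel == "vca" & ev$fate == "corelease", ]
  dwell <- vca$t_off_s - vca$t_on_s
  dwell <- dwell[seq_len(min(1e4, length(dwell)))]
  ks <- stats::ks.test(dwell, "pexp",
                       rate = p$k_A_minus + p$k_V_minus_star)
  expect_gt(ks$p.value, 0.01)
})

test_that("tethered-molecule intervals follow the binding model", {
  # unoccupied intervals: 1/(k_V+ * conc) = 2.0 s at 1e8 and 5 nM
  p <- wt_params(k_V_plus = 1e8, conc_diVCA = 5e-9)
  obs <- observation_config(duration = 2e4, seed = 104)
  ev <- simulate_tethered_arp(p, 25, obs)
  gaps <- unlist(lapply(split(ev, ev$site_id), function(g) {
    g <- g[order(g$t_on_s), ]
    c(g$t_on_s[1], g$t_on_s[-1] - g$t_off_s[-nrow(g)])
  }))
  expect_gt(length(gaps), 1e4)
  expect_lt(abs(mean(gaps) - 2.0), 3 * 2.0 / sqrt(length(gaps)))

  # single-component limit: A_V1 = 1 gives mean dwell tau_V1
  p1 <- wt_params(A_V1 = 1, tau_V1 = 3)
  ev1 <- simulate_tethered_arp(p1, 10, observation_config(duration = 600,
                                                          seed = 105))
  d1 <- ev1$t_off_s - ev1$t_on_s
  d1 <- d1[ev1$t_off_s < 600 - 1e-9]
  expect_lt(abs(mean(d1) - 3), 3 * 3 / sqrt(length(d1)))

  # wild-type mixture mean: 0.24 * 8 + 0.76 * 61 = 48.3 s
  pw <- wt_params()
  evw <- simulate_tethered_arp(pw, 5, observation_config(duration = 2e4,
                                                         seed = 106))
  dw <- evw$t_off_s - evw$t_on_s
  dw <- dw[evw$t_off_s < 2e4 - 1e-9]
  mix_sd <- sqrt(0.24 * (2 * 8^2) + 0.76 * (2 * 61^2) - 48.3^2)
  expect_lt(abs(mean(dw) - 48.3), 3 * mix_sd / sqrt(length(dw)))

  expect_equal(nrow(simulate_tethered_arp(pw, 0, observation_config())), 0)
})

test_that("observation model degrades events as configured", {
  p <- wt_params()
  ev <- simulate_filament_sites(p, 30, observation_config(duration = 300,
                                                          seed = 107))

  # identity limit: no bleaching, no jitter, no detection cut, no
  # background leaves the events on the frame grid
  ident <- observation_config(t_min = 0, bleach_rate_per_power = 0,
                              loc_sigma = 0, nonspecific_rate = 0,
                              duration = 300, seed = 108)
  o <- apply_observation_model(ev, ident)
  expect_equal(nrow(o), nrow(ev))
  expect_equal(o$x_um, ev$x_um)
  expect_equal(o$t_on_s, floor(ev$t_on_s / 0.05) * 0.05)
  expect_equal(o$t_off_s, ceiling(ev$t_off_s / 0.05) * 0.05)

  # detection cut: exponential survival exp(-t_min / tau)
  tau <- 0.1443
  n <- 1e4
  tr <- spot_event_table(site_id = seq_len(n) - 1L, channel = "arp",
                         x_um = 1, y_um = 1, t_on_s = 1,
                         t_off_s = 1 + with_seed_rexp(109, n, 1 / tau))
  oc <- observation_config(t_min = 0.1, bleach_rate_per_power = 0,
                           loc_sigma = 0, nonspecific_rate = 0,
                           duration = 300, seed = 110)
  oo <- apply_observation_model(tr, oc)
  surv <- nrow(oo) / n
  expect_lt(abs(surv - 0.5), 3 * sqrt(0.25 / n))

  # an independent bleach clock adds to the observed dissociation rate
  rate_true <- 2; b <- 1
  tr2 <- spot_event_table(site_id = seq_len(n) - 1L, channel = "arp",
                          x_um = 1, y_um = 1, t_on_s = 1,
                          t_off_s = 1 + with_seed_rexp(111, n, rate_true))
  ob <- observation_config(frame_interval = 1e-4, t_min = 0,
                           bleach_rate_per_power = b, laser_power = 1,
                           loc_sigma = 0, nonspecific_rate = 0,
                           duration = 300, seed = 112)
  o2 <- apply_observation_model(tr2, ob)
  fit <- fit_exp_mixture(o2$t_off_s - o2$t_on_s, 1)
  rate_obs <- 1 / fit$components$tau
  expect_lt(abs(rate_obs - (rate_true + b)),
            3 * (rate_true + b) / sqrt(nrow(o2)))

  expect_error(observation_config(laser_power = -1), "laser_power")
})

test_that("simulation is reproducible under a fixed seed", {
  p <- wt_params()
  obs <- observation_config(duration = 200, seed = 113)
  a <- simulate_filament_sites(p, 25, obs)
  b <- simulate_filament_sites(p, 25, obs)
  expect_identical(as.data.frame(a), as.data.frame(b))
  oa <- apply_observation_model(a, observation_config(duration = 200,
                                                      seed = 114))
  ob <- apply_observation_model(b, observation_config(duration = 200,
                                                      seed = 114))
  expect_identical(as.data.frame(oa), as.data.frame(ob))

  # different seeds give statistically indistinguishable dwell summaries
  c2 <- simulate_filament_sites(p, 200, observation_config(duration = 600,
                                                           seed = 115))
  c3 <- simulate_filament_sites(p, 200, observation_config(duration = 600,
                                                           seed = 116))
  s2 <- c2$fate == "corelease" & c2$channel == "vca"
  s3 <- c3$fate == "corelease" & c3$channel == "vca"
  d2 <- c2$t_off_s[s2] - c2$t_on_s[s2]
  d3 <- c3$t_off_s[s3] - c3$t_on_s[s3]
  expect_gt(stats::ks.test(d2, d3)$p.value, 0.001)
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(kinetic_params("wt", k_A_minus = -1), "non-negative")
  expect_error(kinetic_params("wt", k_A_minus = Inf), "finite")
  expect_error(kinetic_params("wt", f_AV_truth = 1.2), "0, 1")
  expect_error(kinetic_params("nope"), "unknown construct")
})
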