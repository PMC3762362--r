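make_events <- function(x, t_on, t_off, channel = "arp", y = 0) {
  spot_event_table(site_id = seq_along(x) - 1L, channel = channel,
                   x_um = x, y_um = y, t_on_s = t_on, t_off_s = t_off)
}

test_that("arrival coincidence uses both the distance and time windows", {
  arp <- make_events(0, 10, 12)
  # inside both windows
  vca <- make_events(0.10, 10.10, 11)
  m <- match_channels(arp, vca)
  expect_true(m$coincident)

  # outside the 0.15 s window
  vca2 <- make_events(0.10, 10.20, 11)
  expect_false(match_channels(arp, vca2)$coincident)

  # outside the 0.27 um window
  vca3 <- make_events(0.30, 10.05, 11)
  expect_false(match_channels(arp, vca3)$coincident)

  # ambiguous candidates resolve nearest-in-time and are flagged
  vca4 <- make_events(c(0.05, 0.01), c(10.10, 10.02), c(11, 11))
  m4 <- match_channels(arp, vca4)
  expect_true(m4$coincident)
  expect_true(m4$ambiguous)
  expect_equal(m4$vca_row, 2L)

  expect_error(match_channels(arp, vca, dist_window = 0), "positive")
  expect_error(match_channels(spot_event_table(), vca), "empty")
})

test_that("departure order classifies co-release, diVCA release, anomalies", {
  arp <- make_events(c(0, 0, 0, 0), c(10, 20, 30, 40),
                     c(15, 25.10, 35.20, 44))
  vca <- make_events(c(0, 0, 0, 0), c(10, 20, 30, 40),
                     c(15, 25, 35, 45), channel = "vca")
  m <- match_channels(arp, vca)
  dep <- classify_departures(m)
  # same frame, within 0.10 s -> co-release; 0.20 s gap -> diVCA release;
  # diVCA outliving Arp2/3 -> anomalous, excluded
  expect_equal(unname(dep$category), c("corelease", "corelease",
                                       "vca_release", "anomalous"))
  expect_equal(dep$n, 3)
  expect_equal(dep$f_corelease, 2 / 3)
  expect_equal(dep$f_V_minus, 1 / 3)
  expect_true(dep$f_corelease + dep$f_V_minus <= 1)
})

test_that("detection efficiency is the fitted survival at t_min", {
  expect_equal(detection_efficiency(list(amplitude = 1, tau = 2), 0), 1)
  expect_equal(detection_efficiency(list(amplitude = 1, tau = 0.1443), 0.1),
               0.5, tolerance = 1e-3)
  # a short-dominated three-exponential, as seen for Arp2/3 on filament
  # sides, puts p0 in the typical 0.5-0.6 range
  fit3 <- list(amplitude = c(0.6, 0.3, 0.1), tau = c(0.08, 0.6, 50))
  p0 <- detection_efficiency(fit3, 0.1)
  expect_true(p0 > 0.5 && p0 < 0.6)
  expect_error(detection_efficiency(list(amplitude = 1, tau = 1), -0.1),
               "t_min")
  expect_error(detection_efficiency(list(amplitude = c(0.5, 0.2),
                                         tau = c(1, 2)), 0.1), "sum to 1")
})

test_that("non-specific correction removes a Poisson background in expectation", {
  expect_equal(nonspecific_correction(100, 0), 100)
  expect_equal(nonspecific_correction(100, 20, 1), 80)
  expect_warning(out <- nonspecific_correction(5, 10), "exceed")
  expect_equal(out, 0)

  set.seed(201)
  lambda_sig <- 60; lambda_bg <- 25
  corrected <- replicate(100, {
    on <- rpois(1, lambda_sig + lambda_bg)
    ctrl <- rpois(1, lambda_bg)
    suppressWarnings(nonspecific_correction(on, ctrl))
  })
  se <- sqrt((lambda_sig + 2 * lambda_bg) / 100)
  expect_lt(abs(mean(corrected) - lambda_sig), 3 * se)
})

test_that("daughter initiation time comes from the length extrapolation", {
  est <- estimate_initiation_time(c(10, 20, 30), c(0.25, 0.75, 1.25), 0)
  expect_equal(est$t_init, 5, tolerance = 1e-9)
  expect_equal(est$slope, 0.05, tolerance = 1e-9)
  expect_true(est$included)

  # noisy lines: recovered within 2 SE in most replicates
  set.seed(202)
  hits <- replicate(100, {
    t <- seq(5, 50, by = 5)
    L <- 0.05 * (t - 5) + rnorm(10, 0, 0.1)
    keep <- L > 0
    if (sum(keep) < 3) return(NA)
    e <- estimate_initiation_time(t[keep], L[keep], 0)
    abs(e$t_init - 5) <= 2 * e$t_init_se
  })
  expect_gt(mean(hits, na.rm = TRUE), 0.85)

  # stated filter: initiation within 0.1 s of arrival is excluded
  e2 <- estimate_initiation_time(c(10, 20, 30), c(0.25, 0.75, 1.25),
                                 arrival_t = 4.95)
  expect_false(e2$included)
  expect_error(estimate_initiation_time(c(1, 2, 3), c(3, 2, 1), 0),
               "slope")
  expect_error(estimate_initiation_time(c(1, 2), c(1, 2), 0), "3 length")
})

test_that("classifier agrees with ground-truth fates when windows are wide", {
  p <- wt_params()
  ev <- simulate_filament_sites(p, 100, observation_config(duration = 600,
                                                           seed = 203))
  # benign observation: no background, mild jitter, no bleaching
  o <- apply_observation_model(
    ev, observation_config(duration = 600, bleach_rate_per_power = 0,
                           loc_sigma = 0.03, nonspecific_rate = 0,
                           seed = 204))
  oa <- assign_sites(o, attr(ev, "sites"), 0.3)
  arp <- oa[oa$channel == "arp" & oa$on_site, ]
  m <- match_channels(arp, oa[oa$channel == "vca", ])
  dep <- classify_departures(m)
  truth_rel <- m$fate %in% c("vca_release_branch", "vca_release_no_branch")
  pred_rel <- !is.na(dep$category) & dep$category == "vca_release"
  # coincident rows with known fates: classification matches the labels
  idx <- m$coincident
  agree <- mean(truth_rel[idx] == pred_rel[idx])
  expect_gte(agree, 0.99)
  # and arrival coincidence matches the diVCA-bound ground truth
  expect_gte(mean(m$coincident == (m$fate != "arp_only")), 0.99)
})

test_that("fate fractions sum coherently on a full pipeline run", {
  p <- wt_params()
  ev <- simulate_filament_sites(p, 80, observation_config(duration = 600,
                                                          seed = 205))
  o <- apply_observation_model(ev, observation_config(duration = 600,
                                                      seed = 206))
  fs <- summarize_fates(o, attr(ev, "sites"), seed = 207)
  expect_true(fs$f_corelease + fs$f_V_minus <= 1 + 1e-12)
  expect_equal(fs$f_corelease + fs$f_V_minus, 1, tolerance = 1e-9)
  expect_true(fs$f_AV >= 0 && fs$f_AV <= 1)
  expect_true(fs$p0_plus > 0 && fs$p0_plus <= 1)
  expect_gte(fs$n_coincident / fs$p0_plus, fs$n_coincident)
})

test_that("detection-efficiency correction recovers true event counts", {
  # truncated single-exponential populations: corrected counts match the
  # pre-truncation totals within 3 SE over 100 replicates
  set.seed(208)
  tau <- 0.4; t_min <- 0.1; n_true <- 500
  err <- replicate(100, {
    d <- rexp(n_true, 1 / tau)
    obs <- d[d >= t_min]
    fit <- fit_exp_mixture(obs, 1, t_min = t_min)
    length(obs) / detection_efficiency(fit, t_min) - n_true
  })
  se_mean <- sd(err) / sqrt(100)
  expect_lt(abs(mean(err)), 3 * se_mean + 1e-9)
})
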