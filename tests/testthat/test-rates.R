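test_that("counting error follows binomial statistics", {
  expect_equal(counting_error(0.5, 100), 0.05)
  expect_equal(counting_error(0, 50), 0)
  expect_equal(counting_error(1, 50), 0)
  expect_equal(counting_error(0.026, 758), 0.00578, tolerance = 1e-3)
  expect_error(counting_error(0.5, 0), "N")
  expect_error(counting_error(1.5, 10), "0, 1")
})

test_that("diVCA release rate is the release fraction over the mean lifetime", {
  # published per-construct values reproduce the published k_V-* column
  tab <- divca_constructs()
  tab <- tab[tab$construct != "none", ]
  for (i in seq_len(nrow(tab))) {
    kv <- compute_kv_star(tab$f_V_minus[i], tab$tau_V_star[i],
                          tab$f_V_minus_se[i], tab$tau_V_star_se[i])
    expect_lt(abs(kv$value - tab$k_V_star[i]), tab$k_V_star_se[i])
  }
  # specific numbers: wild-type 0.026/0.7 and C* 0.018/0.37
  expect_equal(compute_kv_star(0.026, 0.7)$value, 0.0371, tolerance = 2e-3)
  expect_equal(compute_kv_star(0.018, 0.37)$value, 0.0486, tolerance = 2e-3)
  expect_equal(compute_kv_star(0, 1)$value, 0)
  # algebraic identity: f_V-/tau_V* returns the scheme's k_V-* exactly
  kA <- 1.0; kV <- 0.25
  expect_equal(compute_kv_star(kV / (kA + kV), 1 / (kA + kV))$value, kV,
               tolerance = 1e-12)
  expect_error(compute_kv_star(0.1, 0), "tau")
})

test_that("branch-formation rate composes the two arrival classes", {
  kb <- compute_kB(2.1e4, 0.83, 0.008, 0.006)
  expect_equal(kb$value, 160.9, tolerance = 1e-3)
  # f_AV = 1 reduces to the diVCA-bound class
  expect_equal(compute_kB(1e4, 1, 0.01, 0.5)$value, 100)
  # equal class efficiencies make the mixture weight irrelevant
  expect_equal(compute_kB(1e4, 0.3, 0.02, 0.02)$value,
               compute_kB(1e4, 0.9, 0.02, 0.02)$value)
  expect_error(compute_kB(-1, 0.5, 0.1, 0.1), "k_A_plus")
  expect_error(compute_kB(1e4, 1.5, 0.1, 0.1), "fractions")
})

test_that("error propagation is first order with independent errors", {
  kv <- compute_kv_star(0.026, 0.7, 0.004, 0.1)
  se_manual <- sqrt((0.004 / 0.7)^2 + (0.026 * 0.1 / 0.49)^2)
  expect_equal(kv$se, se_manual, tolerance = 1e-12)
  kb <- compute_kB(2.1e4, 0.83, 0.008, 0.006, 0.3e4, 0.09, 0.002, 0.002)
  g <- c(0.83 * 0.008 + 0.17 * 0.006, 2.1e4 * 0.002, 2.1e4 * 0.83,
         2.1e4 * 0.17)
  expect_equal(kb$se, sqrt(sum((g * c(0.3e4, 0.09, 0.002, 0.002))^2)),
               tolerance = 1e-12)
})

test_that("scheme consistency identities are verified and violations flagged", {
  # any positive pair of rates satisfies the identities exactly
  for (rates in list(c(1, 0.25), c(0.5, 0.01), c(3, 1))) {
    kA <- rates[1]; kV <- rates[2]
    chk <- consistency_check(kV / (kA + kV), 1 / (kA + kV), kA, kV)
    expect_equal(chk$tau_residual, 0, tolerance = 1e-12)
    expect_equal(chk$f_residual, 0, tolerance = 1e-12)
    expect_equal(chk$kv_residual, 0, tolerance = 1e-12)
    expect_true(chk$consistent)
  }
  # a perturbed lifetime is flagged against tight errors
  kA <- 1.39; kV <- 0.037
  chk <- consistency_check(kV / (kA + kV), 1.1 / (kA + kV), kA, kV,
                           f_V_minus_se = 1e-4, tau_V_star_se = 1e-3)
  expect_false(chk$consistent)
})

test_that("rate table estimated from a large simulation is self-consistent", {
  p <- wt_params()
  ev <- simulate_filament_sites(p, 300, observation_config(duration = 600,
                                                           seed = 601))
  o <- apply_observation_model(ev, observation_config(duration = 600,
                                                      seed = 602))
  est <- estimate_rates(o, attr(ev, "sites"), seed = 603)
  chk <- consistency_check(est$summary$f_V_minus, est$tau_V_star,
                           p$k_A_minus, p$k_V_minus_star,
                           f_V_minus_se = est$summary$f_V_minus_se,
                           tau_V_star_se = est$tau_V_star_se)
  expect_true(chk$consistent)
  # derived release rate agrees with the generating constant within 3 SE
  expect_lt(abs(est$k_V_star - p$k_V_minus_star), 3 * est$k_V_star_se)
})

test_that("rate_table assembles derived constants for all constructs", {
  tab <- divca_constructs()
  m <- tab[tab$construct != "none", ]
  m$f_B_minus <- tab$f_B[tab$construct == "none"]
  m$f_B_minus_se <- tab$f_B_se[tab$construct == "none"]
  out <- rate_table(m)
  expect_true(all(abs(out$k_V_star - m$k_V_star) <= m$k_V_star_se))
  expect_true(all(abs(out$k_B - m$k_B) <= m$k_B_se))
  expect_true(all(out$k_V_star * m$tau_V_star - m$f_V_minus < 1e-12))
})
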