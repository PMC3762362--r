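test_that("single-exponential MLE handles left truncation analytically", {
  set.seed(301)
  d <- rexp(2000, 1 / 2.5)
  f <- fit_exp_mixture(d, 1)
  expect_equal(f$components$tau, mean(d), tolerance = 1e-4)

  # truncated at t_min: memorylessness gives tau-hat = mean - t_min
  d2 <- 0.1 + rexp(2000, 1 / 0.5)
  f2 <- fit_exp_mixture(d2, 1, t_min = 0.1)
  expect_equal(f2$components$tau, mean(d2) - 0.1, tolerance = 1e-3)

  # grid-search likelihood oracle: no random tau beats the MLE
  set.seed(302)
  grid <- exp(runif(1000, log(0.05), log(5)))
  ll_grid <- vapply(grid, function(tau)
    exp_mixture_loglik(d2, 1, tau, t_min = 0.1), numeric(1))
  expect_gte(f2$loglik, max(ll_grid) - 1e-6)
})

test_that("two-component mixtures are recovered with bootstrap coverage", {
  n_ok <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    d <- c(rexp(4000, 1 / 0.3), rexp(1000, 1 / 30))
    fit <- fit_exp_mixture(d, 2, n_boot = 40, seed = 500 + s,
                           n_starts = 6)
    cmp <- fit$components
    ok <- abs(cmp$amplitude[1] - 0.8) <= 3 * cmp$se_amplitude[1] &&
      abs(cmp$tau[1] - 0.3) <= 3 * cmp$se_tau[1] &&
      abs(cmp$tau[2] - 30) <= 3 * cmp$se_tau[2]
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok, 18)
})

test_that("mixture likelihood beats random parameter grids", {
  set.seed(303)
  d <- c(rexp(600, 1 / 0.5), rexp(400, 1 / 10))
  d <- d[d >= 0.1]
  fit <- fit_exp_mixture(d, 2, t_min = 0.1, seed = 304)
  set.seed(305)
  better <- 0
  for (i in 1:1000) {
    a1 <- runif(1)
    taus <- sort(exp(runif(2, log(0.05), log(50))))
    ll <- exp_mixture_loglik(d, c(a1, 1 - a1), taus, t_min = 0.1)
    if (ll > fit$loglik + 1e-6) better <- better + 1
  }
  expect_equal(better, 0)
})

test_that("right-censored dwells contribute survival terms", {
  set.seed(306)
  d <- rexp(3000, 1 / 5)
  cens <- d > 6            # record ends at 6 s
  d[cens] <- 6
  fit <- fit_exp_mixture(d, 1, censored = cens)
  expect_equal(fit$components$tau, 5, tolerance = 0.15)
  # ignoring censoring would bias tau low by the truncation
  naive <- mean(d)
  expect_lt(naive, 4)
})

test_that("fitted survival is a proper normalized survival function", {
  set.seed(307)
  d <- 0.1 + c(rexp(800, 1 / 0.4), rexp(200, 1 / 8))
  fit <- fit_exp_mixture(d, 2, t_min = 0.1, seed = 308)
  cmp <- fit$components
  t <- seq(0.1, 30, length.out = 200)
  S <- exp_mixture_survival(t, cmp$amplitude, cmp$tau) /
    exp_mixture_survival(0.1, cmp$amplitude, cmp$tau)
  expect_equal(S[1], 1, tolerance = 1e-12)
  expect_true(all(diff(S) <= 1e-12))
})

test_that("bootstrap error of a single-exponential tau scales as tau/sqrt(n)", {
  set.seed(309)
  d <- rexp(1000, 1 / 4)
  fit <- fit_exp_mixture(d, 1, n_boot = 300, seed = 310)
  se_expect <- fit$components$tau / sqrt(1000)
  expect_lt(abs(fit$components$se_tau - se_expect) / se_expect, 0.2)
})

test_that("degenerate inputs are rejected or collapsed", {
  expect_error(fit_exp_mixture(rexp(15), 2), "at least 10")
  expect_error(fit_exp_mixture(c(0.05, rexp(50) + 0.2), 1, t_min = 0.1),
               ">= t_min")
  expect_error(fit_exp_mixture(rexp(50), 4), "1, 2 or 3")
  # over-parameterized fit of single-exponential data: the extra
  # component adds nothing (likelihood tie with the 1-component fit and
  # an implied mean equal to the sample mean)
  set.seed(311)
  d <- rexp(400, 1)
  fit2 <- suppressWarnings(fit_exp_mixture(d, 2, seed = 312))
  fit1 <- fit_exp_mixture(d, 1)
  expect_gte(fit2$loglik, fit1$loglik - 1e-6)
  implied_mean <- sum(fit2$components$amplitude * fit2$components$tau)
  expect_equal(implied_mean, mean(d), tolerance = 0.02)
})

test_that("waiting times give the second-order association constant", {
  set.seed(313)
  w <- rexp(2000, 1 / 68)
  out <- fit_waiting_times(w, 5e-9, n_subunits = 148)
  k_true <- (1 / 68) / (5e-9 * 148)   # about 2.0e4, the k_A+ scale
  expect_equal(k_true, 1.99e4, tolerance = 1e-2)
  expect_lt(abs(out$k - k_true), 3 * out$k_se)

  # doubling concentration halves the mean wait at identical k
  w2 <- w / 2
  out2 <- fit_waiting_times(w2, 1e-8, n_subunits = 148)
  expect_equal(out2$k, out$k, tolerance = 1e-12)

  # rescaling the waits rescales k inversely
  out10 <- fit_waiting_times(w * 10, 5e-9, n_subunits = 148)
  expect_equal(out10$k, out$k / 10, tolerance = 1e-12)

  expect_error(fit_waiting_times(w, 0), "concentration")
  expect_error(fit_waiting_times(c(-1, w), 1e-9), "> 0")
})

test_that("photobleaching regression recovers shared slope and intercepts", {
  # flat in power: slope 0, intercepts equal the observed rates
  df0 <- data.frame(construct = rep(c("a", "b"), each = 3),
                    power = rep(c(1, 2, 4), 2),
                    rate = rep(c(0.02, 0.05), each = 3),
                    se = 0.001)
  bc0 <- photobleach_correct(df0)
  expect_equal(bc0$slope, 0, tolerance = 1e-9)
  expect_equal(unname(bc0$intercepts), c(0.02, 0.05), tolerance = 1e-9)

  # synthetic rates k_c + b*P recovered within 2 SE in most replicates
  set.seed(314)
  k_c <- c(0.02, 0.05, 0.1); b <- 0.01; powers <- c(1, 2, 4, 8)
  hits_b <- hits_k <- 0
  for (r in 1:100) {
    df <- expand.grid(construct = c("a", "b", "c"), power = powers)
    mu <- k_c[as.integer(df$construct)] + b * df$power
    df$se <- 0.05 * mu
    df$rate <- mu * (1 + rnorm(nrow(df), 0, 0.05))
    bc <- photobleach_correct(df)
    hits_b <- hits_b + (abs(bc$slope - b) <= 2 * bc$slope_se)
    hits_k <- hits_k + all(abs(bc$intercepts - k_c) <=
                             2 * bc$intercept_se)
  }
  expect_gte(hits_b, 85)
  expect_gte(hits_k, 80)

  # a decrease with power beyond noise is flagged
  dfm <- data.frame(construct = "a", power = c(1, 2, 4),
                    rate = c(0.1, 0.05, 0.02), se = 0.001)
  expect_true(photobleach_correct(dfm)$monotonic_flags[["a"]])
  expect_error(photobleach_correct(data.frame(construct = "a", power = 1,
                                              rate = 0.1, se = 0.01)),
               "two distinct")
})
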