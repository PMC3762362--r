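#' Survival and log-likelihood of a left-truncated exponential mixture
#'
#' `exp_mixture_survival()` evaluates S(t) = sum_i A_i exp(-t / tau_i).
#' `exp_mixture_loglik()` evaluates the log-likelihood of durations under
#' the mixture density conditioned on detection (t >= t_min), i.e.
#' f(t)/S(t_min) for observed durations and S(t)/S(t_min) for
#' right-censored ones. Exposed so that fitted likelihoods can be compared
#' against external parameter grids.
#'
#' @param t Times (s).
#' @param amplitudes Mixture amplitudes (must sum to 1).
#' @param taus Time constants (s), all > 0.
#' @param durations Observed dwell durations (s), all >= `t_min`.
#' @param t_min Left-truncation point: the minimum detectable dwell (s).
#' @param censored Logical vector marking right-censored durations
#'   (the molecule was still bound when the record ended); default none.
#' @return Survival values, or a single log-likelihood.
#' @export
exp_mixture_survival <- function(t, amplitudes, taus) {
  stopifnot(length(amplitudes) == length(taus), all(taus > 0))
  drop(exp(-outer(t, 1 / taus)) %*% amplitudes)
}

#' @rdname exp_mixture_survival
#' @export
exp_mixture_loglik <- function(durations, amplitudes, taus, t_min = 0,
                               censored = NULL) {
  stopifnot(length(amplitudes) == length(taus), all(taus > 0))
  if (abs(sum(amplitudes) - 1) > 1e-8) stop("amplitudes must sum to 1")
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  n <- length(durations)
  k <- length(taus)
  lse <- function(m) { # row-wise log-sum-exp, k <= 3 columns
    mx <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
    mx + log(rowSums(exp(m - mx)))
  }
  log_s_tmin <- log(sum(amplitudes * exp(-t_min / taus)))
  ll <- numeric(n)
  if (any(!censored)) {
    d <- durations[!censored]
    m <- -outer(d, 1 / taus) +
      rep(log(amplitudes) - log(taus), each = length(d))
    ll[!censored] <- lse(m)
  }
  if (any(censored)) {
    d <- durations[censored]
    m <- -outer(d, 1 / taus) + rep(log(amplitudes), each = length(d))
    ll[censored] <- lse(m)
  }
  sum(ll) - n * log_s_tmin
}

softmax0 <- function(z) { # weights from (K-1) free logits, first logit 0
  e <- exp(c(0, z) - max(c(0, z)))
  e / sum(e)
}

#' Maximum-likelihood fit of a left-truncated exponential mixture
#'
#' Fits dwell-time distributions to one-, two- or three-exponential
#' mixtures by maximum likelihood. Left truncation at the minimum
#' detectable dwell is handled in the likelihood (division by the mixture
#' survival at `t_min`), not by shifting the data. Right-censored
#' durations contribute survival terms. Standard errors come from a seeded
#' nonparametric bootstrap over events.
#'
#' Optimization is multi-start: moment- and quantile-based initializations
#' plus random perturbations, best likelihood wins, ties broken in favour
#' of fewer effective components. Components whose fitted amplitude falls
#' below 1e-3 are collapsed with a warning.
#'
#' @param durations Dwell durations (s), all >= `t_min`.
#' @param n_components Number of exponential components (1-3).
#' @param t_min Minimum detectable dwell (s).
#' @param n_boot Bootstrap resamples for standard errors (0 = skip).
#' @param seed Seed for the bootstrap and random restarts.
#' @param censored Optional logical right-censoring flags.
#' @param n_starts Number of optimization starts (>= 1).
#' @return An object of class `exp_mixture_fit`: a list with `components`
#'   (data.frame of amplitude, tau and bootstrap SEs, sorted by ascending
#'   tau), `loglik`, `n_obs`, `t_min`, `n_boot`.
#' @export
#' @examples
#' d <- rexp(500, 1 / 3)
#' fit_exp_mixture(d, 1)$components
fit_exp_mixture <- function(durations, n_components = 1, t_min = 0,
                            n_boot = 0, seed = NULL, censored = NULL,
                            n_starts = 10) {
  if (!n_components %in% 1:3) stop("n_components must be 1, 2 or 3")
  if (t_min < 0) stop("t_min must be >= 0")
  durations <- as.numeric(durations)
  if (any(durations < t_min - 1e-9))
    stop("all durations must be >= t_min")
  n <- length(durations)
  if (n < 10 * n_components)
    stop("need at least 10 observations per component")
  if (is.null(censored)) censored <- rep(FALSE, n)

  with_local_seed(seed, {
    fit <- fit_mixture_core(durations, censored, n_components, t_min, n_starts)
    if (any(fit$amplitudes < 1e-3) && n_components > 1) {
      warning("degenerate mixture component (amplitude < 1e-3) collapsed")
      keep <- fit$amplitudes >= 1e-3
      fit <- fit_mixture_core(durations, censored, sum(keep), t_min, n_starts)
    }
    k <- length(fit$taus)
    se_a <- rep(NA_real_, k); se_tau <- rep(NA_real_, k)
    if (n_boot > 0) {
      boot_a <- matrix(NA_real_, n_boot, k)
      boot_tau <- matrix(NA_real_, n_boot, k)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        bf <- fit_mixture_core(durations[idx], censored[idx], k, t_min,
                               n_starts = 2, init = fit)
        boot_a[b, ] <- bf$amplitudes
        boot_tau[b, ] <- bf$taus
      }
      se_a <- apply(boot_a, 2, stats::sd)
      se_tau <- apply(boot_tau, 2, stats::sd)
    }
    structure(list(
      components = data.frame(amplitude = fit$amplitudes, tau = fit$taus,
                              se_amplitude = se_a, se_tau = se_tau),
      loglik = fit$loglik, n_obs = n, t_min = t_min, n_boot = n_boot
    ), class = "exp_mixture_fit")
  })
}

# One full multi-start optimization; returns amplitudes/taus sorted by tau.
fit_mixture_core <- function(durations, censored, k, t_min, n_starts,
                             init = NULL) {
  n <- length(durations)
  obj <- function(par) {
    taus <- exp(par[seq_len(k)])
    if (any(!is.finite(taus)) || any(taus <= 0)) return(1e10)
    a <- if (k > 1) softmax0(par[(k + 1):(2 * k - 1)]) else 1
    -exp_mixture_loglik(durations, a, taus, t_min, censored)
  }

  center <- max(mean(durations) - t_min, 1e-6)
  starts <- list()
  if (!is.null(init)) {
    p0 <- c(log(init$taus),
            if (k > 1) log(init$amplitudes[-1] / init$amplitudes[1]))
    starts[[1]] <- p0
    if (n_starts > 1) starts[[2]] <- p0 + stats::rnorm(length(p0), 0, 0.15)
  }
  # moment / quantile-based spreads
  if (length(starts) < n_starts) {
    qs <- stats::quantile(pmax(durations - t_min, 1e-6),
                          probs = seq(0.15, 0.9, length.out = k))
    base <- list(rep(center, k),
                 as.numeric(qs),
                 center * 4^(seq_len(k) - (k + 1) / 2))
    for (bs in base) {
      if (length(starts) >= n_starts) break
      starts[[length(starts) + 1L]] <- c(log(pmax(bs, 1e-6)), rep(0, k - 1))
    }
    while (length(starts) < n_starts) {
      taus0 <- center * exp(stats::rnorm(k, 0, 1.2))
      w0 <- stats::rnorm(k - 1, 0, 1)
      starts[[length(starts) + 1L]] <- c(log(taus0), w0)
    }
  }

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      stats::optim(p0, obj, method = if (length(p0) == 1) "BFGS" else "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(res) && length(p0) > 1) { # polish
      res2 <- tryCatch(stats::optim(res$par, obj, method = "BFGS",
                                    control = list(maxit = 200)),
                       error = function(e) NULL)
      if (!is.null(res2) && res2$value < res$value) res <- res2
    }
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-9) best <- res
  }
  if (is.null(best)) stop("mixture optimization failed from all starts")
  taus <- exp(best$par[seq_len(k)])
  a <- if (k > 1) softmax0(best$par[(k + 1):(2 * k - 1)]) else 1
  o <- order(taus)
  list(amplitudes = a[o], taus = taus[o], loglik = -best$value)
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  k <- nrow(x$components)
  cat(sprintf("%d-exponential dwell fit (n = %d, t_min = %g s, logLik = %.2f)\n",
              k, x$n_obs, x$t_min, x$loglik))
  comp <- x$components
  for (i in seq_len(k))
    cat(sprintf("  A%d = %.3f (SE %.3g), tau%d = %.4g s (SE %.3g)\n",
                i, comp$amplitude[i], comp$se_amplitude[i],
                i, comp$tau[i], comp$se_tau[i]))
  invisible(x)
}

#' Second-order association rate constant from first-appearance times
#'
#' Fits the waiting times until first appearance of a molecule on a
#' resolvable filament segment with a single exponential (MLE: the sample
#' mean) and converts the rate into a second-order per-subunit constant by
#' dividing by concentration and the number of actin subunits per segment.
#'
#' @param waits Waiting times (s), all > 0.
#' @param concentration Solution concentration (M), > 0.
#' @param n_subunits Actin subunits per segment (default 0.4 um at
#'   370 subunits/um).
#' @return List with `k` (M^-1 s^-1 per subunit), `k_se`, `rate` (s^-1),
#'   `rate_se`, `tau` and `n`.
#' @export
fit_waiting_times <- function(waits, concentration, n_subunits = 148) {
  waits <- as.numeric(waits)
  if (any(waits <= 0)) stop("waits must be > 0")
  if (concentration <= 0) stop("concentration must be > 0")
  if (n_subunits <= 0) stop("n_subunits must be > 0")
  n <- length(waits)
  tau <- mean(waits)
  rate <- 1 / tau
  rate_se <- rate / sqrt(n)
  k <- rate / (concentration * n_subunits)
  list(k = k, k_se = rate_se / (concentration * n_subunits),
       rate = rate, rate_se = rate_se, tau = tau, n = n)
}

#' Photobleaching correction by laser-power regression
#'
#' The observed dissociation rate of a fluorophore-labeled complex is the
#' sum of the true dissociation rate and a photobleaching rate proportional
#' to excitation power. Given observed rates (with SEs) measured at several
#' laser powers for one or more constructs, fits the global weighted
#' least-squares model `rate = intercept[construct] + slope * power` with a
#' single shared slope (the photobleaching rate coefficient); the
#' intercepts are the photobleaching-corrected dissociation rates.
#'
#' @param fits_by_power data.frame with columns `construct`, `power`,
#'   `rate`, `se` (SE of the observed rate; weights are 1/se^2).
#' @return Object of class `bleach_correction`: list with `slope`,
#'   `slope_se`, `intercepts` (named vector), `intercept_se`, `fit` (the
#'   underlying `lm`), and `monotonic_flags` marking constructs whose
#'   observed rates decrease with power by more than 2 combined SEs.
#' @export
photobleach_correct <- function(fits_by_power) {
  df <- as.data.frame(fits_by_power)
  needed <- c("construct", "power", "rate", "se")
  if (!all(needed %in% names(df)))
    stop("fits_by_power needs columns construct, power, rate, se")
  if (length(unique(df$power)) < 2)
    stop("at least two distinct laser powers are required")
  if (any(df$se <= 0)) stop("rate SEs must be > 0")
  df$construct <- factor(df$construct)

  fit <- if (nlevels(df$construct) > 1)
    stats::lm(rate ~ 0 + construct + power, data = df, weights = 1 / se^2)
  else
    stats::lm(rate ~ power, data = df, weights = 1 / se^2)
  cf <- stats::coef(fit)
  # the observation SEs are known (from the dwell fits), so parameter
  # errors come from the fixed-variance covariance (X' W X)^-1 rather
  # than lm's residual-rescaled estimate, which is unstable at the few
  # power levels typical of these experiments
  X <- stats::model.matrix(fit)
  se <- sqrt(diag(solve(t(X) %*% (X / df$se^2))))
  names(se) <- names(cf)
  slope <- unname(cf["power"])
  inter <- cf[names(cf) != "power"]
  names(inter) <- if (nlevels(df$construct) > 1)
    sub("^construct", "", names(inter)) else levels(df$construct)
  inter_se <- se[names(cf) != "power"]
  names(inter_se) <- names(inter)

  # positive-slope model implies rates non-decreasing in power
  flags <- vapply(split(df, df$construct), function(g) {
    g <- g[order(g$power), ]
    d <- diff(g$rate)
    dse <- sqrt(g$se[-1]^2 + g$se[-nrow(g)]^2)
    any(d < -2 * dse)
  }, logical(1))

  structure(list(slope = slope, slope_se = unname(se["power"]),
                 intercepts = inter, intercept_se = inter_se,
                 fit = fit, monotonic_flags = flags),
            class = "bleach_correction")
}

#' @export
print.bleach_correction <- function(x, ...) {
  cat(sprintf("Photobleaching rate coefficient: %.4g +- %.2g s^-1 per power unit\n",
              x$slope, x$slope_se))
  cat("Corrected dissociation rates (s^-1):\n")
  for (nm in names(x$intercepts))
    cat(sprintf("  %s: %.4g +- %.2g%s\n", nm, x$intercepts[nm],
                x$intercept_se[nm],
                if (x$monotonic_flags[nm]) "  [non-monotonic in power]" else ""))
  invisible(x)
}
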