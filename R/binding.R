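#' Equilibrium occupancy of a ligand-binding site
#'
#' Single-site equilibrium: fraction bound = L / (L + K_D). With
#' `n_sites = 2` returns the probability that at least one of two
#' independent identical sites is occupied, `1 - (K_D / (K_D + L))^2`.
#' The single-site form is the default used for the "at least one actin
#' bound" estimate on the VCA dimer.
#'
#' @param K_D Dissociation constant (M), > 0.
#' @param ligand_conc Free ligand concentration (M), >= 0.
#' @param n_sites 1 (default) or 2 independent sites.
#' @return Fraction bound in \[0, 1\].
#' @export
#' @examples
#' equilibrium_occupancy(300e-9, 1e-6) # about 0.77
equilibrium_occupancy <- function(K_D, ligand_conc, n_sites = 1) {
  if (K_D <= 0) stop("K_D must be > 0")
  if (any(ligand_conc < 0)) stop("ligand_conc must be >= 0")
  single <- ligand_conc / (ligand_conc + K_D)
  if (n_sites == 1) single
  else if (n_sites == 2) 1 - (1 - single)^2
  else stop("n_sites must be 1 or 2")
}

#' Pseudo-first-order binding rate
#'
#' `k_obs = k_on * conc`, the expected apparent binding rate at a given
#' solution concentration.
#'
#' @param k_on Second-order association rate constant (M^-1 s^-1), >= 0.
#' @param conc Concentration (M), >= 0.
#' @return Rate in s^-1.
#' @export
#' @examples
#' expected_pseudo_first_order_rate(1e8, 5e-9) # 0.5
expected_pseudo_first_order_rate <- function(k_on, conc) {
  if (any(k_on < 0) || any(conc < 0)) stop("inputs must be non-negative")
  k_on * conc
}

#' Bound probe by exact two-species mass balance
#'
#' Concentration of receptor-probe complex for one receptor species and
#' one labeled probe, with no excess-receptor approximation: the physical
#' root of the quadratic in the complex concentration.
#'
#' @param receptor_tot,probe_tot Total concentrations (M).
#' @param K_D Dissociation constant (M), > 0.
#' @return Complex concentration (M), vectorized over `receptor_tot`.
#' @export
bound_probe_direct <- function(receptor_tot, probe_tot, K_D) {
  if (K_D <= 0) stop("K_D must be > 0")
  s <- receptor_tot + probe_tot + K_D
  (s - sqrt(s^2 - 4 * receptor_tot * probe_tot)) / 2
}

#' Free receptor in a two-ligand competition at equilibrium
#'
#' Solves the coupled mass balance for one single-site receptor R binding
#' a probe L (dissociation constant `K_probe`) and a competitor C
#' (`K_comp`):
#' `F + L F/(K_probe + F) + C F/(K_comp + F) = R_tot`,
#' equivalently the physical branch of the cubic
#' `F^3 + a F^2 + b F + c = 0` with
#' `a = K_probe + K_comp + L + C - R`,
#' `b = K_probe K_comp + K_comp (L - R) + K_probe (C - R)`,
#' `c = -K_probe K_comp R`.
#' The trigonometric root on the physical branch is polished by Newton
#' iteration on the monotone mass-balance function.
#'
#' @param receptor_tot,probe_tot,comp_tot Total concentrations (M).
#' @param K_probe,K_comp Dissociation constants (M), > 0.
#' @return List with `free_receptor`, `probe_bound`, `comp_bound` (each
#'   vectorized over `comp_tot`).
#' @export
free_receptor_competition <- function(receptor_tot, probe_tot, comp_tot,
                                      K_probe, K_comp) {
  if (K_probe <= 0 || K_comp <= 0) stop("dissociation constants must be > 0")
  if (receptor_tot < 0 || probe_tot < 0 || any(comp_tot < 0))
    stop("concentrations must be >= 0")
  R <- receptor_tot; L <- probe_tot
  FF <- vapply(comp_tot, function(C) {
    a <- K_probe + K_comp + L + C - R
    b <- K_probe * K_comp + K_comp * (L - R) + K_probe * (C - R)
    cc <- -K_probe * K_comp * R
    q <- sqrt(pmax(a^2 - 3 * b, 0))
    arg <- (-2 * a^3 + 9 * a * b - 27 * cc) / (2 * q^3)
    arg <- min(max(arg, -1), 1)
    f0 <- (2 * q * cos(acos(arg) / 3) - a) / 3
    f0 <- min(max(f0, 0), R)
    # Newton polish on g(F) = F(1 + L/(Kp+F) + C/(Kc+F)) - R, g' >= 1
    for (it in 1:50) {
      g <- f0 + L * f0 / (K_probe + f0) + C * f0 / (K_comp + f0) - R
      gp <- 1 + L * K_probe / (K_probe + f0)^2 + C * K_comp / (K_comp + f0)^2
      step <- g / gp
      f0 <- min(max(f0 - step, 0), R)
      if (abs(step) < 1e-15 * max(f0, R * 1e-12, .Machine$double.xmin)) break
    }
    if (f0 < 0 || f0 > R || !is.finite(f0))
      stop("competition solver left the physical branch")
    f0
  }, numeric(1))
  list(free_receptor = FF,
       probe_bound = L * FF / (K_probe + FF),
       comp_bound = comp_tot * FF / (K_comp + FF))
}

# anisotropy as mole-fraction-weighted average of free/bound endpoints
aniso_from_bound <- function(bound_frac, r_free, r_bound) {
  r_free + (r_bound - r_free) * bound_frac
}

#' Fit a direct fluorescence-anisotropy binding isotherm
#'
#' Nonlinear least squares of anisotropy against titrated receptor
#' concentration, with the bound probe fraction given by the exact
#' two-species mass balance ([bound_probe_direct()]) and anisotropy
#' modeled as the mole-fraction-weighted average of free and bound
#' endpoints. Fit parameters: K_D and both anisotropy endpoints.
#'
#' @param receptor_conc Titrated receptor concentrations (M), >= 5 points.
#' @param anisotropy Measured anisotropies.
#' @param probe_conc Fixed labeled-probe concentration (M).
#' @return List with `K_D`, `K_D_se`, `aniso_free`, `aniso_bound` (each
#'   with SE), the `nls` fit object, and `wide_ci` flagging a relative
#'   K_D error above 1 (no transition resolved in the data range).
#' @export
fit_direct_isotherm <- function(receptor_conc, anisotropy, probe_conc) {
  if (length(receptor_conc) < 5) stop("need at least 5 titration points")
  if (probe_conc <= 0) stop("probe_conc must be > 0")
  df <- data.frame(R = receptor_conc, r = anisotropy)
  mid <- stats::approx(anisotropy, receptor_conc,
                       xout = mean(range(anisotropy)), ties = mean)$y
  k0 <- if (is.finite(mid) && mid > 0) mid else stats::median(receptor_conc)
  fit <- minpack.lm::nlsLM(
    r ~ rf + (rb - rf) * bound_probe_direct(R, probe_conc, exp(lK)) / probe_conc,
    data = df,
    start = list(rf = min(anisotropy), rb = max(anisotropy), lK = log(k0)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  K <- exp(cf[["lK"]]); K_se <- K * se[["lK"]]
  list(K_D = K, K_D_se = K_se,
       aniso_free = cf[["rf"]], aniso_free_se = se[["rf"]],
       aniso_bound = cf[["rb"]], aniso_bound_se = se[["rb"]],
       fit = fit, wide_ci = K_se / K > 1)
}

#' Fit a competition fluorescence-anisotropy isotherm
#'
#' Nonlinear least squares of anisotropy against competitor concentration
#' at fixed probe and receptor, with the bound probe given by the full
#' two-ligand/one-receptor mass balance ([free_receptor_competition()]).
#' The probe's own K_D is held at the value determined from the direct
#' isotherm; fit parameters are the competitor K_D and the anisotropy
#' endpoints.
#'
#' @param comp_conc Competitor concentrations (M).
#' @param anisotropy Measured anisotropies.
#' @param probe_conc,receptor_conc Fixed concentrations (M).
#' @param K_D_probe Probe dissociation constant (M), from the direct fit.
#' @return List with `K_D` (competitor), `K_D_se`, anisotropy endpoints
#'   with SEs, the `nls` fit object, and `flat` flagging an unresolved
#'   displacement (relative K_D error above 1).
#' @export
fit_competition_isotherm <- function(comp_conc, anisotropy, probe_conc,
                                     receptor_conc, K_D_probe) {
  if (length(comp_conc) < 5) stop("need at least 5 titration points")
  if (K_D_probe <= 0) stop("K_D_probe must be > 0")
  df <- data.frame(C = comp_conc, r = anisotropy)
  pred <- function(C, lK, rf, rb) {
    pb <- free_receptor_competition(receptor_conc, probe_conc, C,
                                    K_D_probe, exp(lK))$probe_bound
    aniso_from_bound(pb / probe_conc, rf, rb)
  }
  fit <- minpack.lm::nlsLM(
    r ~ pred(C, lK, rf, rb), data = df,
    start = list(lK = log(K_D_probe),
                 rf = min(anisotropy), rb = max(anisotropy)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  K <- exp(cf[["lK"]]); K_se <- K * se[["lK"]]
  list(K_D = K, K_D_se = K_se,
       aniso_free = cf[["rf"]], aniso_free_se = se[["rf"]],
       aniso_bound = cf[["rb"]], aniso_bound_se = se[["rb"]],
       fit = fit, flat = K_se / K > 1)
}

#' Simulate an anisotropy titration
#'
#' Generates synthetic direct or competition titrations from known ground
#' truth, for round-trip testing of the isotherm fitters.
#'
#' @param conc Titrated concentrations (M): receptor for direct mode,
#'   competitor for competition mode.
#' @param probe_conc Probe concentration (M).
#' @param K_D_probe Probe dissociation constant (M).
#' @param receptor_conc Receptor concentration (M), competition mode only.
#' @param K_D_comp Competitor dissociation constant (M), competition mode.
#' @param aniso_free,aniso_bound Anisotropy endpoints.
#' @param noise_sd Additive Gaussian noise standard deviation (anisotropy
#'   units).
#' @param seed Seed.
#' @return data.frame with `conc` and `anisotropy`.
#' @export
simulate_titration <- function(conc, probe_conc, K_D_probe,
                               receptor_conc = NULL, K_D_comp = NULL,
                               aniso_free = 0.08, aniso_bound = 0.24,
                               noise_sd = 0, seed = NULL) {
  with_local_seed(seed, {
    bound <- if (is.null(K_D_comp)) {
      bound_probe_direct(conc, probe_conc, K_D_probe) / probe_conc
    } else {
      if (is.null(receptor_conc)) stop("competition mode needs receptor_conc")
      free_receptor_competition(receptor_conc, probe_conc, conc,
                                K_D_probe, K_D_comp)$probe_bound / probe_conc
    }
    r <- aniso_from_bound(bound, aniso_free, aniso_bound)
    if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
    data.frame(conc = conc, anisotropy = r)
  })
}
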