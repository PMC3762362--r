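#' Published colocalization kinetics of diVCA constructs
#'
#' Reference single-molecule measurements for the wild-type dimeric VCA
#' (diVCA) and the three targeted mutants (V*, C*, A*) interacting with
#' Arp2/3 complex off filament, on filament sides, and at branch sites, plus
#' the no-VCA control where applicable. These published values parameterize
#' the simulator's ground truth and serve as inputs to the derived-rate and
#' correlation analyses.
#'
#' Units: second-order rate constants in M^-1 s^-1 (`k_A_plus` is per mother
#' filament subunit), lifetimes in seconds, fractions dimensionless.
#' `A_V1` is the amplitude of the short off-filament dwell component.
#'
#' @return A data.frame with one row per construct (`none`, `wt`, `Vstar`,
#'   `Cstar`, `Astar`) and columns for each measured quantity and its
#'   standard error. VCA-specific columns are `NA` in the `none` row.
#' @export
#' @examples
#' divca_constructs()[, c("construct", "f_V_minus", "tau_V_star", "k_B")]
divca_constructs <- function() {
  data.frame(
    construct    = c("none", "wt", "Vstar", "Cstar", "Astar"),
    k_V_plus     = c(NA, 16, 7, 6, 16) * 1e7,
    k_V_plus_se  = c(NA, 5, 3, 1, 1) * 1e7,
    N_V          = c(NA, 1528, 957, 1339, 1262),
    tau_V1       = c(NA, 8, 3.6, 2.4, 40),
    tau_V1_se    = c(NA, 1, 0.4, 0.1, 10),
    A_V1         = c(NA, 0.24, 0.42, 0.98, 0.28),
    A_V1_se      = c(NA, 0.03, 0.02, 0.02, 0.09),
    tau_V2       = c(NA, 61, 56, 14, 250),
    tau_V2_se    = c(NA, 3, 3, 6, 30),
    N_A          = c(715, 877, 407, 1089, 597),
    k_A_plus     = c(2.0, 2.1, 1.3, 2, 0.8) * 1e4,
    k_A_plus_se  = c(0.3, 0.3, 0.2, 1, 0.2) * 1e4,
    f_AV         = c(NA, 0.83, 0.7, 0.59, 0.7),
    f_AV_se      = c(NA, 0.09, 0.1, 0.08, 0.1),
    f_V_minus    = c(NA, 0.026, 0.041, 0.018, 0.015),
    f_V_minus_se = c(NA, 0.004, 0.009, 0.003, 0.004),
    f_B          = c(0.006, 0.008, 0.029, 0.015, 0.013),
    f_B_se       = c(0.002, 0.002, 0.008, 0.003, 0.003),
    N_B          = c(NA, 57, 69, 69, 40),
    tau_V_star   = c(NA, 0.7, 0.54, 0.37, 0.7),
    tau_V_star_se = c(NA, 0.1, 0.08, 0.04, 0.2),
    k_V_star     = c(NA, 0.04, 0.08, 0.05, 0.022),
    k_V_star_se  = c(NA, 0.01, 0.02, 0.01, 0.008),
    k_B          = c(120, 160, 320, 200, 100),
    k_B_se       = c(40, 50, 90, 100, 30),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth kinetic parameters of the branch-formation scheme
#'
#' Bundles the rate constants of the nascent-branch kinetic scheme together
#' with the observation-independent model parameters the simulator needs.
#' The nascent branch (filament-bound Arp2/3-diVCA complex) resolves by
#' kinetic competition between intact dissociation from the filament
#' (`k_A_minus`) and diVCA release (`k_V_minus_star`); released (activated)
#' complexes nucleate a daughter with probability `p_nuc`.
#'
#' Defaults for a named `construct` are derived from [divca_constructs()]:
#' `k_V_minus_star = f_V_minus / tau_V_star`,
#' `k_A_minus = 1 / tau_V_star - k_V_minus_star`, and
#' `p_nuc = f_B / f_V_minus`.
#'
#' @param construct One of `"wt"`, `"Vstar"`, `"Cstar"`, `"Astar"`; selects
#'   default rates from the reference table. Ignored for any field supplied
#'   explicitly.
#' @param k_V_plus diVCA to Arp2/3 association rate constant (M^-1 s^-1).
#' @param k_V_minus_star diVCA release rate from the nascent branch (s^-1).
#' @param k_A_plus Arp2/3 filament-side association rate constant
#'   (M^-1 s^-1 per filament subunit).
#' @param k_A_minus Intact nascent-branch dissociation rate from the
#'   filament (s^-1).
#' @param tau_V1,tau_V2,A_V1 Two-component dwell mixture of diVCA on
#'   off-filament Arp2/3 complex: time constants (s) and short-component
#'   amplitude.
#' @param p_nuc Probability that an activated (diVCA-released,
#'   filament-bound) complex nucleates a daughter filament.
#' @param conc_diVCA,conc_arp Solution concentrations (M).
#' @param f_AV_truth Fraction of filament-binding Arp2/3 complexes arriving
#'   with diVCA bound.
#' @param subunit_density Actin subunits per micrometer of filament
#'   (2.7 nm rise per subunit gives 370 / um).
#' @param segment_length_um Length of one resolvable filament site (um).
#' @return An object of class `kinetic_params` (a validated list).
#' @export
#' @examples
#' p <- kinetic_params("wt")
#' p$k_V_minus_star * p$tau_V_star_truth() # equals f_V_minus by construction
kinetic_params <- function(construct = "wt",
                           k_V_plus = NULL,
                           k_V_minus_star = NULL,
                           k_A_plus = NULL,
                           k_A_minus = NULL,
                           tau_V1 = NULL, tau_V2 = NULL, A_V1 = NULL,
                           p_nuc = NULL,
                           conc_diVCA = 5e-9,
                           conc_arp = 5e-9,
                           f_AV_truth = NULL,
                           subunit_density = 370,
                           segment_length_um = 0.4) {
  ref <- divca_constructs()
  if (!construct %in% ref$construct[-1])
    stop("unknown construct: ", construct)
  row <- ref[ref$construct == construct, ]

  if (is.null(k_V_plus)) k_V_plus <- row$k_V_plus
  if (is.null(k_A_plus)) k_A_plus <- row$k_A_plus
  if (is.null(tau_V1)) tau_V1 <- row$tau_V1
  if (is.null(tau_V2)) tau_V2 <- row$tau_V2
  if (is.null(A_V1)) A_V1 <- row$A_V1
  if (is.null(f_AV_truth)) f_AV_truth <- row$f_AV
  if (is.null(k_V_minus_star)) k_V_minus_star <- row$f_V_minus / row$tau_V_star
  if (is.null(k_A_minus)) k_A_minus <- 1 / row$tau_V_star - k_V_minus_star
  if (is.null(p_nuc)) p_nuc <- row$f_B / row$f_V_minus

  p <- list(
    construct = construct,
    k_V_plus = k_V_plus, k_V_minus_star = k_V_minus_star,
    k_A_plus = k_A_plus, k_A_minus = k_A_minus,
    tau_V1 = tau_V1, tau_V2 = tau_V2, A_V1 = A_V1,
    p_nuc = p_nuc, conc_diVCA = conc_diVCA, conc_arp = conc_arp,
    f_AV_truth = f_AV_truth,
    subunit_density = subunit_density,
    segment_length_um = segment_length_um
  )

  rates <- c(p$k_V_plus, p$k_V_minus_star, p$k_A_plus, p$k_A_minus,
             1 / p$tau_V1, 1 / p$tau_V2)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and non-negative")
  probs <- c(p$A_V1, p$p_nuc, p$f_AV_truth)
  if (any(probs < 0 | probs > 1))
    stop("A_V1, p_nuc and f_AV_truth must lie in [0, 1]")
  if (any(c(p$conc_diVCA, p$conc_arp) < 0))
    stop("concentrations must be non-negative")

  # convenience closures for the derived scheme observables
  p$tau_V_star_truth <- function() 1 / (p$k_A_minus + p$k_V_minus_star)
  p$f_V_minus_truth <- function()
    p$k_V_minus_star / (p$k_A_minus + p$k_V_minus_star)
  class(p) <- "kinetic_params"
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Branch-formation kinetic scheme (", x$construct, ")\n", sep = "")
  cat(sprintf("  k_V+  = %.3g M^-1 s^-1   k_A+ = %.3g M^-1 s^-1 /subunit\n",
              x$k_V_plus, x$k_A_plus))
  cat(sprintf("  k_A-  = %.4g s^-1        k_V-* = %.4g s^-1\n",
              x$k_A_minus, x$k_V_minus_star))
  cat(sprintf("  implied tau_V* = %.3g s, f_V- = %.4g, p_nuc = %.3g\n",
              x$tau_V_star_truth(), x$f_V_minus_truth(), x$p_nuc))
  cat(sprintf("  off-filament diVCA dwell: %.0f%% tau %.3g s + %.0f%% tau %.3g s\n",
              100 * x$A_V1, x$tau_V1, 100 * (1 - x$A_V1), x$tau_V2))
  cat(sprintf("  [diVCA] = %.3g M, [Arp2/3] = %.3g M, f_AV(truth) = %.2f\n",
              x$conc_diVCA, x$conc_arp, x$f_AV_truth))
  invisible(x)
}

#' Camera observation model configuration
#'
#' Parameters of the model that degrades true molecular events into what a
#' TIRF camera records: exponential photobleaching proportional to
#' excitation power, a minimum detectable dwell, snapping of times to the
#' frame grid, Gaussian localization jitter, and a spatially uniform
#' Poisson background of non-specific surface binding.
#'
#' @param frame_interval Camera frame interval (s).
#' @param t_min Minimum detectable dwell (s); shorter events are missed.
#' @param bleach_rate_per_power Photobleaching rate coefficient
#'   (s^-1 per power unit).
#' @param laser_power Excitation power (arbitrary power units).
#' @param loc_sigma Localization jitter standard deviation (um).
#' @param nonspecific_rate Non-specific surface binding rate
#'   (events s^-1 um^-2, per channel).
#' @param nonspecific_mean_dwell Mean dwell of non-specific events (s).
#' @param duration Record duration (s).
#' @param fov_um Side length of the square field of view (um).
#' @param seed Integer seed for the stochastic parts of the observation
#'   model and simulators; `NULL` uses the current RNG state.
#' @return An object of class `observation_config`.
#' @export
observation_config <- function(frame_interval = 0.05,
                               t_min = 0.1,
                               bleach_rate_per_power = 0.005,
                               laser_power = 1,
                               loc_sigma = 0.05,
                               nonspecific_rate = 0.005,
                               nonspecific_mean_dwell = 0.1,
                               duration = 600,
                               fov_um = 40,
                               seed = NULL) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (t_min < 0) stop("t_min must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (laser_power < 0) stop("laser_power must be >= 0")
  if (bleach_rate_per_power < 0) stop("bleach_rate_per_power must be >= 0")
  if (loc_sigma < 0 || nonspecific_rate < 0 || fov_um <= 0)
    stop("loc_sigma and nonspecific_rate must be >= 0 and fov_um > 0")
  structure(list(
    frame_interval = frame_interval, t_min = t_min,
    bleach_rate_per_power = bleach_rate_per_power, laser_power = laser_power,
    loc_sigma = loc_sigma, nonspecific_rate = nonspecific_rate,
    nonspecific_mean_dwell = nonspecific_mean_dwell,
    duration = duration, fov_um = fov_um, seed = seed
  ), class = "observation_config")
}

# Run code under a local, restorable RNG state. Every stochastic operation
# in the package funnels through this so that an explicit seed gives
# byte-identical output without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
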