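#' Normalize a pyrene-actin polymerization trace
#'
#' Scales raw pyrene fluorescence to polymer fraction using the mean of
#' the first `baseline_frac` of points as 0% and the mean of the final
#' `plateau_frac` as 100% polymer. Polymer concentration is total actin
#' times the scaled fraction (critical-concentration offset ignored).
#'
#' @param time_s Times (s), increasing.
#' @param fluorescence Raw pyrene fluorescence (arbitrary units).
#' @param total_actin Total actin concentration (M).
#' @param baseline_frac,plateau_frac Fractions of the record averaged for
#'   the 0% and 100% anchors.
#' @return data.frame with `time_s`, `polymer_fraction`, `polymer_M`.
#' @export
normalize_pyrene_trace <- function(time_s, fluorescence, total_actin,
                                   baseline_frac = 0.02,
                                   plateau_frac = 0.05) {
  n <- length(time_s)
  if (n < 10) stop("trace too short")
  if (is.unsorted(time_s)) stop("time must be increasing")
  n0 <- max(1L, ceiling(baseline_frac * n))
  n1 <- max(1L, ceiling(plateau_frac * n))
  f0 <- mean(fluorescence[seq_len(n0)])
  f1 <- mean(fluorescence[seq.int(n - n1 + 1L, n)])
  if (f1 <= f0) stop("no fluorescence increase: not a polymerization trace")
  frac <- (fluorescence - f0) / (f1 - f0)
  data.frame(time_s = time_s, polymer_fraction = frac,
             polymer_M = total_actin * frac)
}

#' Barbed-end concentration at half-polymerization
#'
#' Normalizes the trace, fits the slope of polymer concentration against
#' time restricted to the 42-58% polymerization window, and divides by the
#' filament elongation rate to obtain the concentration of growing barbed
#' ends at the reaction midpoint.
#'
#' @inheritParams normalize_pyrene_trace
#' @param elongation_rate Elongation rate (subunits s^-1 per end),
#'   default 10.
#' @param window Polymer-fraction window for the slope fit.
#' @return List with `ends_M`, `ends_se`, `slope_M_per_s`, `slope_se`,
#'   `n_points`, `t50` (first crossing of 50%).
#' @export
barbed_ends_at_t50 <- function(time_s, fluorescence, total_actin,
                               elongation_rate = 10,
                               window = c(0.42, 0.58)) {
  if (elongation_rate <= 0) stop("elongation_rate must be > 0")
  tr <- normalize_pyrene_trace(time_s, fluorescence, total_actin)
  if (max(tr$polymer_fraction) < 0.5)
    stop("trace does not cross 50% polymerization")
  # select the window on a median-smoothed fraction so that measurement
  # noise does not correlate with point selection (which would bias the
  # slope low); the fit itself uses the raw points
  smooth_frac <- stats::runmed(tr$polymer_fraction, 5)
  sel <- smooth_frac >= window[1] & smooth_frac <= window[2]
  if (sum(sel) < 4)
    stop("fewer than 4 points in the mid-polymerization window")
  fit <- stats::lm(polymer_M ~ time_s, data = tr[sel, ])
  slope <- unname(stats::coef(fit)[2])
  slope_se <- sqrt(stats::vcov(fit)[2, 2])
  t50 <- tr$time_s[which(smooth_frac >= 0.5)[1]]
  list(ends_M = slope / elongation_rate,
       ends_se = slope_se / elongation_rate,
       slope_M_per_s = slope, slope_se = slope_se,
       n_points = sum(sel), t50 = t50)
}

#' Fold-stimulation of nucleation by an activator
#'
#' Barbed ends created by actin alone are subtracted from both the
#' activator-present and activator-absent conditions; the ratio of the
#' excesses is the fold-stimulation:
#' `(ends_arp_vca - ends_actin) / (ends_arp - ends_actin)`.
#'
#' @param ends_arp_vca Ends with Arp2/3 complex plus diVCA (M).
#' @param ends_arp Ends with Arp2/3 complex alone (M).
#' @param ends_actin Ends with actin alone (M).
#' @return Dimensionless fold-stimulation.
#' @export
#' @examples
#' fold_stimulation(5e-9, 3e-9, 1e-9) # 2
fold_stimulation <- function(ends_arp_vca, ends_arp, ends_actin) {
  if (ends_arp <= ends_actin)
    stop("ends with Arp2/3 must exceed ends from actin alone")
  (ends_arp_vca - ends_actin) / (ends_arp - ends_actin)
}

#' Simulate a bulk pyrene polymerization trace
#'
#' Two toy generators for round-trip testing. `model = "constant_ends"`
#' holds a fixed barbed-end concentration elongating at a constant rate
#' until monomer exhaustion (piecewise linear polymer growth);
#' `model = "logistic"` produces a smooth sigmoid with a prescribed
#' mid-reaction slope. Fluorescence is polymer fraction scaled by an
#' arbitrary gain and offset with additive Gaussian noise.
#'
#' @param total_actin Total actin (M).
#' @param ends Barbed-end concentration (M), constant_ends model.
#' @param elongation_rate Subunits s^-1 per end.
#' @param mid_slope Polymer production rate at midpoint (M/s), logistic
#'   model.
#' @param duration,dt Record length and sampling interval (s).
#' @param lag Delay before polymerization starts (s), constant_ends model;
#'   keeps the baseline anchor region flat as in a real mixing experiment.
#' @param gain,offset Fluorescence scale and baseline.
#' @param noise_sd Noise SD as a fraction of the fluorescence range.
#' @param model `"constant_ends"` or `"logistic"`.
#' @param seed Seed.
#' @return data.frame with `time_s` and `fluorescence`.
#' @export
simulate_pyrene_trace <- function(total_actin, ends = NULL,
                                  elongation_rate = 10, mid_slope = NULL,
                                  duration = 2000, dt = 2,
                                  lag = duration / 10,
                                  gain = 1000, offset = 50, noise_sd = 0,
                                  model = c("constant_ends", "logistic"),
                                  seed = NULL) {
  model <- match.arg(model)
  t <- seq(0, duration, by = dt)
  frac <- switch(model,
    constant_ends = {
      if (is.null(ends)) stop("constant_ends model needs ends")
      pmin(ends * elongation_rate * pmax(t - lag, 0) / total_actin, 1)
    },
    logistic = {
      if (is.null(mid_slope)) stop("logistic model needs mid_slope")
      # logistic with max slope mid_slope/total_actin at t0 = duration/3
      s <- total_actin / (4 * mid_slope)
      1 / (1 + exp(-(t - duration / 3) / s))
    })
  with_local_seed(seed, {
    fl <- offset + gain * frac
    if (noise_sd > 0)
      fl <- fl + stats::rnorm(length(fl), 0, noise_sd * gain)
    data.frame(time_s = t, fluorescence = fl)
  })
}
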