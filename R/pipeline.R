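#' Filament association rate constant from first-appearance times
#'
#' Estimates k_A+ from the waiting times until the first detected Arp2/3
#' appearance on each resolvable filament segment ([fit_waiting_times()]),
#' corrected for detection efficiency: undetected transient events thin the
#' observed arrival process by a factor p0, so the observed rate is divided
#' by `p0`.
#'
#' @param events Observed `spot_events` table with site assignment columns
#'   (see [assign_sites()]) or a raw table plus `sites`.
#' @param sites Filament site positions.
#' @param conc_arp Arp2/3 concentration (M).
#' @param p0 Detection efficiency used for the thinning correction
#'   (default 1: no correction).
#' @param n_subunits Actin subunits per segment.
#' @param site_radius Site-assignment radius (um).
#' @return The [fit_waiting_times()] list with `k` and `k_se` corrected by
#'   `1/p0`, plus `n_sites_used`.
#' @export
estimate_association_rate <- function(events, sites, conc_arp,
                                      p0 = 1, n_subunits = 148,
                                      site_radius = 0.3) {
  ev <- assign_sites(as.data.frame(events), sites, site_radius)
  arp <- ev[ev$channel == "arp" & ev$on_site, , drop = FALSE]
  if (!nrow(arp)) stop("no on-site Arp2/3 events")
  first <- tapply(arp$t_on_s, arp$assigned_site, min)
  waits <- as.numeric(first)
  waits <- waits[waits > 0]
  out <- fit_waiting_times(waits, conc_arp, n_subunits)
  out$k <- out$k / p0
  out$k_se <- out$k_se / p0
  out$n_sites_used <- length(waits)
  out
}

#' Mean diVCA lifetime on the nascent branch
#'
#' Averages the dwell times of diVCA on nascent branches. Under the
#' competing-clock scheme the nascent-branch lifetime distribution is the
#' same whether the branch resolves by co-release or by diVCA release, so
#' by default all classified nascent branches are pooled
#' (`productive_only = FALSE`); set `productive_only = TRUE` to restrict
#' to branches that produced a daughter filament.
#'
#' Two camera effects are removed analytically: detection truncation at
#' `t_min` (by memorylessness, subtract `t_min` from the mean) and frame
#' snapping (onset floored, offset ceiled inflates each dwell by one frame
#' interval in expectation).
#'
#' @param summary A [summarize_fates()] result.
#' @param t_min Minimum detectable dwell (s).
#' @param frame_interval Camera frame interval (s) used when the events
#'   were recorded.
#' @param productive_only Use only branches that nucleated a daughter.
#' @return List with `tau_V_star`, `se` (analytic, `tau / sqrt(n)` for an
#'   exponential dwell), `n`.
#' @export
estimate_tau_star <- function(summary, t_min = 0.1, frame_interval = 0.05,
                              productive_only = FALSE) {
  stopifnot(inherits(summary, "fate_summary"))
  m <- summary$matched
  sel <- if (productive_only)
    which(summary$is_branch & summary$departure_category %in% "vca_release")
  else which(summary$departure_category %in% c("corelease", "vca_release"))
  if (!length(sel))
    return(list(tau_V_star = NA_real_, se = NA_real_, n = 0L))
  dwell <- m$vca_t_off[sel] - m$vca_t_on[sel]
  tau <- mean(dwell) - t_min - frame_interval
  list(tau_V_star = tau, se = max(tau, 1e-6) / sqrt(length(dwell)),
       n = length(sel))
}

#' End-to-end rate estimation from an observed experiment
#'
#' Runs the full analysis on one simulated (or recorded) two-channel
#' experiment: fate classification with corrections, mean productive
#' nascent-branch lifetime, association rate from first-appearance times,
#' and the derived constants k_V-* and k_B with propagated errors.
#'
#' @param events Observed `spot_events` table.
#' @param sites Filament site positions (defaults to the `sites`
#'   attribute).
#' @param conc_arp Arp2/3 concentration (M).
#' @param t_min Minimum detectable dwell (s).
#' @param frame_interval Camera frame interval (s).
#' @param n_subunits Subunits per segment.
#' @param f_B_minus,f_B_minus_se Branching efficiency of diVCA-free
#'   arrivals (defaults 0: the scheme simulated here nucleates only after
#'   diVCA release).
#' @param ... Passed to [summarize_fates()].
#' @return List with the `fate_summary`, `tau_V_star` (+se, n),
#'   `k_A_plus` (+se), `k_V_star` (+se), `k_B` (+se).
#' @export
estimate_rates <- function(events, sites = attr(events, "sites"),
                           conc_arp = 5e-9, t_min = 0.1,
                           frame_interval = 0.05,
                           n_subunits = 148, f_B_minus = 0,
                           f_B_minus_se = 0, ...) {
  fs <- summarize_fates(events, sites, t_min = t_min, ...)
  ts <- estimate_tau_star(fs, t_min, frame_interval)
  ka <- estimate_association_rate(events, sites, conc_arp,
                                  p0 = fs$p0_minus,
                                  n_subunits = n_subunits)
  kv <- if (!is.na(ts$tau_V_star) && ts$tau_V_star > 0)
    compute_kv_star(fs$f_V_minus, ts$tau_V_star, fs$f_V_minus_se, ts$se)
  else list(value = NA_real_, se = NA_real_)
  kb <- compute_kB(ka$k, fs$f_AV, fs$f_B, f_B_minus,
                   ka$k_se, fs$f_AV_se, fs$f_B_se, f_B_minus_se)
  list(summary = fs,
       tau_V_star = ts$tau_V_star, tau_V_star_se = ts$se,
       n_branch_dwells = ts$n,
       k_A_plus = ka$k, k_A_plus_se = ka$k_se,
       k_V_star = kv$value, k_V_star_se = kv$se,
       k_B = kb$value, k_B_se = kb$se)
}
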