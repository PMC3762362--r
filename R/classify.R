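#' Match diVCA appearances to Arp2/3 arrivals
#'
#' For each Arp2/3 event, searches the diVCA channel for an appearance
#' within `dist_window` micrometers and `time_window` seconds of the
#' Arp2/3 arrival. Each diVCA event is matched at most once; when several
#' candidates fall inside both windows the nearest in time wins, with
#' distance as tie-break, and the ambiguity is flagged.
#'
#' @param arp,vca `spot_events` tables (single channel each).
#' @param dist_window Colocalization distance window (um), default 0.27
#'   (2 pixels).
#' @param time_window Arrival coincidence window (s), default 0.15
#'   (3 frames).
#' @return The `arp` table with added columns `vca_row` (index into `vca`,
#'   NA if none), `coincident`, `dt_on` (vca minus arp arrival time),
#'   `dist_um`, `ambiguous`, and matched diVCA times `vca_t_on`,
#'   `vca_t_off`.
#' @export
match_channels <- function(arp, vca, dist_window = 0.27, time_window = 0.15) {
  if (dist_window <= 0 || time_window <= 0)
    stop("windows must be positive")
  arp <- as.data.frame(arp); vca <- as.data.frame(vca)
  if (!nrow(arp)) stop("empty Arp2/3 event table")

  out <- arp
  out$vca_row <- NA_integer_; out$coincident <- FALSE
  out$dt_on <- NA_real_; out$dist_um <- NA_real_; out$ambiguous <- FALSE
  out$vca_t_on <- NA_real_; out$vca_t_off <- NA_real_
  if (!nrow(vca)) return(out)

  ord <- order(vca$t_on_s)
  v_t <- vca$t_on_s[ord]
  taken <- rep(FALSE, nrow(vca))
  # process arp events in time order so greedy matching is deterministic
  for (i in order(arp$t_on_s)) {
    lo <- findInterval(arp$t_on_s[i] - time_window, v_t) + 1L
    hi <- findInterval(arp$t_on_s[i] + time_window + 1e-12, v_t)
    if (hi < lo) next
    cand <- ord[lo:hi]
    cand <- cand[!taken[cand]]
    if (!length(cand)) next
    d <- sqrt((vca$x_um[cand] - arp$x_um[i])^2 +
              (vca$y_um[cand] - arp$y_um[i])^2)
    ok <- d <= dist_window
    cand <- cand[ok]; d <- d[ok]
    if (!length(cand)) next
    dt <- abs(vca$t_on_s[cand] - arp$t_on_s[i])
    best <- order(dt, d)[1]
    j <- cand[best]
    taken[j] <- TRUE
    out$vca_row[i] <- j
    out$coincident[i] <- TRUE
    out$dt_on[i] <- vca$t_on_s[j] - arp$t_on_s[i]
    out$dist_um[i] <- d[best]
    out$ambiguous[i] <- length(cand) > 1
    out$vca_t_on[i] <- vca$t_on_s[j]
    out$vca_t_off[i] <- vca$t_off_s[j]
  }
  out
}

#' Detection efficiency from a dwell-time fit
#'
#' The probability that an event lasts long enough to be detected:
#' `p0 = sum_i A_i exp(-t_min / tau_i)`, the fitted survival evaluated at
#' the minimum detectable dwell. Raw event counts are corrected by `1/p0`.
#'
#' @param fit An [fit_exp_mixture()] result, or a list with elements
#'   `amplitude` and `tau`.
#' @param t_min Minimum detectable dwell (s), >= 0.
#' @return `p0` in (0, 1].
#' @export
#' @examples
#' detection_efficiency(list(amplitude = 1, tau = 0.1443), 0.1) # 0.5
detection_efficiency <- function(fit, t_min) {
  if (t_min < 0) stop("t_min must be >= 0")
  comp <- if (inherits(fit, "exp_mixture_fit")) fit$components else
    as.data.frame(fit)
  if (abs(sum(comp$amplitude) - 1) > 1e-6)
    stop("fit amplitudes must sum to 1")
  sum(comp$amplitude * exp(-t_min / comp$tau))
}

#' Correct event counts for non-specific surface binding
#'
#' Subtracts the expected contribution of non-specific binding, estimated
#' from control regions of the field of view that contain no filament:
#' `corrected = on_target - control * area_ratio`, floored at zero.
#'
#' @param on_target_counts Counts at filament sites.
#' @param control_counts Counts in control regions.
#' @param area_ratio Ratio of on-target area to control area.
#' @return Corrected counts (same length as `on_target_counts`).
#' @export
nonspecific_correction <- function(on_target_counts, control_counts,
                                   area_ratio = 1) {
  if (area_ratio <= 0) stop("area_ratio must be > 0")
  corrected <- on_target_counts - control_counts * area_ratio
  if (any(corrected < 0)) {
    warning("control counts exceed on-target counts; flooring at 0")
    corrected <- pmax(corrected, 0)
  }
  corrected
}

#' Classify departure order of matched Arp2/3-diVCA pairs
#'
#' Partitions coincidently arrived pairs by the order of their
#' disappearances. Co-release: the two labels vanish within `time_window`
#' of each other. diVCA release: diVCA disappears first and Arp2/3 persists
#' for at least `time_window` afterwards (the activated complex). Pairs in
#' which diVCA outlasts Arp2/3 by more than the window are anomalous and
#' excluded from the fractions.
#'
#' @param matched Output of [match_channels()].
#' @param time_window Departure coincidence window (s).
#' @return List with counts `n_corelease`, `n_release`, `n_anomalous`,
#'   total `n`, fractions `f_corelease`, `f_V_minus` with counting errors,
#'   and a `category` vector aligned with the rows of `matched`
#'   (`NA` for non-coincident rows).
#' @export
classify_departures <- function(matched, time_window = 0.15) {
  if (time_window <= 0) stop("time_window must be positive")
  category <- rep(NA_character_, nrow(matched))
  idx <- which(matched$coincident)
  delta <- matched$t_off_s[idx] - matched$vca_t_off[idx] # arp minus vca
  category[idx] <- ifelse(abs(delta) <= time_window + 1e-12, "corelease",
                          ifelse(delta > time_window, "vca_release",
                                 "anomalous"))
  n_co <- sum(category == "corelease", na.rm = TRUE)
  n_rel <- sum(category == "vca_release", na.rm = TRUE)
  n_anom <- sum(category == "anomalous", na.rm = TRUE)
  n <- n_co + n_rel
  f_co <- if (n > 0) n_co / n else NA_real_
  f_rel <- if (n > 0) n_rel / n else NA_real_
  list(n_corelease = n_co, n_release = n_rel, n_anomalous = n_anom, n = n,
       f_corelease = f_co,
       f_corelease_se = if (n > 0) counting_error(f_co, n) else NA_real_,
       f_V_minus = f_rel,
       f_V_minus_se = if (n > 0) counting_error(f_rel, n) else NA_real_,
       category = category)
}

#' Arrival coincidence classification with detection-efficiency correction
#'
#' Matches diVCA appearances to Arp2/3 arrivals ([match_channels()]) and
#' estimates the coincident-arrival fraction f_AV. Raw counts in the
#' +diVCA and -diVCA arrival classes are corrected separately by the
#' inverse detection efficiency `1/p0` of each class, computed from
#' exponential-mixture fits to the class's Arp2/3 dwell times
#' ([detection_efficiency()]).
#'
#' @inheritParams match_channels
#' @param t_min Minimum detectable dwell used for the p0 correction (s).
#' @param n_components Mixture components for the dwell fits of each class.
#' @param correct_detection Apply the 1/p0 correction (default TRUE).
#' @param seed Seed for the mixture-fit restarts.
#' @return List with the matched table, raw and corrected counts, `p0_plus`,
#'   `p0_minus`, `f_AV`, `f_AV_se` (counting error on corrected counts) and
#'   `f_AV_raw`.
#' @export
classify_arrivals <- function(arp, vca, dist_window = 0.27,
                              time_window = 0.15, t_min = 0.1,
                              n_components = 2, correct_detection = TRUE,
                              seed = NULL) {
  if (!nrow(as.data.frame(vca))) stop("empty diVCA event table")
  matched <- match_channels(arp, vca, dist_window, time_window)
  n_plus <- sum(matched$coincident)
  n_minus <- sum(!matched$coincident)

  p0p <- p0m <- 1
  if (correct_detection && t_min > 0) {
    dur <- matched$t_off_s - matched$t_on_s
    p0p <- p0_from_durations(dur[matched$coincident], n_components, t_min, seed)
    p0m <- p0_from_durations(dur[!matched$coincident], n_components, t_min, seed)
  }
  N_plus <- n_plus / p0p
  N_minus <- n_minus / p0m
  f_AV <- N_plus / (N_plus + N_minus)
  list(matched = matched,
       n_coincident = n_plus, n_alone = n_minus,
       p0_plus = p0p, p0_minus = p0m,
       N_coincident_corrected = N_plus, N_alone_corrected = N_minus,
       f_AV = f_AV,
       f_AV_se = counting_error(f_AV, N_plus + N_minus),
       f_AV_raw = n_plus / (n_plus + n_minus))
}

# fit the class dwells, falling back to fewer components for small classes
p0_from_durations <- function(dur, n_components, t_min, seed = NULL) {
  dur <- dur[is.finite(dur)]
  k <- n_components
  while (k > 1 && length(dur) < 10 * k) k <- k - 1
  if (length(dur) < 10) return(1)
  fit <- suppressWarnings(
    fit_exp_mixture(dur, k, t_min = t_min, seed = seed, n_starts = 6))
  detection_efficiency(fit, t_min)
}

#' Estimate daughter filament initiation time
#'
#' Least-squares linear fit of daughter length against time; the
#' initiation time is the extrapolation of the fit line to zero length.
#' Events whose estimated initiation falls within 0.1 s of the Arp2/3
#' arrival are excluded (`included = FALSE`), since length measurement
#' noise can otherwise place nucleation before the complex arrived.
#'
#' @param t Times of length measurements (s), >= 3 points.
#' @param length_um Daughter filament lengths (um), > 0.
#' @param arrival_t Arrival time of the Arp2/3 complex at the site (s).
#' @return List with `t_init`, `t_init_se`, `slope` (um/s), `slope_se`,
#'   `included`.
#' @export
#' @examples
#' estimate_initiation_time(c(10, 20, 30), c(0.25, 0.75, 1.25), 0)$t_init # 5
estimate_initiation_time <- function(t, length_um, arrival_t) {
  if (length(t) < 3) stop("need at least 3 length points")
  if (any(length_um <= 0)) stop("lengths must be positive")
  fit <- stats::lm(length_um ~ t)
  b <- stats::coef(fit)
  if (b[2] <= 0) stop("non-positive slope: not a growing daughter")
  t_init <- unname(-b[1] / b[2])
  # exact (zero-residual) inputs trip summary.lm's perfect-fit warning
  V <- suppressWarnings(stats::vcov(fit))
  # delta method on -b0/b1
  g <- c(-1 / b[2], b[1] / b[2]^2)
  t_init_se <- sqrt(drop(t(g) %*% V %*% g))
  list(t_init = t_init, t_init_se = t_init_se,
       slope = unname(b[2]), slope_se = sqrt(V[2, 2]),
       included = t_init > arrival_t + 0.1)
}

#' Assign observed events to known filament sites
#'
#' Adds an `on_site` flag and `assigned_site` column by proximity to the
#' known site positions (the filament mask, which the experimenter has).
#'
#' @param events A `spot_events` table.
#' @param sites data.frame with `site_id`, `x_um`, `y_um` (e.g. the
#'   `sites` attribute of a simulated table).
#' @param radius Assignment radius (um).
#' @return The events table with `on_site` and `assigned_site` columns.
#' @export
assign_sites <- function(events, sites, radius = 0.3) {
  events <- as.data.frame(events)
  events$on_site <- FALSE
  events$assigned_site <- NA_integer_
  if (!nrow(events) || !nrow(sites)) return(events)
  d2 <- outer(events$x_um, sites$x_um, "-")^2 +
    outer(events$y_um, sites$y_um, "-")^2
  j <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_len(nrow(events)), j)]
  hit <- dmin <= radius^2
  events$on_site <- hit
  events$assigned_site[hit] <- sites$site_id[j[hit]]
  events
}

#' Full fate summary of a two-channel colocalization experiment
#'
#' Runs the complete classification pipeline on an observed event table:
#' assigns events to filament sites, matches channels, classifies arrival
#' coincidence (with per-class detection-efficiency correction) and
#' departure order, counts branch events from the actin channel, and
#' corrects category counts for non-specific surface binding using control
#' regions placed away from any filament.
#'
#' @param events Observed `spot_events` table (all channels together).
#' @param sites Known filament-site positions (data.frame `site_id`,
#'   `x_um`, `y_um`); defaults to the table's `sites` attribute.
#' @param dist_window,time_window Coincidence windows (um, s).
#' @param t_min Minimum detectable dwell (s) for the p0 correction.
#' @param site_radius Site-assignment radius (um).
#' @param n_components Mixture components for the p0 dwell fits.
#' @param fov_um Field-of-view side (um), for placing control regions.
#' @param correct_nonspecific,correct_detection Toggle the corrections.
#' @param max_arp_events Optionally truncate the analysis to the first
#'   `max_arp_events` on-site Arp2/3 events in time order.
#' @param seed Seed for control-region placement and fit restarts.
#' @return Object of class `fate_summary`: counts (`N_A`, `n_coincident`,
#'   `n_corelease`, `n_release`, `n_branch`), detection efficiencies,
#'   corrected fractions `f_AV`, `f_corelease`, `f_V_minus`, `f_B` with
#'   counting errors, and the matched pair table.
#' @export
summarize_fates <- function(events, sites = attr(events, "sites"),
                            dist_window = 0.27, time_window = 0.15,
                            t_min = 0.1, site_radius = 0.3,
                            n_components = 2, fov_um = NULL,
                            correct_nonspecific = TRUE,
                            correct_detection = TRUE,
                            max_arp_events = NULL, seed = NULL) {
  events <- as.data.frame(events)
  if (is.null(sites)) stop("filament site positions are required")
  if (is.null(fov_um))
    fov_um <- max(c(events$x_um, events$y_um, sites$x_um, sites$y_um, 1))

  with_local_seed(seed, {
    ev <- assign_sites(events, sites, site_radius)
    arp_on <- ev[ev$channel == "arp" & ev$on_site, , drop = FALSE]
    arp_on <- arp_on[order(arp_on$t_on_s), , drop = FALSE]
    if (!is.null(max_arp_events) && nrow(arp_on) > max_arp_events)
      arp_on <- arp_on[seq_len(max_arp_events), , drop = FALSE]
    vca_all <- ev[ev$channel == "vca", , drop = FALSE]
    actin_all <- ev[ev$channel == "actin", , drop = FALSE]

    arr <- classify_arrivals(arp_on, vca_all, dist_window, time_window,
                             t_min, n_components, correct_detection,
                             seed = NULL)
    dep <- classify_departures(arr$matched, time_window)

    # branch events: actin appearance at the pair's location during/after
    # the Arp2/3 residence
    matched <- arr$matched
    is_branch <- rep(FALSE, nrow(matched))
    if (nrow(actin_all)) {
      for (i in which(matched$coincident)) {
        d <- sqrt((actin_all$x_um - matched$x_um[i])^2 +
                  (actin_all$y_um - matched$y_um[i])^2)
        hit <- d <= dist_window &
          actin_all$t_on_s >= matched$t_on_s[i] - time_window &
          actin_all$t_on_s <= matched$t_off_s[i] + time_window
        is_branch[i] <- any(hit)
      }
    }
    n_branch <- sum(is_branch)

    # control regions: as many off-filament positions as there are sites
    ctrl <- list(n_arp = 0, n_coinc = 0, n_corelease = 0, n_release = 0)
    if (correct_nonspecific) {
      ctrl_sites <- control_positions(sites, fov_um, site_radius)
      ev_ctrl <- assign_sites(events, ctrl_sites, site_radius)
      arp_ctrl <- ev_ctrl[ev_ctrl$channel == "arp" & ev_ctrl$on_site, ,
                          drop = FALSE]
      if (nrow(arp_ctrl)) {
        arr_c <- classify_arrivals(arp_ctrl, vca_all, dist_window,
                                   time_window, t_min = 0,
                                   correct_detection = FALSE)
        dep_c <- classify_departures(arr_c$matched, time_window)
        ctrl <- list(n_arp = nrow(arp_ctrl), n_coinc = arr_c$n_coincident,
                     n_corelease = dep_c$n_corelease,
                     n_release = dep_c$n_release)
      }
    }

    # corrected category counts: non-specific subtraction on raw counts,
    # then inverse detection efficiency per arrival class
    n_coinc_c <- nonspecific_correction(arr$n_coincident, ctrl$n_coinc)
    n_alone_c <- nonspecific_correction(arr$n_alone,
                                        ctrl$n_arp - ctrl$n_coinc)
    N_plus <- n_coinc_c / arr$p0_plus
    N_minus <- n_alone_c / arr$p0_minus
    f_AV <- N_plus / (N_plus + N_minus)
    # propagate the Poisson variance of both the category counts and the
    # subtracted control counts through the corrections (delta method);
    # the bare counting error understates the error of the corrected f_AV
    var_Np <- (arr$n_coincident + ctrl$n_coinc) / arr$p0_plus^2
    var_Nm <- (arr$n_alone + max(ctrl$n_arp - ctrl$n_coinc, 0)) /
      arr$p0_minus^2
    f_AV_se <- sqrt(N_minus^2 * var_Np + N_plus^2 * var_Nm) /
      (N_plus + N_minus)^2

    n_co_c <- nonspecific_correction(dep$n_corelease, ctrl$n_corelease)
    n_rel_c <- nonspecific_correction(dep$n_release, ctrl$n_release)
    # departures and branches of the coincident class share its dwell
    # distribution and hence its detection efficiency, which cancels in
    # the fractions: raw (non-specific-corrected) ratios are unbiased
    n_pairs <- n_co_c + n_rel_c
    f_co <- if (n_pairs > 0) n_co_c / n_pairs else NA_real_
    f_rel <- if (n_pairs > 0) n_rel_c / n_pairs else NA_real_
    f_V_minus <- f_rel
    f_B <- if (n_pairs > 0) n_branch / n_pairs else NA_real_

    structure(list(
      N_A = nrow(arp_on),
      n_coincident = arr$n_coincident, n_alone = arr$n_alone,
      p0_plus = arr$p0_plus, p0_minus = arr$p0_minus,
      f_AV = f_AV,
      f_AV_se = f_AV_se,
      f_AV_counting_se = counting_error(f_AV, N_plus + N_minus),
      f_AV_raw = arr$f_AV_raw,
      n_corelease = dep$n_corelease, n_release = dep$n_release,
      n_anomalous = dep$n_anomalous, n_branch = n_branch,
      f_corelease = f_co,
      f_corelease_se = if (n_pairs > 0) counting_error(f_co, n_pairs) else NA_real_,
      f_V_minus = f_V_minus,
      f_V_minus_se = if (n_pairs > 0) counting_error(f_V_minus, n_pairs) else NA_real_,
      f_B = f_B,
      f_B_se = if (n_pairs > 0 && !is.na(f_B))
        counting_error(f_B, n_pairs) else NA_real_,
      control_counts = ctrl,
      matched = matched, departure_category = dep$category,
      is_branch = is_branch
    ), class = "fate_summary")
  })
}

# random positions at least 2*radius away from every real site
control_positions <- function(sites, fov_um, radius) {
  n <- nrow(sites)
  out <- matrix(NA_real_, 0, 2)
  guard <- 0
  while (nrow(out) < n && guard < 50) {
    cand <- cbind(stats::runif(2 * n, 0, fov_um),
                  stats::runif(2 * n, 0, fov_um))
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      min((sites$x_um - cand[i, 1])^2 + (sites$y_um - cand[i, 2])^2) >
        (2 * radius)^2
    }, logical(1))
    out <- rbind(out, cand[ok, , drop = FALSE])
    guard <- guard + 1
  }
  out <- out[seq_len(min(n, nrow(out))), , drop = FALSE]
  data.frame(site_id = seq_len(nrow(out)) - 1L,
             x_um = out[, 1], y_um = out[, 2])
}

#' @export
print.fate_summary <- function(x, ...) {
  cat(sprintf("Fate summary: N_A = %d Arp2/3 events (%d coincident, %d alone)\n",
              x$N_A, x$n_coincident, x$n_alone))
  cat(sprintf("  p0(+diVCA) = %.3f, p0(-diVCA) = %.3f\n",
              x$p0_plus, x$p0_minus))
  cat(sprintf("  f_AV = %.3f +- %.3f (raw %.3f)\n",
              x$f_AV, x$f_AV_se, x$f_AV_raw))
  cat(sprintf("  departures: %d co-release, %d diVCA release, %d anomalous, %d branches\n",
              x$n_corelease, x$n_release, x$n_anomalous, x$n_branch))
  cat(sprintf("  f_corelease = %.4f +- %.4f, f_V- = %.4f +- %.4f, f_B = %.4f\n",
              x$f_corelease, x$f_corelease_se, x$f_V_minus, x$f_V_minus_se,
              x$f_B))
  invisible(x)
}
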