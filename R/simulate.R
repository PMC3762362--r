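#' Spot event tables
#'
#' The pipeline's universal currency is a table of spot-level single-molecule
#' events: one row per appearance/disappearance of a fluorescent spot in one
#' channel at one site. Columns are `site_id` (0-based integer), `channel`
#' (`"arp"`, `"vca"` or `"actin"`), `x_um`, `y_um` (positions in micrometers),
#' `t_on_s`, `t_off_s` (appearance/disappearance times in seconds) and
#' `fate` (ground-truth tag where known, `NA` otherwise).
#'
#' @param site_id,channel,x_um,y_um,t_on_s,t_off_s,fate Column vectors.
#' @return A `data.frame` of class `spot_events`.
#' @export
spot_event_table <- function(site_id = integer(), channel = character(),
                             x_um = numeric(), y_um = numeric(),
                             t_on_s = numeric(), t_off_s = numeric(),
                             fate = NA_character_) {
  df <- data.frame(site_id = as.integer(site_id),
                   channel = as.character(channel),
                   x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   t_on_s = as.numeric(t_on_s), t_off_s = as.numeric(t_off_s),
                   fate = rep_len(as.character(fate), length(site_id)),
                   stringsAsFactors = FALSE)
  validate_spot_events(df)
}

validate_spot_events <- function(df) {
  needed <- c("site_id", "channel", "x_um", "y_um", "t_on_s", "t_off_s", "fate")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("event table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    bad <- which(!(df$t_off_s > df$t_on_s))
    if (length(bad))
      stop("t_off_s must exceed t_on_s; offending rows: ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
      stop("non-finite coordinates in event table")
    if (any(df$site_id < 0)) stop("site_id must be non-negative")
    if (!all(df$channel %in% c("arp", "vca", "actin")))
      stop("channel must be one of 'arp', 'vca', 'actin'")
  }
  class(df) <- unique(c("spot_events", class(df)))
  df
}

#' Simulate Arp2/3 and diVCA dynamics at filament sites
#'
#' Continuous-time Markov chain simulation of the branch-formation pathway
#' at `n_sites` resolvable filament segments. At each site, Arp2/3 complexes
#' arrive as a Poisson process with rate
#' `k_A_plus * conc_arp * subunit_density * segment_length_um`; each arrival
#' carries diVCA with probability `f_AV_truth`. A diVCA-bound arrival (the
#' nascent branch) resolves by competing exponential clocks: intact
#' dissociation of the Arp2/3-diVCA complex from the filament (`k_A_minus`,
#' co-release of both labels) versus diVCA release (`k_V_minus_star`,
#' leaving an activated filament-bound Arp2/3 complex). Activated complexes
#' nucleate a daughter filament with probability `p_nuc`; they remain bound
#' for the rest of the record either way, so their disappearance is set by
#' photobleaching in the observation model. Arrivals without diVCA dwell
#' exponentially with rate `k_A_minus` and leave.
#'
#' Returns the true (pre-observation) event stream; pass it through
#' [apply_observation_model()] to emulate what the camera records. Daughter
#' nucleation additionally emits an `actin` channel event starting at the
#' diVCA release time.
#'
#' Ground-truth `fate` tags: `"corelease"`, `"vca_release_branch"`,
#' `"vca_release_no_branch"`, `"arp_only"`.
#'
#' @param params A [kinetic_params()] object.
#' @param n_sites Number of filament sites (>= 1).
#' @param obs An [observation_config()]; supplies `duration`, `fov_um` and
#'   the seed.
#' @return A `spot_events` table with attributes `sites` (data.frame of
#'   site_id, x_um, y_um) and `params`.
#' @export
#' @examples
#' p <- kinetic_params("wt")
#' ev <- simulate_filament_sites(p, 5, observation_config(duration = 120, seed = 1))
#' table(ev$channel)
simulate_filament_sites <- function(params, n_sites, obs) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(obs, "observation_config"))
  if (n_sites < 1) stop("n_sites must be >= 1")

  with_local_seed(obs$seed, {
    lambda_arr <- params$k_A_plus * params$conc_arp *
      params$subunit_density * params$segment_length_um
    k_tot <- params$k_A_minus + params$k_V_minus_star
    p_rel <- if (k_tot > 0) params$k_V_minus_star / k_tot else 0

    sites <- data.frame(site_id = seq_len(n_sites) - 1L,
                        x_um = stats::runif(n_sites, 0, obs$fov_um),
                        y_um = stats::runif(n_sites, 0, obs$fov_um))
    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      sid <- sites$site_id[i]; sx <- sites$x_um[i]; sy <- sites$y_um[i]
      t <- 0
      ev <- list()
      repeat {
        if (lambda_arr <= 0) break
        t_on <- t + stats::rexp(1, lambda_arr)
        if (t_on >= obs$duration) break
        has_vca <- stats::runif(1) < params$f_AV_truth
        if (has_vca) {
          dwell <- if (k_tot > 0) stats::rexp(1, k_tot) else Inf
          released <- stats::runif(1) < p_rel
          if (released) {
            vca_off <- min(t_on + dwell, obs$duration)
            nucleates <- stats::runif(1) < params$p_nuc
            fate <- if (nucleates) "vca_release_branch" else "vca_release_no_branch"
            ev[[length(ev) + 1L]] <- data.frame(
              site_id = sid, channel = c("arp", "vca"), x_um = sx, y_um = sy,
              t_on_s = t_on, t_off_s = c(obs$duration, vca_off), fate = fate)
            if (nucleates && vca_off < obs$duration)
              ev[[length(ev) + 1L]] <- data.frame(
                site_id = sid, channel = "actin", x_um = sx, y_um = sy,
                t_on_s = vca_off, t_off_s = obs$duration, fate = fate)
            break # site permanently occupied by the activated complex
          } else {
            t_off <- min(t_on + dwell, obs$duration)
            ev[[length(ev) + 1L]] <- data.frame(
              site_id = sid, channel = c("arp", "vca"), x_um = sx, y_um = sy,
              t_on_s = t_on, t_off_s = t_off, fate = "corelease")
            t <- t_off
            if (t >= obs$duration) break
          }
        } else {
          dwell <- if (params$k_A_minus > 0)
            stats::rexp(1, params$k_A_minus) else Inf
          t_off <- min(t_on + dwell, obs$duration)
          ev[[length(ev) + 1L]] <- data.frame(
            site_id = sid, channel = "arp", x_um = sx, y_um = sy,
            t_on_s = t_on, t_off_s = t_off, fate = "arp_only")
          t <- t_off
          if (t >= obs$duration) break
        }
      }
      rows[[i]] <- if (length(ev)) do.call(rbind, ev) else NULL
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) out <- spot_event_table()
    out <- out[out$t_off_s > out$t_on_s, , drop = FALSE]
    out <- out[order(out$site_id, out$t_on_s, out$channel), , drop = FALSE]
    rownames(out) <- NULL
    out <- validate_spot_events(out)
    attr(out, "sites") <- sites
    attr(out, "params") <- params
    out
  })
}

#' Simulate diVCA binding to surface-tethered Arp2/3 complexes
#'
#' Each tethered molecule alternates between unoccupied intervals
#' (exponential, rate `k_V_plus * conc_diVCA`) and occupied intervals drawn
#' from the two-component dwell mixture (`A_V1`, `tau_V1`, `tau_V2`).
#' Emits `vca`-channel events only; the tethered Arp2/3 spot itself is
#' continuously present and not tabulated.
#'
#' @inheritParams simulate_filament_sites
#' @param n_molecules Number of tethered Arp2/3 complexes; 0 gives an empty
#'   table.
#' @return A `spot_events` table (true events) with a `sites` attribute.
#' @export
simulate_tethered_arp <- function(params, n_molecules, obs) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(obs, "observation_config"))
  if (params$conc_diVCA <= 0) stop("conc_diVCA must be > 0")
  if (n_molecules == 0) {
    out <- spot_event_table()
    attr(out, "sites") <- data.frame(site_id = integer(),
                                     x_um = numeric(), y_um = numeric())
    return(out)
  }

  with_local_seed(obs$seed, {
    k_on <- params$k_V_plus * params$conc_diVCA
    sites <- data.frame(site_id = seq_len(n_molecules) - 1L,
                        x_um = stats::runif(n_molecules, 0, obs$fov_um),
                        y_um = stats::runif(n_molecules, 0, obs$fov_um))
    rows <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      t <- 0; ev <- list()
      repeat {
        t_on <- t + stats::rexp(1, k_on)
        if (t_on >= obs$duration) break
        tau <- if (stats::runif(1) < params$A_V1) params$tau_V1 else params$tau_V2
        t_off <- min(t_on + stats::rexp(1, 1 / tau), obs$duration)
        ev[[length(ev) + 1L]] <- data.frame(
          site_id = sites$site_id[i], channel = "vca",
          x_um = sites$x_um[i], y_um = sites$y_um[i],
          t_on_s = t_on, t_off_s = t_off, fate = "tethered")
        t <- t_off
        if (t >= obs$duration) break
      }
      rows[[i]] <- if (length(ev)) do.call(rbind, ev) else NULL
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) out <- spot_event_table()
    out <- out[out$t_off_s > out$t_on_s, , drop = FALSE]
    rownames(out) <- NULL
    out <- validate_spot_events(out)
    attr(out, "sites") <- sites
    attr(out, "params") <- params
    out
  })
}

#' Degrade true events into what the camera records
#'
#' Applies, in order: (1) an independent exponential photobleaching clock at
#' rate `bleach_rate_per_power * laser_power` that can end each event early;
#' (2) removal of events whose (bleach-shortened) continuous duration is
#' below `t_min`; (3) snapping of times to the frame grid (`t_on_s` floored,
#' `t_off_s` ceiled); (4) Gaussian localization jitter of standard deviation
#' `loc_sigma` on each position; (5) addition of non-specific surface
#' binding events as a spatial Poisson process of rate `nonspecific_rate`
#' per channel, with exponential dwells of mean `nonspecific_mean_dwell`,
#' subject to the same detection limit and frame grid.
#'
#' @param true_events A `spot_events` table of true events.
#' @param obs An [observation_config()]. A `seed` here makes the whole
#'   observation model reproducible.
#' @return A `spot_events` table of observed events; the `sites` attribute
#'   of the input, if any, is carried through.
#' @export
apply_observation_model <- function(true_events, obs) {
  stopifnot(inherits(obs, "observation_config"))
  true_events <- validate_spot_events(as.data.frame(true_events))
  if (obs$laser_power < 0) stop("laser_power must be >= 0")
  sites <- attr(true_events, "sites")

  with_local_seed(obs$seed, {
    ev <- true_events
    n <- nrow(ev)
    b <- obs$bleach_rate_per_power * obs$laser_power
    if (n && b > 0) {
      bleach_at <- ev$t_on_s + stats::rexp(n, b)
      ev$t_off_s <- pmin(ev$t_off_s, bleach_at)
    }
    if (nrow(ev)) {
      keep <- (ev$t_off_s - ev$t_on_s) >= obs$t_min
      ev <- ev[keep, , drop = FALSE]
    }
    if (nrow(ev) && obs$loc_sigma > 0) {
      ev$x_um <- ev$x_um + stats::rnorm(nrow(ev), 0, obs$loc_sigma)
      ev$y_um <- ev$y_um + stats::rnorm(nrow(ev), 0, obs$loc_sigma)
    }

    # non-specific surface binding, per channel present (or arp+vca default)
    if (obs$nonspecific_rate > 0) {
      channels <- unique(ev$channel)
      if (!length(channels)) channels <- c("arp", "vca")
      area <- obs$fov_um^2
      next_id <- if (nrow(ev)) max(ev$site_id) + 1L else
        if (!is.null(sites) && nrow(sites)) max(sites$site_id) + 1L else 0L
      ns_rows <- list()
      for (ch in channels) {
        if (ch == "actin") next
        n_ns <- stats::rpois(1, obs$nonspecific_rate * area * obs$duration)
        if (n_ns == 0) next
        t_on <- stats::runif(n_ns, 0, obs$duration)
        t_off <- pmin(t_on + stats::rexp(n_ns, 1 / obs$nonspecific_mean_dwell),
                      obs$duration)
        df <- data.frame(site_id = next_id + seq_len(n_ns) - 1L, channel = ch,
                         x_um = stats::runif(n_ns, 0, obs$fov_um),
                         y_um = stats::runif(n_ns, 0, obs$fov_um),
                         t_on_s = t_on, t_off_s = t_off, fate = "nonspecific")
        df <- df[(df$t_off_s - df$t_on_s) >= obs$t_min, , drop = FALSE]
        next_id <- next_id + n_ns
        ns_rows[[ch]] <- df
      }
      if (length(ns_rows)) ev <- rbind(ev, do.call(rbind, ns_rows))
    }

    if (nrow(ev)) {
      dt <- obs$frame_interval
      ev$t_on_s <- floor(ev$t_on_s / dt) * dt
      ev$t_off_s <- ceiling(ev$t_off_s / dt) * dt
      ev <- ev[ev$t_off_s > ev$t_on_s, , drop = FALSE]
      ev <- ev[order(ev$site_id, ev$t_on_s, ev$channel), , drop = FALSE]
      rownames(ev) <- NULL
    }
    ev <- validate_spot_events(ev)
    attr(ev, "sites") <- sites
    ev
  })
}
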