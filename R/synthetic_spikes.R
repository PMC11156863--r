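## Synthetic spike-train generator with planted co-activation ensembles.
## Every generator draws from its own seed stream derived from rng_seed, so
## adding a generator (or an extra session) never perturbs other outputs.

DEFAULT_AREAS <- c("dHPC", "iHPC", "RSC", "PrL", "IL", "Cg1")

## Deterministic per-operation seed stream: label is hashed into a small
## offset, mixed with the base seed; result stays inside 32-bit range.
stream_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + index * 104729) %% 2147483629) + 1L
}

#' Simulation configuration for the synthetic dataset
#'
#' Defaults describe the study conditions exercised throughout the test
#' suite: 60 units spread over six cortical/hippocampal areas, background
#' Poisson firing at 5 Hz, three planted ensembles of eight members each
#' activating at 0.1 Hz with 80% member participation and 3 ms spike
#' jitter, SWRs at 0.2 Hz, and one 20-minute session.
#'
#' @param n_units number of simulated units.
#' @param area_assignment character vector of length `n_units`; by default
#'   areas are assigned round-robin over dHPC, iHPC, RSC, PrL, IL, Cg1.
#' @param background_rates per-unit background firing rate (Hz); a scalar
#'   is recycled.
#' @param n_ensembles,members_per_ensemble planted ensemble geometry
#'   (member sets are disjoint, drawn without replacement).
#' @param event_rate ensemble activation rate (Hz).
#' @param p_participate probability a member emits its extra spike at an
#'   activation event.
#' @param jitter_sd s.d. (s) of member spike jitter around the event time;
#'   must stay below `bin_width / 2` so planted events do not straddle bins
#'   by construction.
#' @param swr_rate planted sharp-wave ripple rate (Hz).
#' @param swr_coupling_prob probability that an ensemble is SWR-coupled.
#' @param swr_coupled optional logical vector (one flag per ensemble)
#'   fixing which ensembles are SWR-coupled instead of drawing them with
#'   `swr_coupling_prob`.
#' @param swr_coupling_jitter s.d. (s) of coupled event times around the
#'   SWR centers.
#' @param sessions data.frame with `day_stamp` (integer days, strictly
#'   increasing) and `duration` (s).
#' @param dropout_prob per-session per-unit probability of being
#'   undetectable (all-or-none for that session).
#' @param ensemble_session_mask optional list (one integer vector per
#'   ensemble) restricting which sessions an ensemble activates in;
#'   `NULL` means all sessions.
#' @param bin_width analysis bin width (s), used only to validate
#'   `jitter_sd`.
#' @param rng_seed integer seed; all generators derive their streams
#'   from it.
#' @param swr_amplitude_sd planted ripple amplitude, in units of the
#'   baseline LFP s.d.
#' @param lfp_noise_sd baseline LFP noise s.d. (uV).
#' @param ripple_freq ripple carrier frequency (Hz).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_units = 60,
                       area_assignment = NULL,
                       background_rates = 5,
                       n_ensembles = 3,
                       members_per_ensemble = 8,
                       event_rate = 0.1,
                       p_participate = 0.8,
                       jitter_sd = 0.003,
                       swr_rate = 0.2,
                       swr_coupling_prob = 0,
                       swr_coupled = NULL,
                       swr_coupling_jitter = 0.01,
                       sessions = data.frame(day_stamp = 0L, duration = 1200),
                       dropout_prob = 0,
                       ensemble_session_mask = NULL,
                       bin_width = 0.025,
                       rng_seed = 1L,
                       swr_amplitude_sd = 5,
                       lfp_noise_sd = 20,
                       ripple_freq = 180) {
  if (is.null(area_assignment)) {
    area_assignment <- DEFAULT_AREAS[((seq_len(n_units) - 1L) %% length(DEFAULT_AREAS)) + 1L]
  }
  stopifnot(length(area_assignment) == n_units)
  background_rates <- rep_len(background_rates, n_units)
  if (any(background_rates < 0) || event_rate < 0 || swr_rate < 0) {
    stop("sim config error: rates must be >= 0")
  }
  for (p in c(p_participate, swr_coupling_prob, dropout_prob)) {
    if (p < 0 || p > 1) stop("sim config error: probabilities must lie in [0, 1]")
  }
  if (jitter_sd >= bin_width / 2) {
    stop("sim config error: jitter_sd must be < bin_width / 2 ",
         "(events would straddle bins by construction)")
  }
  if (n_ensembles * members_per_ensemble > n_units) {
    stop("sim config error: not enough units for disjoint ensemble member sets")
  }
  if (nrow(sessions) > 1 && any(diff(sessions$day_stamp) <= 0)) {
    stop("sim config error: session day_stamps must be strictly increasing")
  }
  if (!is.null(ensemble_session_mask) && length(ensemble_session_mask) != n_ensembles) {
    stop("sim config error: ensemble_session_mask must have one entry per ensemble")
  }
  if (!is.null(swr_coupled) && length(swr_coupled) != n_ensembles) {
    stop("sim config error: swr_coupled must have one flag per ensemble")
  }
  structure(list(
    n_units = as.integer(n_units), area_assignment = area_assignment,
    background_rates = background_rates,
    n_ensembles = as.integer(n_ensembles),
    members_per_ensemble = as.integer(members_per_ensemble),
    event_rate = event_rate, p_participate = p_participate,
    jitter_sd = jitter_sd, swr_rate = swr_rate,
    swr_coupling_prob = swr_coupling_prob, swr_coupled = swr_coupled,
    swr_coupling_jitter = swr_coupling_jitter,
    sessions = sessions, dropout_prob = dropout_prob,
    ensemble_session_mask = ensemble_session_mask,
    bin_width = bin_width, rng_seed = as.integer(rng_seed),
    swr_amplitude_sd = swr_amplitude_sd, lfp_noise_sd = lfp_noise_sd,
    ripple_freq = ripple_freq
  ), class = "sim_config")
}

poisson_times <- function(rate, duration) {
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}

#' Simulate multi-session spike trains with planted ensembles
#'
#' Background spikes are homogeneous Poisson per unit. Each planted
#' ensemble activates at Poisson event times snapped to analysis-bin
#' centers, so that with `jitter_sd < bin_width / 2` a planted
#' co-activation always falls inside one bin — the ground truth the
#' detector is meant to recover; SWR-coupled ensembles instead activate
#' at the planted SWR centers, each taken with probability
#' `min(1, event_rate / swr_rate)` and jittered by
#' `Normal(0, swr_coupling_jitter)`. At every event each member emits one
#' extra spike at `event_time + Normal(0, jitter_sd)` with probability
#' `p_participate`. Units in a session's dropout set emit nothing that
#' session.
#'
#' @param cfg a [sim_config()].
#' @return list with `spike_tables` (one `spike_table` per session) and
#'   `ground_truth`: `ensembles` (member ids, per-session event times,
#'   `swr_coupled` flag), `swr_times` (per-session planted ripple centers),
#'   `dropout` (per-session vector of undetectable unit ids).
#' @export
simulate_spike_trains <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_sessions <- nrow(cfg$sessions)
  unit_ids <- seq_len(cfg$n_units) - 1L   # 0-based ids
  ## structural draws (membership, coupling flags, dropout) on their own stream
  set.seed(stream_seed(cfg$rng_seed, "structure"))
  members <- list()
  pool <- sample(unit_ids)
  if (cfg$n_ensembles > 0) {
    for (e in seq_len(cfg$n_ensembles)) {
      members[[e]] <- sort(pool[seq_len(cfg$members_per_ensemble) +
                                  (e - 1L) * cfg$members_per_ensemble])
    }
  }
  swr_coupled <- if (!is.null(cfg$swr_coupled)) {
    cfg$swr_coupled
  } else if (cfg$n_ensembles > 0) {
    stats::runif(cfg$n_ensembles) < cfg$swr_coupling_prob
  } else logical(0)
  dropout <- lapply(seq_len(n_sessions), function(s) {
    unit_ids[stats::runif(cfg$n_units) < cfg$dropout_prob]
  })

  ## planted SWR centers per session
  swr_times <- lapply(seq_len(n_sessions), function(s) {
    set.seed(stream_seed(cfg$rng_seed, "swr_times", s))
    poisson_times(cfg$swr_rate, cfg$sessions$duration[s])
  })

  ensembles <- lapply(seq_len(cfg$n_ensembles), function(e) {
    list(members = members[[e]], swr_coupled = swr_coupled[e],
         event_times = vector("list", n_sessions))
  })

  spike_tables <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    dur <- cfg$sessions$duration[s]
    set.seed(stream_seed(cfg$rng_seed, "spikes", s))
    times <- list(); units <- list(); k <- 0L
    dropped <- dropout[[s]]
    for (u in seq_len(cfg$n_units)) {
      uid <- unit_ids[u]
      if (uid %in% dropped) next
      ts <- poisson_times(cfg$background_rates[u], dur)
      if (length(ts) > 0) {
        k <- k + 1L; times[[k]] <- ts; units[[k]] <- rep(uid, length(ts))
      }
    }
    ## planted ensemble events
    for (e in seq_len(cfg$n_ensembles)) {
      allowed <- is.null(cfg$ensemble_session_mask) ||
        s %in% cfg$ensemble_session_mask[[e]]
      ev <- numeric(0)
      if (allowed) {
        if (swr_coupled[e]) {
          if (cfg$swr_rate > 0 && length(swr_times[[s]]) > 0) {
            p_take <- min(1, cfg$event_rate / cfg$swr_rate)
            take <- stats::runif(length(swr_times[[s]])) < p_take
            ev <- swr_times[[s]][take] +
              stats::rnorm(sum(take), 0, cfg$swr_coupling_jitter)
            ev <- sort(ev[ev >= 0 & ev < dur])
          }
        } else {
          ## snap to bin centers: planted co-activations occupy one bin
          ev <- poisson_times(cfg$event_rate, dur)
          ev <- (floor(ev / cfg$bin_width) + 0.5) * cfg$bin_width
        }
      }
      ensembles[[e]]$event_times[[s]] <- ev
      if (length(ev) > 0) {
        for (m in ensembles[[e]]$members) {
          if (m %in% dropped) next
          fire <- stats::runif(length(ev)) < cfg$p_participate
          if (any(fire)) {
            ts <- ev[fire] + stats::rnorm(sum(fire), 0, cfg$jitter_sd)
            ts <- ts[ts >= 0 & ts < dur]
            if (length(ts) > 0) {
              k <- k + 1L; times[[k]] <- ts; units[[k]] <- rep(m, length(ts))
            }
          }
        }
      }
    }
    if (k == 0L) {
      df <- data.frame(spike_time_s = numeric(0), unit_id = integer(0),
                       contact_id = integer(0), area = character(0))
    } else {
      uu <- unlist(units)
      df <- data.frame(spike_time_s = unlist(times),
                       unit_id = uu,
                       contact_id = uu,   # one contact per unit in simulation
                       area = cfg$area_assignment[uu + 1L])
    }
    spike_tables[[s]] <- as_spike_table(df)
  }

  list(spike_tables = spike_tables,
       ground_truth = list(ensembles = ensembles, swr_times = swr_times,
                           dropout = dropout))
}
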