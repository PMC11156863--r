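## Ensemble activation dynamics: quadratic activation strength, SWR
## coupling, member/non-member firing contrasts, lifetimes, and the
## lifetime-vs-SWR-tuning classification.

#' Projection operator of an ensemble pattern
#'
#' Outer product of the (member-restricted, re-normalized) weight vector
#' with the diagonal set exactly to zero, so spiking of a single neuron
#' cannot inflate the activation strength.
#'
#' @param w member weight vector (will be re-normalized to unit norm).
#' @return symmetric m x m matrix with zero diagonal.
#' @export
projection_operator <- function(w) {
  if (length(w) < 2) stop("single-member ensemble: projection operator would be all-zero")
  w <- w / sqrt(sum(w^2))
  P <- tcrossprod(w)
  diag(P) <- 0
  P
}

#' Instantaneous ensemble activation strength
#'
#' Per 25-ms bin, `A(t) = z(t)' P z(t)` where `z(t)` is the member
#' neurons' z-scored activity and `P` the zero-diagonal outer product of
#' the member weights (re-normalized to unit norm over the members).
#' Because the diagonal is zeroed, bins where only one member fires give
#' exactly 0, and `A` can be negative (it is not clipped). The ensemble
#' counts as active where `A` exceeds
#' `mean(A) + sd_multiplier * s.d.(A)` (default multiplier 2); with
#' `threshold_mode = "supra_baseline"` the s.d. is taken over the values
#' above the trace mean instead.
#'
#' @param activity a `binned_activity`.
#' @param pattern an `ensemble_pattern`.
#' @param sd_multiplier threshold multiplier (default 2).
#' @param members_only restrict the quadratic form to member neurons
#'   (default, following the definition); `FALSE` uses all neurons with
#'   the full weight vector.
#' @param threshold_mode `"all"` (default) or `"supra_baseline"`.
#' @return an `activation_trace`: list with `A` (per bin), `threshold`,
#'   `active_bins`, `session_slices`, `member_idx`, `bin_width`.
#' @export
activation_strength <- function(activity, pattern, sd_multiplier = 2,
                                members_only = TRUE,
                                threshold_mode = c("all", "supra_baseline")) {
  threshold_mode <- match.arg(threshold_mode)
  idx <- if (members_only) which(pattern$member_mask) else seq_along(pattern$weights)
  if (length(idx) == 0) stop("pattern has no members")
  if (length(idx) < 2) stop("single-member ensemble: activation strength undefined (P all-zero)")
  w <- pattern$weights[idx]
  w <- w / sqrt(sum(w^2))
  Zm <- activity$Z[idx, , drop = FALSE]
  A <- quad_strength(w, Zm)
  mu <- mean(A)
  sdev <- switch(threshold_mode,
                 all = stats::sd(A),
                 supra_baseline = stats::sd(A[A > mu]))
  threshold <- mu + sd_multiplier * sdev
  structure(list(A = A, threshold = threshold, active_bins = A > threshold,
                 session_slices = activity$session_slices,
                 member_idx = idx, member_weights = w,
                 bin_width = activity$bin_width),
            class = "activation_trace")
}

## Zero-diagonal quadratic form per bin: A = (sum_i u_i)^2 - sum_i u_i^2
## with u_i = w_i z_i. Using the same products u_i in both terms makes
## bins with a single nonzero member cancel exactly in floating point.
quad_strength <- function(w, Zm) {
  U <- w * Zm
  colSums(U)^2 - colSums(U * U)
}

#' Chance rate of supra-threshold activation bins
#'
#' Estimates how often the activation strength exceeds the trace's
#' threshold by chance co-firing alone, by circularly shifting each
#' member's z-scored row by an independent random offset (which preserves
#' every neuron's rate and autocorrelation while destroying co-firing)
#' and recomputing the activation trace against the real threshold.
#' Feed the result to [ensemble_lifetime()] to require per-session
#' activation beyond this chance level.
#'
#' @param activity `binned_activity`.
#' @param trace `activation_trace` of the ensemble (carries the member
#'   set, weights and threshold).
#' @param n_shuffles surrogate draws (default 5).
#' @param seed RNG seed for the shifts.
#' @return chance probability per bin of exceeding the threshold.
#' @export
chance_crossing_rate <- function(activity, trace, n_shuffles = 5L, seed = 1L) {
  Zm <- activity$Z[trace$member_idx, , drop = FALSE]
  N <- ncol(Zm)
  set.seed(seed)
  hits <- 0
  for (s in seq_len(n_shuffles)) {
    Zs <- Zm
    for (r in seq_len(nrow(Zm))) {
      off <- sample.int(N - 1L, 1L)
      Zs[r, ] <- Zm[r, c((off + 1L):N, 1L:off)]
    }
    hits <- hits + sum(quad_strength(trace$member_weights, Zs) > trace$threshold)
  }
  hits / (n_shuffles * N)
}

## ---- sharp-wave ripple detection ------------------------------------------

band_pass_channels <- function(lfp, channels, band) {
  fs <- lfp$fs
  if (band[2] >= fs / 2) stop("config error: ripple band must lie below fs / 2")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  t(apply(lfp$samples[channels, , drop = FALSE], 1,
          function(x) signal::filtfilt(bf, x)))
}

#' Detect sharp-wave ripples by the normalized-squared-signal method
#'
#' Each ripple channel is band-passed (zero-phase 4th-order Butterworth,
#' forward-backward); the NSS is the z-scored mean over channels of the
#' squared band-passed signal, smoothed with a centered moving average
#' (11 frames at 1250 Hz, scaled to `fs`, the convention of the classic
#' NSS detection scripts) so single noise cycles cannot cross the peak
#' threshold. Candidate intervals where the NSS exceeds
#' `baseline_sd` are merged when separated by less than `merge_gap`,
#' kept when their NSS peak exceeds `peak_sd`, and kept when their
#' duration lies within `event_duration_bounds`.
#'
#' @param lfp an `lfp_record`.
#' @param ripple_channels channel indices carrying the ripple oscillation.
#' @param config a `run_config` (thresholds, band, duration bounds).
#' @return `swr_events` data.frame: `start`, `end`, `peak` (s),
#'   `aligned_center` (NA until [align_swr()]), `peak_nss`.
#' @export
detect_swr <- function(lfp, ripple_channels = PYR_CHANNELS, config = load_config()) {
  if (length(ripple_channels) < 1) stop("need at least one ripple channel")
  filt <- band_pass_channels(lfp, ripple_channels, config$ripple_band)
  sq <- colMeans(matrix(filt^2, nrow = length(ripple_channels)))
  fs <- lfp$fs
  sq <- moving_average(sq, max(1L, round(11 * fs / 1250)))
  nss <- (sq - mean(sq)) / stats::sd(sq)
  above <- nss > config$baseline_sd
  if (!any(above)) return(empty_swr_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  ## merge intervals separated by < merge_gap
  gap_samp <- config$merge_gap * fs
  if (nrow(iv) > 1) {
    merged <- list(iv[1, ])
    for (i in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[i, 1] - last[2] < gap_samp) {
        merged[[length(merged)]] <- c(last[1], iv[i, 2])
      } else {
        merged[[length(merged) + 1L]] <- iv[i, ]
      }
    }
    iv <- do.call(rbind, merged)
  }
  keep <- logical(nrow(iv)); peak_t <- numeric(nrow(iv)); peak_nss <- numeric(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    seg <- nss[iv[i, 1]:iv[i, 2]]
    peak_nss[i] <- max(seg)
    ## supra-baseline power centroid: symmetric, so the peak estimate is not
    ## quantized by the smoothing window beating against the carrier
    wgt <- pmax(seg - config$baseline_sd, 0)
    idx <- iv[i, 1]:iv[i, 2]
    peak_t[i] <- if (sum(wgt) > 0) sum(wgt * (idx - 1L)) / sum(wgt) / fs else
      (idx[which.max(seg)] - 1L) / fs
    dur <- (iv[i, 2] - iv[i, 1] + 1L) / fs
    keep[i] <- peak_nss[i] > config$peak_sd &&
      dur >= config$event_duration_bounds[1] &&
      dur <= config$event_duration_bounds[2]
  }
  if (!any(keep)) return(empty_swr_events())
  out <- data.frame(start = (iv[keep, 1] - 1L) / fs,
                    end = iv[keep, 2] / fs,
                    peak = peak_t[keep],
                    aligned_center = NA_real_,
                    peak_nss = peak_nss[keep])
  class(out) <- c("swr_events", "data.frame")
  out
}

## centered moving average with shrinking windows at the edges
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  half <- w %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

empty_swr_events <- function() {
  out <- data.frame(start = numeric(0), end = numeric(0), peak = numeric(0),
                    aligned_center = numeric(0), peak_nss = numeric(0))
  class(out) <- c("swr_events", "data.frame")
  out
}

#' Align SWR events to a mean-ripple template
#'
#' Two-step alignment: events are first centered at their NSS power peak;
#' a template is then formed as the mean band-passed window over events
#' and each event is shifted to the lag maximizing its cross-correlation
#' with the template, clamped to `align_max_shift` samples (10 samples =
#' 5 ms at 2 kHz). One refinement pass recomputes the template from the
#' aligned windows; the total shift never exceeds the clamp. Events whose
#' window would extend past the recording edge are dropped with a
#' warning.
#'
#' @param events `swr_events` from [detect_swr()] (>= 2 events).
#' @param lfp the `lfp_record` the events came from.
#' @param ripple_channels channels averaged for the template.
#' @param config `run_config` (band, `align_max_shift`).
#' @param window_s half-window length (s) of the template.
#' @return `events` with `aligned_center` filled in.
#' @export
align_swr <- function(events, lfp, ripple_channels = PYR_CHANNELS,
                      config = load_config(), window_s = 0.025) {
  if (nrow(events) < 2) stop("alignment needs >= 2 events to form a template")
  fs <- lfp$fs
  max_shift <- config$align_max_shift
  half <- round(window_s * fs)
  filt <- band_pass_channels(lfp, ripple_channels, config$ripple_band)
  m <- colMeans(matrix(filt, nrow = length(ripple_channels)))
  n <- length(m)
  peak_i <- round(events$peak * fs) + 1L
  ok <- peak_i - half - max_shift >= 1L & peak_i + half + max_shift <= n
  if (any(!ok)) {
    warning(sum(!ok), " event(s) dropped: alignment window extends past the recording edge")
  }
  events <- events[ok, , drop = FALSE]
  peak_i <- peak_i[ok]
  if (nrow(events) < 2) stop("alignment needs >= 2 events after edge filtering")
  offs <- (-half):half
  win_at <- function(centers) {
    t(vapply(centers, function(ci) m[ci + offs], numeric(length(offs))))
  }
  shifts <- integer(nrow(events))
  for (pass in 1:2) {
    template <- colMeans(win_at(peak_i + shifts))
    for (e in seq_len(nrow(events))) {
      lags <- (-max_shift):max_shift
      cc <- vapply(lags, function(L) {
        tot <- shifts[e] + L
        if (abs(tot) > max_shift) return(-Inf)   # clamp cumulative shift
        sum(template * m[peak_i[e] + tot + offs])
      }, 0)
      shifts[e] <- shifts[e] + lags[which.max(cc)]
    }
  }
  events$aligned_center <- (peak_i - 1L + shifts) / fs
  events
}

#' SWR-triggered ensemble activation tuning
#'
#' Averages the activation trace over lags -20..+20 bins around each SWR
#' center; the tuning statistic is the peak of this peri-event average
#' within +/-2 bins of lag 0, minus the mean over the baseline flank
#' (lags -20..-10).
#'
#' @param trace an `activation_trace`.
#' @param swr_times ripple center times: a numeric vector (seconds within
#'   a single session) or a list of per-session vectors matching the
#'   trace's `session_slices`.
#' @param session session index when `swr_times` is a plain vector.
#' @return list with `tuning` (scalar; `NA` if no SWR falls inside the
#'   trace span), `peri` (the 41-lag peri-event average), `lags`,
#'   `n_events`.
#' @export
swr_triggered_activation <- function(trace, swr_times, session = 1L) {
  if (!is.list(swr_times)) {
    tmp <- vector("list", length(trace$session_slices))
    tmp[[session]] <- swr_times
    swr_times <- tmp
  }
  lags <- -20:20
  bins <- integer(0)
  for (s in seq_along(swr_times)) {
    ts <- swr_times[[s]]
    if (length(ts) == 0) next
    sl <- trace$session_slices[[s]]
    b <- sl["first"] + floor(ts / trace$bin_width)
    nb_last <- sl["last"]
    bins <- c(bins, b[b >= sl["first"] & b <= nb_last])
  }
  n_total <- length(trace$A)
  bins <- bins[bins + min(lags) >= 1 & bins + max(lags) <= n_total]
  if (length(bins) == 0) {
    return(list(tuning = NA_real_, peri = rep(NA_real_, length(lags)),
                lags = lags, n_events = 0L))
  }
  peri <- rowMeans(vapply(bins, function(b) trace$A[b + lags], numeric(length(lags))))
  peak <- max(peri[lags >= -2 & lags <= 2])
  baseline <- mean(peri[lags >= -20 & lags <= -10])
  list(tuning = peak - baseline, peri = peri, lags = lags,
       n_events = length(bins))
}

#' Member vs non-member firing-rate contrast during ensemble activation
#'
#' For each neuron, the mean z-scored count over the trace's active bins;
#' neurons are grouped member/non-member within each area and compared by
#' a two-sided t test. Areas with fewer than two neurons in either group
#' are skipped with a warning.
#'
#' @param activity `binned_activity`.
#' @param pattern `ensemble_pattern`.
#' @param trace `activation_trace` for that pattern.
#' @return list with `per_neuron` (unit, area, member, mean_z) and
#'   `per_area` (area, member/non-member means and s.d., t, p).
#' @export
member_rate_contrast <- function(activity, pattern, trace) {
  if (!any(trace$active_bins)) stop("no active bins: contrast undefined")
  mz <- rowMeans(activity$Z[, trace$active_bins, drop = FALSE])
  per_neuron <- data.frame(unit_id = activity$unit_ids, area = activity$areas,
                           member = pattern$member_mask, mean_z = mz)
  res <- list()
  for (ar in unique(per_neuron$area)) {
    sub <- per_neuron[per_neuron$area == ar, ]
    mem <- sub$mean_z[sub$member]; non <- sub$mean_z[!sub$member]
    if (length(mem) < 2 || length(non) < 2) {
      warning("area ", ar, " skipped: fewer than 2 neurons in a group")
      next
    }
    tt <- stats::t.test(mem, non, alternative = "two.sided")
    res[[length(res) + 1L]] <- data.frame(
      area = ar, n_member = length(mem), n_nonmember = length(non),
      member_mean = mean(mem), member_sd = stats::sd(mem),
      nonmember_mean = mean(non), nonmember_sd = stats::sd(non),
      t = unname(tt$statistic), p = tt$p.value)
  }
  list(per_neuron = per_neuron,
       per_area = if (length(res)) do.call(rbind, res) else NULL)
}

#' Ensemble lifetime across sessions
#'
#' A session counts as active when at least `min_active_bins` of its bins
#' exceed the trace threshold; when a `chance_rate` (from
#' [chance_crossing_rate()]) is supplied, the session must additionally
#' exceed the binomial upper bound (level `1 - alpha`) of chance
#' crossings for its bin count, which keeps long sessions from counting
#' as active through chance co-firing alone. Lifetime is the calendar
#' span (days) from
#' the first to the last active session; dormant sessions inside the span
#' are reported but do not shorten it (ensembles may fall silent for days
#' and re-emerge). A single active session gives lifetime 0; none gives
#' `NA`.
#'
#' @param trace `activation_trace` over the concatenated sessions.
#' @param manifest `session_manifest` (supplies `day_stamp`).
#' @param min_active_bins per-session activity criterion (default 5).
#' @param chance_rate optional per-bin chance crossing probability from
#'   [chance_crossing_rate()].
#' @param alpha tail level of the binomial chance bound (default 0.001).
#' @return list with `lifetime_days`, `active_sessions` (indices),
#'   `dormant_sessions` (inactive sessions inside the span),
#'   `active_bin_counts`.
#' @export
ensemble_lifetime <- function(trace, manifest, min_active_bins = 5L,
                              chance_rate = NULL, alpha = 0.001) {
  slices <- trace$session_slices
  stopifnot(length(slices) == nrow(manifest))
  counts <- vapply(slices, function(sl) {
    sum(trace$active_bins[sl["first"]:sl["last"]])
  }, 0L)
  need <- rep(min_active_bins, length(counts))
  if (!is.null(chance_rate)) {
    nb <- vapply(slices, function(sl) sl["last"] - sl["first"] + 1L, 0L)
    need <- pmax(need, stats::qbinom(1 - alpha, nb, chance_rate) + 1L)
  }
  active <- which(counts >= need)
  if (length(active) == 0) {
    return(list(lifetime_days = NA_real_, active_sessions = integer(0),
                dormant_sessions = integer(0), active_bin_counts = counts))
  }
  days <- manifest$day_stamp
  life <- days[max(active)] - days[min(active)]
  inside <- seq(min(active), max(active))
  list(lifetime_days = as.numeric(life),
       active_sessions = active,
       dormant_sessions = setdiff(inside, active),
       active_bin_counts = counts)
}

#' Member-detectability duration (the > 2/3 rule)
#'
#' A unit is detectable in a session when it has at least one spike
#' there. The statistic is the longest run of consecutive sessions in
#' which strictly more than two-thirds of the ensemble's members are
#' detectable, reported as the calendar span (days) of that run.
#'
#' @param spike_tables per-session spike tables (or a per-session list of
#'   detectable unit ids).
#' @param member_ids ensemble member unit ids.
#' @param manifest `session_manifest`.
#' @return span in days (0 for a single-session run).
#' @export
member_detectability <- function(spike_tables, member_ids, manifest) {
  detectable <- lapply(spike_tables, function(st) {
    if (is.data.frame(st)) unique(st$unit_id) else st
  })
  stopifnot(length(detectable) == nrow(manifest))
  frac <- vapply(detectable, function(d) mean(member_ids %in% d), 0)
  ok <- frac > 2 / 3            # strict inequality
  days <- manifest$day_stamp
  best <- 0
  i <- 1L
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      best <- max(best, days[j] - days[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!any(ok)) return(NA_real_)
  as.numeric(best)
}

#' Classify ensembles by SWR tuning and lifetime
#'
#' Quadrant rule with data-driven cutoffs: `cutoff_tuning = mean + s.d.`
#' of the SWR tunings and `cutoff_life = mean + s.d.` of the lifetimes.
#' `short_lived_high_tuning` when tuning > cutoff_tuning and lifetime <
#' cutoff_life; `long_lived_low_tuning` when lifetime > cutoff_life and
#' tuning < cutoff_tuning; everything else `other`. Records with
#' undefined tuning or lifetime are excluded from the cutoffs and
#' labelled `NA`.
#'
#' @param records data.frame with columns `ensemble_id`, `swr_tuning`,
#'   `lifetime_days` (other columns pass through).
#' @return `records` with `class_label` plus attributes `cutoff_tuning`
#'   and `cutoff_life`.
#' @export
classify_ensembles <- function(records) {
  ok <- is.finite(records$swr_tuning) & is.finite(records$lifetime_days)
  if (sum(ok) < 2) stop("classification needs >= 2 records with defined tuning and lifetime")
  tun <- records$swr_tuning[ok]; life <- records$lifetime_days[ok]
  cutoff_tuning <- mean(tun) + stats::sd(tun)
  cutoff_life <- mean(life) + stats::sd(life)
  lab <- rep(NA_character_, nrow(records))
  lab[ok] <- ifelse(records$swr_tuning[ok] > cutoff_tuning &
                      records$lifetime_days[ok] < cutoff_life,
                    "short_lived_high_tuning",
             ifelse(records$lifetime_days[ok] > cutoff_life &
                      records$swr_tuning[ok] < cutoff_tuning,
                    "long_lived_low_tuning", "other"))
  records$class_label <- lab
  attr(records, "cutoff_tuning") <- cutoff_tuning
  attr(records, "cutoff_life") <- cutoff_life
  records
}
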