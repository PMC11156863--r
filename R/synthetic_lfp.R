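## Synthetic laminar LFP with planted sharp-wave ripples.
##
## Baseline is 1/f-shaped noise per channel. Each planted SWR adds
##   (a) a Gaussian-enveloped ripple-band oscillation on "pyramidal"
##       channels (default 180 Hz carrier, 10 ms envelope s.d.),
##   (b) a negative sharp-wave deflection on "radiatum" channels,
##   (c) a positive deflection on "oriens" channels.
## Ripple amplitude is expressed in units of the baseline noise s.d.

LAMINAR_LABELS <- c("oriens1", "oriens2", "pyr1", "pyr2", "pyr3",
                    "rad1", "rad2", "rad3")
PYR_CHANNELS <- 3:5
ORIENS_CHANNELS <- 1:2
RAD_CHANNELS <- 6:8

## 1/f-shaped noise via spectral shaping of white noise; unit variance.
one_over_f_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                      # avoid division by zero at DC
  f <- pmin(f, n - f + 1)                        # fold to physical frequency
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE)) / n
  as.numeric(scale(shaped))
}

#' Simulate laminar LFP with planted sharp-wave ripples
#'
#' @param cfg a [sim_config()]; uses `swr_rate`, `swr_amplitude_sd`,
#'   `lfp_noise_sd` and `ripple_freq`.
#' @param duration recording length (s); defaults to the first session's
#'   duration.
#' @param swr_times optional vector of ripple centers (s) to plant; by
#'   default the centers are drawn from the same per-session seed stream
#'   as [simulate_spike_trains()], so spikes and LFP share ground truth.
#' @param session session index for the default seed stream.
#' @param fs sampling rate (Hz).
#' @return list with `lfp` (an `lfp_record`, 8 laminar channels) and
#'   `swr_times` (the planted centers, s).
#' @export
simulate_lfp_with_swr <- function(cfg, duration = NULL, swr_times = NULL,
                                  session = 1L, fs = 2000) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$ripple_freq >= fs / 2) {
    stop("sim config error: ripple_freq must be below fs / 2")
  }
  if (is.null(duration)) duration <- cfg$sessions$duration[session]
  if (is.null(swr_times)) {
    set.seed(stream_seed(cfg$rng_seed, "swr_times", session))
    swr_times <- poisson_times(cfg$swr_rate, duration)
  }
  n <- round(duration * fs)
  nch <- length(LAMINAR_LABELS)
  set.seed(stream_seed(cfg$rng_seed, "lfp", session))
  samples <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    samples[ch, ] <- one_over_f_noise(n) * cfg$lfp_noise_sd
  }
  amp <- cfg$swr_amplitude_sd * cfg$lfp_noise_sd
  t_axis <- (seq_len(n) - 1) / fs   # sample i sits at (i-1)/fs, matching read_lfp

  env_sd <- 0.010      # ripple envelope s.d. (s); ~50 ms event
  sw_sd <- 0.030       # sharp-wave deflection s.d. (s)
  for (t0 in swr_times) {
    idx <- which(abs(t_axis - t0) < 4 * sw_sd)
    if (length(idx) == 0) next
    dt <- t_axis[idx] - t0
    ripple <- amp * exp(-dt^2 / (2 * env_sd^2)) *
      cos(2 * pi * cfg$ripple_freq * dt)
    sharp <- amp * 0.8 * exp(-dt^2 / (2 * sw_sd^2))
    for (ch in PYR_CHANNELS) samples[ch, idx] <- samples[ch, idx] + ripple
    for (ch in RAD_CHANNELS) samples[ch, idx] <- samples[ch, idx] - sharp
    for (ch in ORIENS_CHANNELS) samples[ch, idx] <- samples[ch, idx] + 0.5 * sharp
  }
  lfp <- new_lfp_record(samples, fs, LAMINAR_LABELS, uv_per_bit = 0.1)
  list(lfp = lfp, swr_times = swr_times)
}
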