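## Synthetic mean-waveform blocks for the unit-tracking metrics.
##
## Each unit gets a biphasic temporal template (negative trough followed by
## a smaller positive rebound) with a Gaussian spatial decay across the
## contact array, centered on a unit-specific contact. Per time block the
## observed waveform is template * (1 + multiplicative drift) + noise.

biphasic_shape <- function(n_samples, trough_frac = 0.35, trough_sd = 0.05,
                           rebound_sd = 0.12, rebound_amp = 0.35) {
  x <- seq(0, 1, length.out = n_samples)
  -exp(-(x - trough_frac)^2 / (2 * trough_sd^2)) +
    rebound_amp * exp(-(x - trough_frac - 0.25)^2 / (2 * rebound_sd^2))
}

#' Simulate drifting waveform blocks for unit tracking
#'
#' @param cfg a [sim_config()] (supplies the seed stream).
#' @param n_track_units number of tracked units.
#' @param n_blocks number of time blocks (sessions).
#' @param n_contacts,n_samples waveform geometry (contacts x samples).
#' @param peak_uv template trough amplitude (uV) at the center contact.
#' @param spatial_sd spatial decay of the template across contacts
#'   (in contact units).
#' @param snr template peak over noise s.d.; noise s.d. is `peak_uv / snr`.
#' @param drift_per_block s.d. of the per-block multiplicative amplitude
#'   drift (e.g. 0.02 for 2% per block).
#' @param spikes_per_block individual spike snippets drawn per block
#'   (template + noise), used for the PCA feature space.
#' @return list with `blocks` (one `waveform_block` per unit x block:
#'   `unit_id`, `block_id`, `mean_waveform` contacts x samples,
#'   `center_contact`, `n_spikes`, `spikes` n_spikes x (contacts*samples)
#'   matrix) and `ground_truth` (`templates` per unit, `center_contacts`,
#'   `noise_sd`).
#' @export
simulate_waveform_blocks <- function(cfg, n_track_units = 10, n_blocks = 6,
                                     n_contacts = 64, n_samples = 41,
                                     peak_uv = 100, spatial_sd = 1.5,
                                     snr = 5, drift_per_block = 0.02,
                                     spikes_per_block = 40) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_samples < 3) stop("sim config error: n_samples must be >= 3")
  set.seed(stream_seed(cfg$rng_seed, "waveforms"))
  noise_sd <- peak_uv / snr
  ## distinct center contacts (away from the array edge), distinct shapes
  usable <- seq(4L, n_contacts - 3L)
  centers <- sample(usable, n_track_units, replace = n_track_units > length(usable))
  templates <- vector("list", n_track_units)
  for (u in seq_len(n_track_units)) {
    shape <- biphasic_shape(n_samples,
                            trough_frac = stats::runif(1, 0.3, 0.4),
                            trough_sd = stats::runif(1, 0.04, 0.07),
                            rebound_amp = stats::runif(1, 0.25, 0.45))
    spatial <- exp(-((seq_len(n_contacts) - centers[u])^2) / (2 * spatial_sd^2))
    templates[[u]] <- peak_uv * outer(spatial, shape)   # contacts x samples
  }
  blocks <- list()
  i <- 0L
  for (u in seq_len(n_track_units)) {
    drift <- cumprod(1 + c(0, stats::rnorm(n_blocks - 1, 0, drift_per_block)))
    for (b in seq_len(n_blocks)) {
      tmpl <- templates[[u]] * drift[b]
      spikes <- matrix(rep(as.numeric(tmpl), each = spikes_per_block),
                       nrow = spikes_per_block) +
        matrix(stats::rnorm(spikes_per_block * length(tmpl), 0, noise_sd),
               nrow = spikes_per_block)
      mean_wf <- matrix(colMeans(spikes), n_contacts, n_samples)
      i <- i + 1L
      blocks[[i]] <- structure(list(
        unit_id = u - 1L, block_id = b - 1L,
        mean_waveform = mean_wf,
        center_contact = center_contact(mean_wf),
        n_spikes = spikes_per_block,
        spikes = spikes), class = "waveform_block")
    }
  }
  list(blocks = blocks,
       ground_truth = list(templates = templates,
                           center_contacts = centers - 1L,
                           noise_sd = noise_sd))
}

#' Center contact of a waveform: contact holding the largest |amplitude|
#' @param mean_waveform contacts x samples matrix
#' @return 0-based contact index
#' @export
center_contact <- function(mean_waveform) {
  which.max(apply(abs(mean_waveform), 1, max)) - 1L
}
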