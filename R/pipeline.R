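## End-to-end orchestration: dataset simulation to disk, and the full
## analysis pipeline (binning -> MP/ICA ensemble detection -> activation ->
## SWR detection/alignment -> tuning/lifetime/classification), with a
## machine-readable run report per invocation.

#' Simulate a dataset and write it to disk
#'
#' Writes per-session spike tables (TSV), LFP binaries with JSON sidecars,
#' a session manifest, the run configuration and `ground_truth.json`
#' (ensemble members, per-session event times, SWR centers, dropout).
#' Deterministic given `seed`.
#'
#' @param cfg a [sim_config()]; its `rng_seed` is replaced by `seed`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param with_lfp also simulate and write LFP per session.
#' @return the manifest path, invisibly; the manifest indexes everything.
#' @export
simulate_dataset <- function(cfg, out_dir, seed = cfg$rng_seed, with_lfp = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create output directory ", out_dir)
  cfg$rng_seed <- as.integer(seed)
  sim <- simulate_spike_trains(cfg)
  n_sessions <- nrow(cfg$sessions)
  st_paths <- character(n_sessions); lfp_paths <- rep(NA_character_, n_sessions)
  for (s in seq_len(n_sessions)) {
    st_paths[s] <- file.path(out_dir, sprintf("session%02d_spikes.tsv", s))
    write_spike_table(sim$spike_tables[[s]], st_paths[s])
    if (with_lfp) {
      lf <- simulate_lfp_with_swr(cfg, session = s,
                                  swr_times = sim$ground_truth$swr_times[[s]])
      lfp_paths[s] <- file.path(out_dir, sprintf("session%02d_lfp.bin", s))
      write_lfp(lf$lfp, lfp_paths[s])
    }
  }
  manifest <- as_session_manifest(data.frame(
    session_id = sprintf("session%02d", seq_len(n_sessions)),
    day_stamp = cfg$sessions$day_stamp,
    duration_s = cfg$sessions$duration,
    spike_table = basename(st_paths),
    lfp = ifelse(is.na(lfp_paths), NA_character_, basename(lfp_paths))))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_session_manifest(manifest, manifest_path)
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(ensembles = lapply(gt$ensembles, function(e) {
           list(members = e$members, swr_coupled = e$swr_coupled,
                event_times = e$event_times)
         }),
         swr_times = gt$swr_times, dropout = gt$dropout),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

read_manifest_tables <- function(manifest, base_dir) {
  lapply(manifest$spike_table, function(p) {
    read_spike_table(file.path(base_dir, p))
  })
}

#' Run the full analysis pipeline
#'
#' Stages, mirroring the analysis order: bin and z-score the concatenated
#' sessions; correlation spectrum and Marcenko-Pastur count; ICA pattern
#' extraction with Otsu membership; activation traces with the
#' 2-s.d. threshold; SWR detection and alignment per session (skipped
#' with a warning when a session has no LFP); SWR-triggered tuning,
#' lifetimes and the lifetime-vs-tuning classification. Outputs are
#' written under `out_dir` together with a run report JSON.
#'
#' @param manifest_path path to a session manifest TSV; sibling files are
#'   resolved relative to its directory.
#' @param out_dir output directory.
#' @param config a `run_config` (see [load_config()]).
#' @param seed seed for the ICA restarts.
#' @param skip_swr skip the SWR stages even if LFP is present.
#' @param members_only restrict activation strength to member neurons.
#' @return list with `activity`, `spectrum`, `patterns`, `traces`,
#'   `swr_events` (per session), `records` (classified dynamics records),
#'   `report`.
#' @export
run_full_pipeline <- function(manifest_path, out_dir, config = load_config(),
                              seed = config$rng_seed, skip_swr = FALSE,
                              members_only = TRUE) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_dir <- dirname(manifest_path)
  manifest <- read_session_manifest(manifest_path)
  tables <- read_manifest_tables(manifest, base_dir)
  warnings_log <- character(0)

  activity <- withCallingHandlers(
    bin_and_zscore(tables, bin_width = config$bin_width,
                   durations = manifest$duration_s),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  spectrum <- correlation_matrix(activity)
  k <- count_significant(spectrum)
  patterns <- if (k > 0) {
    extract_patterns(activity, k, seed = seed,
                     ica_restarts = config$ica_restarts)
  } else list()
  write_ensembles_json(patterns, activity, file.path(out_dir, "ensembles.json"))

  ## SWR detection per session
  swr_events <- vector("list", nrow(manifest))
  swr_centers <- vector("list", nrow(manifest))
  have_lfp <- !skip_swr & !is.na(manifest$lfp) & nzchar(manifest$lfp)
  for (s in seq_len(nrow(manifest))) {
    if (!have_lfp[s]) {
      if (!skip_swr) {
        warnings_log <- c(warnings_log,
                          paste0("session ", s, ": no LFP; SWR stage skipped"))
      }
      swr_centers[[s]] <- numeric(0)
      next
    }
    lfp <- read_lfp(file.path(base_dir, manifest$lfp[s]))
    ev <- detect_swr(lfp, config = config)
    if (nrow(ev) >= 2) ev <- align_swr(ev, lfp, config = config)
    swr_events[[s]] <- ev
    swr_centers[[s]] <- if (nrow(ev) > 0) {
      ifelse(is.na(ev$aligned_center), ev$peak, ev$aligned_center)
    } else numeric(0)
    write_swr_events(ev, file.path(out_dir, sprintf("session%02d_swr.tsv", s)))
  }

  ## dynamics records
  records <- NULL; traces <- list()
  usable <- Filter(function(p) sum(p$member_mask) >= 2, patterns)
  if (length(usable) > 0) {
    rows <- lapply(usable, function(p) {
      tr <- activation_strength(activity, p,
                                sd_multiplier = config$activation_sd_multiplier,
                                members_only = members_only)
      traces[[length(traces) + 1L]] <<- tr
      life <- ensemble_lifetime(tr, manifest,
                                chance_rate = chance_crossing_rate(activity, tr,
                                                                   seed = seed))
      tun <- swr_triggered_activation(tr, swr_centers)
      det <- member_detectability(tables, activity$unit_ids[p$member_mask], manifest)
      data.frame(ensemble_id = p$ensemble_id, swr_tuning = tun$tuning,
                 lifetime_days = life$lifetime_days,
                 detectability_days = det)
    })
    records <- do.call(rbind, rows)
    if (sum(is.finite(records$swr_tuning) & is.finite(records$lifetime_days)) >= 2) {
      records <- classify_ensembles(records)
    } else {
      records$class_label <- NA_character_
    }
    utils::write.table(records, file.path(out_dir, "dynamics_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    stage = "full_pipeline",
    manifest = manifest_path,
    n_sessions = nrow(manifest),
    n_neurons = nrow(activity$Z),
    n_bins = activity$n_bins,
    n_significant = k,
    n_patterns = length(patterns),
    seed = seed,
    config = unclass(config)[names(run_config_defaults())],
    warnings = warnings_log,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(activity = activity, spectrum = spectrum, patterns = patterns,
       traces = traces, swr_events = swr_events, records = records,
       report = report)
}
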