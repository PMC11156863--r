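## Run configuration: flat key-value text, every key typed and validated.
## Defaults anchor to the analysis conventions used throughout the package:
## 25 ms bins, 130-200 Hz ripple band, NSS thresholds 2/5 s.d., event
## durations 30-100 ms, 30 ms merge gap, +/-10-sample alignment bound at
## 2 kHz, activation threshold mean + 2 s.d.

run_config_defaults <- function() {
  list(
    bin_width = 0.025,                 # s, co-activation window
    ripple_low = 130,                  # Hz
    ripple_high = 200,                 # Hz
    baseline_sd = 2,                   # NSS baseline threshold (z units)
    peak_sd = 5,                       # NSS peak threshold (z units)
    min_duration = 0.03,               # s, SWR duration bounds
    max_duration = 0.1,                # s
    merge_gap = 0.03,                  # s, merge events closer than this
    align_max_shift = 10,              # samples, alignment clamp
    activation_sd_multiplier = 2,      # threshold = mean + k * s.d.
    rng_seed = 1,
    ica_restarts = 5
  )
}

#' Load run configuration
#'
#' Reads a flat key-value text file (lines of `key value` or `key = value`;
#' blank lines and `#` comments ignored). Missing keys take the documented
#' defaults: 25 ms bins, ripple band 130-200 Hz, NSS thresholds 2 / 5 s.d.,
#' SWR duration bounds 30-100 ms, 30 ms merge gap, alignment clamp 10
#' samples, activation threshold multiplier 2.
#'
#' @param path config file path, or `NULL` for all defaults.
#' @return a `run_config` list; `ripple_band` and `event_duration_bounds`
#'   are exposed as length-2 vectors derived from the flat keys.
#' @export
load_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(gsub("=", " ", ln), "[[:space:]]+")[[1]]
      parts <- parts[nzchar(parts)]
      if (length(parts) != 2) stop("config parse error on line: '", ln, "'")
      key <- parts[1]
      if (!key %in% names(cfg)) {
        stop("unknown config key '", key, "'; valid keys: ",
             paste(names(cfg), collapse = ", "))
      }
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val)) stop("config parse error: non-numeric value for '", key, "': ", parts[2])
      cfg[[key]] <- val
    }
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$bin_width <= 0) stop("config validation error: bin_width must be > 0")
  if (cfg$ripple_low >= cfg$ripple_high) {
    stop("config validation error: ripple band low must be < high")
  }
  if (cfg$min_duration >= cfg$max_duration) {
    stop("config validation error: min_duration must be < max_duration")
  }
  for (k in c("baseline_sd", "peak_sd", "activation_sd_multiplier", "merge_gap")) {
    if (cfg[[k]] <= 0) stop("config validation error: ", k, " must be > 0")
  }
  if (cfg$align_max_shift < 1) stop("config validation error: align_max_shift must be >= 1")
  cfg$ripple_band <- c(cfg$ripple_low, cfg$ripple_high)
  cfg$event_duration_bounds <- c(cfg$min_duration, cfg$max_duration)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$ica_restarts <- as.integer(cfg$ica_restarts)
  cfg$align_max_shift <- as.integer(cfg$align_max_shift)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to a flat key-value file
#' @param cfg run_config (or plain list of flat keys)
#' @param path output path
#' @export
write_config <- function(cfg, path) {
  keys <- names(run_config_defaults())
  lines <- vapply(keys, function(k) paste(k, format(cfg[[k]], digits = 15)), "")
  writeLines(lines, path)
  invisible(path)
}
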