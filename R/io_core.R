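SPIKE_TABLE_COLS <- c("spike_time_s", "unit_id", "contact_id", "area")
MANIFEST_COLS <- c("session_id", "day_stamp", "duration_s", "spike_table", "lfp")

#' Read a spike table
#'
#' Spike tables are tab-separated UTF-8 text with a header row and columns
#' `spike_time_s` (seconds from session start), `unit_id`, `contact_id`
#' (non-negative integers) and `area` (brain-area label, e.g. dHPC, PrL).
#' Rows are returned sorted by unit then time.
#'
#' @param path path to a TSV file.
#' @return a `spike_table`: a `data.frame` with the four columns above.
#' @export
read_spike_table <- function(path) {
  if (!file.exists(path)) stop("spike table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(SPIKE_TABLE_COLS, names(df))
  if (length(missing) > 0) {
    stop("spike table format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  df <- df[SPIKE_TABLE_COLS]
  as_spike_table(df)
}

#' Construct / validate a spike table
#'
#' @param df data.frame with columns `spike_time_s`, `unit_id`, `contact_id`, `area`.
#' @return validated `spike_table`, sorted by unit then time.
#' @export
as_spike_table <- function(df) {
  missing <- setdiff(SPIKE_TABLE_COLS, names(df))
  if (length(missing) > 0) {
    stop("spike table format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  df <- df[SPIKE_TABLE_COLS]
  df$spike_time_s <- as.numeric(df$spike_time_s)
  df$unit_id <- as.integer(df$unit_id)
  df$contact_id <- as.integer(df$contact_id)
  df$area <- as.character(df$area)
  if (nrow(df) > 0) {
    if (any(!is.finite(df$spike_time_s)) || any(df$spike_time_s < 0)) {
      stop("spike table validation error: spike_time_s must be finite and >= 0")
    }
    if (any(df$unit_id < 0) || any(df$contact_id < 0)) {
      stop("spike table validation error: unit_id and contact_id must be non-negative")
    }
    ## one area label per unit
    amap <- tapply(df$area, df$unit_id, function(a) length(unique(a)))
    if (any(amap > 1)) {
      stop("spike table validation error: unit(s) with multiple area labels: ",
           paste(names(amap)[amap > 1], collapse = ", "))
    }
    df <- df[order(df$unit_id, df$spike_time_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("spike_table", "data.frame")
  df
}

#' Write a spike table to TSV
#' @param x spike_table
#' @param path output path
#' @export
write_spike_table <- function(x, path) {
  x <- as_spike_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a session manifest
#'
#' TSV with columns `session_id`, `day_stamp` (integer calendar day relative
#' to the first session), `duration_s`, `spike_table` (path) and `lfp`
#' (path, may be empty). Day stamps must be strictly increasing.
#'
#' @param path manifest TSV path
#' @return `session_manifest` data.frame
#' @export
read_session_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing) > 0) {
    stop("manifest format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  as_session_manifest(df[MANIFEST_COLS])
}

#' @rdname read_session_manifest
#' @param df data.frame with the manifest columns
#' @export
as_session_manifest <- function(df) {
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing) > 0) {
    stop("manifest format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  df <- df[MANIFEST_COLS]
  df$session_id <- as.character(df$session_id)
  df$day_stamp <- as.integer(df$day_stamp)
  df$duration_s <- as.numeric(df$duration_s)
  df$spike_table <- as.character(df$spike_table)
  df$lfp <- as.character(df$lfp)
  if (nrow(df) > 1 && any(diff(df$day_stamp) <= 0)) {
    stop("manifest validation error: day_stamp must be strictly increasing")
  }
  if (any(df$duration_s <= 0)) {
    stop("manifest validation error: duration_s must be > 0")
  }
  rownames(df) <- NULL
  class(df) <- c("session_manifest", "data.frame")
  df
}

#' @rdname read_session_manifest
#' @param x session_manifest
#' @export
write_session_manifest <- function(x, path) {
  x <- as_session_manifest(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read multi-channel LFP from a flat binary with a JSON sidecar header
#'
#' The binary holds little-endian signed 16-bit integers, channel-interleaved
#' (all channels of sample 1, then all channels of sample 2, ...). The JSON
#' sidecar declares `n_channels`, `fs_hz`, `uv_per_bit` and `channel_labels`.
#' Voltages are returned in microvolts (`raw * uv_per_bit`).
#'
#' @param data_path path to the flat int16 binary
#' @param header_path path to the JSON sidecar (default `<data_path>.json`)
#' @return an `lfp_record`: list with `samples` (channels x time matrix, uV),
#'   `fs` (Hz), `channel_labels`, `uv_per_bit`.
#' @export
read_lfp <- function(data_path, header_path = paste0(data_path, ".json")) {
  if (!file.exists(data_path)) stop("LFP binary not found: ", data_path)
  if (!file.exists(header_path)) stop("LFP header not found: ", header_path)
  hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  need <- c("n_channels", "fs_hz", "uv_per_bit", "channel_labels")
  missing <- setdiff(need, names(hdr))
  if (length(missing) > 0) stop("LFP header missing field(s): ", paste(missing, collapse = ", "))
  nch <- as.integer(hdr$n_channels)
  if (length(hdr$channel_labels) != nch) {
    stop("LFP header error: channel_labels length != n_channels")
  }
  nbytes <- file.size(data_path)
  if (nbytes %% (2L * nch) != 0) {
    stop("LFP truncation error: file length ", nbytes,
         " bytes is not divisible by 2 x n_channels (", nch, ")")
  }
  nsamp <- nbytes %/% (2L * nch)
  raw <- readBin(data_path, what = "integer", n = nch * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  samples <- matrix(as.numeric(raw) * hdr$uv_per_bit, nrow = nch)
  rownames(samples) <- hdr$channel_labels
  new_lfp_record(samples, hdr$fs_hz, hdr$channel_labels, hdr$uv_per_bit)
}

new_lfp_record <- function(samples, fs, channel_labels, uv_per_bit = 1) {
  if (fs <= 0) stop("LFP validation error: fs must be > 0")
  if (any(!is.finite(samples))) stop("LFP validation error: non-finite samples")
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 uv_per_bit = uv_per_bit),
            class = "lfp_record")
}

#' Write an LFP record as flat int16 binary + JSON sidecar
#'
#' Voltages are quantized as `round(samples / uv_per_bit)`; values outside
#' the int16 range are an error (choose a coarser `uv_per_bit`).
#'
#' @param lfp `lfp_record`
#' @param data_path output binary path; sidecar goes to `<data_path>.json`
#' @export
write_lfp <- function(lfp, data_path) {
  raw <- round(lfp$samples / lfp$uv_per_bit)
  if (any(abs(raw) > 32767)) {
    stop("LFP write error: values exceed int16 range at uv_per_bit = ", lfp$uv_per_bit)
  }
  ## column-major write of a channels x time matrix yields channel interleaving
  writeBin(as.integer(raw), data_path, size = 2L, endian = "little")
  hdr <- list(n_channels = nrow(lfp$samples), fs_hz = lfp$fs,
              uv_per_bit = lfp$uv_per_bit, channel_labels = lfp$channel_labels)
  jsonlite::write_json(hdr, paste0(data_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(data_path)
}

#' @export
print.lfp_record <- function(x, ...) {
  cat(sprintf("<lfp_record> %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

#' Write / read SWR events as BED-like TSV
#'
#' Columns: `start_s`, `end_s`, `peak_s`, `aligned_center_s`.
#' @param events data.frame of SWR events
#' @param path output TSV path
#' @export
write_swr_events <- function(events, path) {
  out <- data.frame(start_s = events$start, end_s = events$end,
                    peak_s = events$peak, aligned_center_s = events$aligned_center)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_swr_events
#' @export
read_swr_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(start = df$start_s, end = df$end_s, peak = df$peak_s,
             aligned_center = df$aligned_center_s)
}

#' Write detected ensembles to JSON
#'
#' One record per ensemble: `ensemble_id`, `weights`, `otsu_threshold`,
#' `members` (unit ids), `unit_ids`, `areas`.
#'
#' @param patterns list of `ensemble_pattern`
#' @param activity the `binned_activity` the patterns were extracted from
#' @param path output JSON path
#' @export
write_ensembles_json <- function(patterns, activity, path) {
  recs <- lapply(patterns, function(p) {
    list(ensemble_id = p$ensemble_id,
         weights = p$weights,
         otsu_threshold = p$otsu_threshold,
         members = activity$unit_ids[p$member_mask],
         unit_ids = activity$unit_ids,
         areas = activity$areas)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
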