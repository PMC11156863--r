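## Spike-sorting quality and cross-session single-unit tracking metrics:
## SNR, ISI-violation percentage, nearest-neighbor Mahalanobis distance,
## per-contact PCA features, waveform Pearson correlation, standardized
## mean difference (SMD), and the same / different / neighboring-different
## pair-category analysis.

#' Unit signal-to-noise ratio
#'
#' Peak |amplitude| of the mean waveform at the unit's center contact
#' (the contact with the largest absolute amplitude), divided by the RMS
#' of the band-passed signal at that contact.
#'
#' @param mean_waveform contacts x samples matrix (uV).
#' @param rms_noise_per_contact per-contact RMS noise (uV); a scalar is
#'   recycled.
#' @return SNR (dimensionless).
#' @export
unit_snr <- function(mean_waveform, rms_noise_per_contact) {
  if (all(mean_waveform == 0)) stop("SNR undefined: all-zero waveform")
  rms <- rep_len(rms_noise_per_contact, nrow(mean_waveform))
  cc <- center_contact(mean_waveform) + 1L
  if (rms[cc] <= 0) stop("SNR undefined: non-positive RMS at the center contact")
  max(abs(mean_waveform[cc, ])) / rms[cc]
}

#' Percentage of inter-spike-interval violations
#'
#' Fraction (in percent) of consecutive inter-spike intervals shorter
#' than `threshold` (default 2 ms). Units above `flag_above` (default 2%)
#' are flagged as contaminated.
#'
#' @param spike_times sorted ascending spike times (s).
#' @param threshold refractory bound (s).
#' @param flag_above contamination flag level (percent).
#' @return list with `percent` (`NA` for < 2 spikes), `n_violations`,
#'   `n_intervals`, `flagged`.
#' @export
isi_violation_rate <- function(spike_times, threshold = 0.002, flag_above = 2) {
  if (length(spike_times) < 2) {
    return(list(percent = NA_real_, n_violations = NA_integer_,
                n_intervals = 0L, flagged = NA))
  }
  if (is.unsorted(spike_times)) stop("spike_times must be sorted ascending")
  isi <- diff(spike_times)
  nv <- sum(isi < threshold)
  pct <- 100 * nv / length(isi)
  list(percent = pct, n_violations = nv, n_intervals = length(isi),
       flagged = pct > flag_above)
}

#' Per-contact PCA reduction of spike waveforms
#'
#' For each recording contact, PCA is fitted on that contact's spike
#' snippets and the top 3 scores are kept, reducing each spike from
#' (contacts x samples) to (contacts x 3). Features are concatenated
#' across contacts in contact order.
#'
#' @param spike_waveforms spikes x (contacts * samples) matrix, columns
#'   in column-major contact-fastest order (contact varies within a
#'   sample), as produced by flattening a contacts x samples array.
#' @param n_contacts,n_samples waveform geometry.
#' @param contact_span optional contact indices covered (defaults to all).
#' @param rotation optional list of per-contact PCA rotations (centers +
#'   loadings) from a previous fit, so several clusters can share one
#'   feature basis.
#' @return a `cluster_features`: list with `features` (spikes x
#'   3*n_contacts), `contact_span`, `rotation`.
#' @export
pca_features <- function(spike_waveforms, n_contacts, n_samples,
                         contact_span = seq_len(n_contacts), rotation = NULL) {
  n_spk <- nrow(spike_waveforms)
  if (is.null(rotation) && n_spk < 4) stop("pca_features needs >= 4 spikes")
  stopifnot(ncol(spike_waveforms) == n_contacts * n_samples)
  feats <- matrix(0, n_spk, 3L * length(contact_span))
  rot_out <- vector("list", length(contact_span))
  for (i in seq_along(contact_span)) {
    ct <- contact_span[i]
    ## columns of contact ct across samples (contacts x samples, column-major)
    cols <- ct + (seq_len(n_samples) - 1L) * n_contacts
    Xc <- spike_waveforms[, cols, drop = FALSE]
    if (is.null(rotation)) {
      pc <- stats::prcomp(Xc, center = TRUE, scale. = FALSE, rank. = 3L)
      rot <- list(center = pc$center, loadings = pc$rotation)
    } else {
      rot <- rotation[[i]]
    }
    sc <- sweep(Xc, 2, rot$center) %*% rot$loadings
    if (ncol(sc) < 3L) sc <- cbind(sc, matrix(0, n_spk, 3L - ncol(sc)))
    feats[, 3L * (i - 1L) + 1:3] <- sc[, 1:3]
    rot_out[[i]] <- rot
  }
  structure(list(features = feats, contact_span = contact_span,
                 rotation = rot_out),
            class = "cluster_features")
}

#' Nearest-neighbor Mahalanobis distance between clusters
#'
#' Mahalanobis distance from the target cluster's center to each
#' neighboring cluster (those whose center contact lies within
#' `neighborhood` contacts of the target's), using the neighbor cloud's
#' covariance with a small ridge (1e-6 x mean diagonal), minimized over
#' neighbors.
#'
#' @param target `cluster_features` of the unit of interest.
#' @param others list of `cluster_features` for candidate neighbors.
#' @param target_center,other_centers 0-based center contacts.
#' @param neighborhood contact radius (default 3).
#' @return list with `distance` (`NA` if no neighbor in span) and
#'   `nearest` (index into `others`).
#' @export
nearest_neighbor_distance <- function(target, others, target_center,
                                      other_centers, neighborhood = 3L) {
  stopifnot(length(others) == length(other_centers))
  near <- which(abs(other_centers - target_center) <= neighborhood)
  if (length(near) == 0) return(list(distance = NA_real_, nearest = NA_integer_))
  mu_t <- colMeans(target$features)
  d <- vapply(near, function(i) {
    F <- others[[i]]$features
    S <- stats::cov(F)
    ridge <- 1e-6 * mean(diag(S))
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-12
    S <- S + diag(ridge, ncol(S))
    sqrt(stats::mahalanobis(mu_t, colMeans(F), S))
  }, 0)
  list(distance = min(d), nearest = near[which.min(d)])
}

#' Pearson correlation between two mean waveforms
#'
#' `R = C_ij / sqrt(C_ii * C_jj)` on the waveforms flattened over
#' contacts x samples (row-major by contact).
#'
#' @param wf_i,wf_j contacts x samples matrices of equal shape.
#' @return correlation in `[-1, 1]`; `NA` for zero-variance input.
#' @export
waveform_pearson <- function(wf_i, wf_j) {
  stopifnot(all(dim(wf_i) == dim(wf_j)))
  x <- as.numeric(t(wf_i))   # row-major by contact
  y <- as.numeric(t(wf_j))
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cov(x, y) / sqrt(stats::var(x) * stats::var(y))
}

#' Standardized mean difference between two feature clusters
#'
#' `SMD = sqrt( sum_d ((m_k,d - m_l,d) / (2 * sqrt(sigma_k,d +
#' sigma_l,d)))^2 )` with per-dimension means `m` and variances `sigma`
#' across the spikes of each cluster.
#'
#' @param cluster_k,cluster_l `cluster_features` (or plain spikes x D
#'   matrices) with matching D.
#' @return SMD (>= 0).
#' @export
smd <- function(cluster_k, cluster_l) {
  Fk <- if (inherits(cluster_k, "cluster_features")) cluster_k$features else cluster_k
  Fl <- if (inherits(cluster_l, "cluster_features")) cluster_l$features else cluster_l
  stopifnot(ncol(Fk) == ncol(Fl))
  mk <- colMeans(Fk); ml <- colMeans(Fl)
  vk <- apply(Fk, 2, stats::var); vl <- apply(Fl, 2, stats::var)
  denom <- vk + vl
  dm <- mk - ml
  ## identical degenerate dimensions contribute 0; a mean difference with no
  ## spread is genuinely degenerate
  if (any(denom == 0 & dm != 0)) {
    stop("degenerate-variance error: sigma_k + sigma_l = 0 in a dimension with nonzero mean difference")
  }
  terms <- ifelse(denom == 0, 0, (dm / (2 * sqrt(denom)))^2)
  sqrt(sum(terms))
}

#' Pair-category tracking analysis
#'
#' Enumerates all pairs of (unit, time-block) clusters into three
#' disjoint categories — `same_unit` (same unit, different blocks),
#' `neighboring_different_unit` (different units whose center contacts
#' lie within `neighborhood` contacts) and `different_unit` (remaining
#' different-unit pairs) — and computes the waveform Pearson correlation
#' and the SMD for each pair. PCA features are fitted once per contact on
#' the pooled spikes of all clusters so all clusters share one feature
#' basis. Per-category medians/IQRs and Wilcoxon rank-sum comparisons
#' (same vs different, same vs neighboring-different) are reported.
#'
#' @param blocks list of `waveform_block` (with `spikes` matrices), e.g.
#'   from [simulate_waveform_blocks()].
#' @param neighborhood contact radius for the neighboring category.
#' @return list with `pairs` (data.frame: unit_a, block_a, unit_b,
#'   block_b, category, pearson_r, smd), `summary` (per-category median
#'   and IQR of both metrics, with n), and `tests` (rank-sum p-values).
#' @export
pair_category_analysis <- function(blocks, neighborhood = 3L) {
  stopifnot(length(blocks) >= 2)
  units <- vapply(blocks, function(b) b$unit_id, 0L)
  if (length(unique(units)) < 2) stop("pair analysis needs >= 2 units")
  nc <- nrow(blocks[[1]]$mean_waveform)
  ns <- ncol(blocks[[1]]$mean_waveform)
  ## shared per-contact PCA basis from the pooled spikes
  pooled <- do.call(rbind, lapply(blocks, function(b) b$spikes))
  basis <- pca_features(pooled, nc, ns)
  feats <- lapply(blocks, function(b) {
    pca_features(b$spikes, nc, ns, rotation = basis$rotation)
  })
  centers <- vapply(blocks, function(b) b$center_contact, 0L)
  idx <- utils::combn(length(blocks), 2)
  n_pairs <- ncol(idx)
  cat_v <- character(n_pairs); r_v <- numeric(n_pairs); smd_v <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    a <- idx[1, p]; b <- idx[2, p]
    if (units[a] == units[b]) {
      cat_v[p] <- "same_unit"
    } else if (abs(centers[a] - centers[b]) <= neighborhood) {
      cat_v[p] <- "neighboring_different_unit"
    } else {
      cat_v[p] <- "different_unit"
    }
    r_v[p] <- waveform_pearson(blocks[[a]]$mean_waveform, blocks[[b]]$mean_waveform)
    smd_v[p] <- smd(feats[[a]], feats[[b]])
  }
  pairs <- data.frame(
    unit_a = units[idx[1, ]], block_a = vapply(blocks[idx[1, ]], function(b) b$block_id, 0L),
    unit_b = units[idx[2, ]], block_b = vapply(blocks[idx[2, ]], function(b) b$block_id, 0L),
    category = cat_v, pearson_r = r_v, smd = smd_v)
  summ <- do.call(rbind, lapply(split(pairs, pairs$category), function(g) {
    data.frame(category = g$category[1], n = nrow(g),
               median_r = stats::median(g$pearson_r, na.rm = TRUE),
               iqr_r = stats::IQR(g$pearson_r, na.rm = TRUE),
               median_smd = stats::median(g$smd),
               iqr_smd = stats::IQR(g$smd))
  }))
  rownames(summ) <- NULL
  same <- pairs[pairs$category == "same_unit", ]
  diff_all <- pairs[pairs$category != "same_unit", ]
  neigh <- pairs[pairs$category == "neighboring_different_unit", ]
  ranksum <- function(x, y, metric) {
    if (nrow(x) == 0 || nrow(y) == 0) return(NA_real_)
    stats::wilcox.test(x[[metric]], y[[metric]])$p.value
  }
  tests <- list(
    r_same_vs_different = ranksum(same, diff_all, "pearson_r"),
    r_same_vs_neighboring = ranksum(same, neigh, "pearson_r"),
    smd_same_vs_different = ranksum(same, diff_all, "smd"),
    smd_same_vs_neighboring = ranksum(same, neigh, "smd"))
  list(pairs = pairs, summary = summ, tests = tests)
}

#' Write tracking pair metrics as TSV
#' @param result output of [pair_category_analysis()]
#' @param path output TSV path
#' @export
write_pair_metrics <- function(result, path) {
  utils::write.table(result$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
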