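## Ensemble (cell-assembly) detection from binned, z-scored spike counts.
##
## Pipeline: spike counts in 25 ms bins -> per-neuron z-scoring over the
## concatenated sessions -> correlation matrix C = Z Z^T / N -> eigenvalues
## against the Marcenko-Pastur upper edge -> fastICA on the significant
## subspace -> unit-norm weight patterns -> Otsu threshold on |weights|
## to call members.

#' Bin spike trains and z-score per neuron
#'
#' Spikes are counted in half-open bins `[k*dt, (k+1)*dt)` from each
#' session start; sessions are concatenated along the bin axis and each
#' neuron's counts are z-scored with the mean and (population) s.d. over
#' the concatenation, so every row of `Z` has mean 0 and variance 1.
#' Neurons with zero count variance (silent or perfectly constant) are
#' dropped with a warning naming them.
#'
#' @param spike_tables a `spike_table` or list of them (one per session).
#' @param bin_width bin width in seconds (default 0.025).
#' @param durations per-session durations (s); defaults to the last spike
#'   time rounded up to a whole bin.
#' @return a `binned_activity`: list with `Z` (neurons x bins), `n_bins`,
#'   `bin_width`, `unit_ids`, `areas`, `session_slices` (list of
#'   first/last bin index per session), `counts` (raw count matrix) and
#'   `dropped_units`.
#' @export
bin_and_zscore <- function(spike_tables, bin_width = 0.025, durations = NULL) {
  if (inherits(spike_tables, "spike_table")) spike_tables <- list(spike_tables)
  stopifnot(length(spike_tables) >= 1, bin_width > 0)
  if (is.null(durations)) {
    durations <- vapply(spike_tables, function(st) {
      if (nrow(st) == 0) bin_width else max(st$spike_time_s) + bin_width / 2
    }, 0)
  }
  stopifnot(length(durations) == length(spike_tables))
  n_bins_per <- pmax(1L, as.integer(ceiling(durations / bin_width)))

  ## unit universe: union over sessions, with area lookup
  all_units <- sort(unique(unlist(lapply(spike_tables, function(st) st$unit_id))))
  if (length(all_units) == 0) stop("empty-activity error: no spikes in any session")
  area_of <- character(length(all_units)); names(area_of) <- as.character(all_units)
  for (st in spike_tables) {
    if (nrow(st) == 0) next
    first <- !duplicated(st$unit_id)
    area_of[as.character(st$unit_id[first])] <- st$area[first]
  }

  total_bins <- sum(n_bins_per)
  counts <- matrix(0L, length(all_units), total_bins)
  offset <- 0L
  session_slices <- vector("list", length(spike_tables))
  for (s in seq_along(spike_tables)) {
    st <- spike_tables[[s]]
    nb <- n_bins_per[s]
    session_slices[[s]] <- c(first = offset + 1L, last = offset + nb)
    if (nrow(st) > 0) {
      b <- floor(st$spike_time_s / bin_width) + 1L
      keep <- b >= 1L & b <= nb
      r <- match(st$unit_id[keep], all_units)
      tab <- table(factor(r, levels = seq_along(all_units)),
                   factor(b[keep], levels = seq_len(nb)))
      counts[, offset + seq_len(nb)] <- counts[, offset + seq_len(nb)] +
        matrix(as.integer(tab), length(all_units), nb)
    }
    offset <- offset + nb
  }

  mu <- rowMeans(counts)
  sdev <- sqrt(rowMeans(counts^2) - mu^2)   # population s.d. so diag(C) = 1
  zero_var <- sdev <= 0
  if (all(zero_var)) stop("empty-activity error: all neurons have zero count variance")
  dropped <- all_units[zero_var]
  if (length(dropped) > 0) {
    warning("dropping zero-variance unit(s): ", paste(dropped, collapse = ", "))
  }
  keep <- !zero_var
  Z <- (counts[keep, , drop = FALSE] - mu[keep]) / sdev[keep]

  structure(list(Z = Z, n_bins = total_bins, bin_width = bin_width,
                 unit_ids = all_units[keep],
                 areas = unname(area_of[as.character(all_units[keep])]),
                 session_slices = session_slices,
                 counts = counts[keep, , drop = FALSE],
                 dropped_units = dropped),
            class = "binned_activity")
}

#' Correlation matrix and eigenspectrum of binned activity
#'
#' Computes `C = Z %*% t(Z) / N` (N = number of bins) and its full
#' symmetric eigendecomposition, eigenvalues sorted descending, together
#' with the Marcenko-Pastur significance bound for the matrix aspect
#' ratio.
#'
#' @param activity a `binned_activity`.
#' @return a `correlation_spectrum`: list with `C`, `eigenvalues`,
#'   `eigenvectors` (columns), `mp_threshold`, `n_neurons`, `n_bins`.
#' @export
correlation_matrix <- function(activity) {
  Z <- activity$Z
  if (any(!is.finite(Z))) stop("validation error: non-finite entries in Z")
  n <- nrow(Z); N <- ncol(Z)
  if (N <= n) {
    warning("fewer bins (", N, ") than neurons (", n,
            "); correlation spectrum will be rank deficient")
  }
  C <- tcrossprod(Z) / N
  eig <- eigen(C, symmetric = TRUE)
  structure(list(C = C, eigenvalues = eig$values, eigenvectors = eig$vectors,
                 mp_threshold = marcenko_pastur_threshold(n, N),
                 n_neurons = n, n_bins = N),
            class = "correlation_spectrum")
}

#' Marcenko-Pastur upper eigenvalue bound
#'
#' Upper edge `(1 + sqrt(q))^2` of the Marcenko-Pastur distribution for a
#' random correlation matrix with aspect ratio `q = n_neurons / n_bins`.
#' Eigenvalues above this edge indicate non-random co-activation
#' structure.
#'
#' @param n_neurons,n_bins matrix dimensions.
#' @return the threshold (a scalar; tends to 1 as q tends to 0).
#' @export
marcenko_pastur_threshold <- function(n_neurons, n_bins) {
  if (n_neurons <= 0) stop("n_neurons must be > 0")
  if (n_bins <= 0) stop("n_bins must be > 0")
  (1 + sqrt(n_neurons / n_bins))^2
}

#' Number of significant ensembles
#'
#' Counts eigenvalues strictly above the Marcenko-Pastur bound.
#'
#' @param spectrum a `correlation_spectrum`.
#' @return integer count.
#' @export
count_significant <- function(spectrum) {
  sum(spectrum$eigenvalues > spectrum$mp_threshold)
}

## ---- fastICA (deflation, logcosh contrast) --------------------------------
## X must be whitened (k x N, identity covariance). Returns the orthogonal
## unmixing matrix W (k x k, rows are components). Deflation with
## Gram-Schmidt decorrelation; logcosh nonlinearity g(u) = tanh(u).
fast_ica_deflation <- function(X, tol = 1e-6, max_iter = 1000L,
                               inner_restarts = 5L, seed = 1L) {
  k <- nrow(X); N <- ncol(X)
  W <- matrix(0, k, k)
  set.seed(seed)
  for (comp in seq_len(k)) {
    converged <- FALSE
    for (r in seq_len(max(1L, inner_restarts))) {
      w <- stats::rnorm(k)
      if (comp > 1) {
        prev <- W[seq_len(comp - 1), , drop = FALSE]
        w <- w - as.vector(crossprod(prev, prev %*% w))
      }
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        u <- as.vector(w %*% X)
        g <- tanh(u)
        gprime <- 1 - g^2
        w_new <- as.vector(X %*% g) / N - mean(gprime) * w
        if (comp > 1) {
          prev <- W[seq_len(comp - 1), , drop = FALSE]
          w_new <- w_new - as.vector(crossprod(prev, prev %*% w_new))
        }
        nrm <- sqrt(sum(w_new^2))
        if (nrm < .Machine$double.eps^0.5) break   # collapsed; restart
        w_new <- w_new / nrm
        if (abs(abs(sum(w_new * w)) - 1) < tol) {
          w <- w_new; converged <- TRUE; break
        }
        w <- w_new
      }
      if (converged) break
    }
    if (!converged) {
      stop("ICA convergence error: component ", comp, " did not converge ",
           "within ", max_iter, " iterations at tolerance ", tol,
           " after ", inner_restarts, " restart(s)")
    }
    W[comp, ] <- w
  }
  W
}

## Negentropy surrogate of one source, J(s) ~ (E[log cosh s] - E[log cosh nu])^2
## with nu standard normal (E[log cosh nu] = 0.3745...). Deflation can stall in
## mixed fixed points; restarting the whole decomposition and keeping the run
## with maximal total negentropy picks the best-separated solution.
LOGCOSH_GAUSS <- 0.37456697
negentropy_sum <- function(W, X) {
  S <- W %*% X
  sum((rowMeans(log(cosh(S))) - LOGCOSH_GAUSS)^2)
}

#' Extract ensemble weight patterns by PCA projection + fastICA
#'
#' Projects the z-scored activity onto the top-`k` eigenvectors of the
#' correlation matrix, whitens the projected data, and runs deflation-mode
#' fastICA (logcosh contrast, tolerance 1e-6, up to 1000 iterations).
#' The whole decomposition is repeated from `ica_restarts` starting seeds
#' and the run with the largest total negentropy is kept, which avoids
#' the mixed fixed points deflation can stall in; within a run, each
#' component also re-seeds on non-convergence. The independent-component
#' loadings are back-projected to neuron space, scaled to unit norm, and
#' sign-fixed so each pattern's largest-|weight| element is positive.
#' Patterns are returned sorted by descending largest |weight|, with
#' membership called by [otsu_members()].
#'
#' @param activity a `binned_activity`.
#' @param k number of significant components (e.g. from
#'   [count_significant()]); `1 <= k <= n_neurons`.
#' @param seed seed for the ICA restarts.
#' @param ica_restarts independent decomposition runs compared by
#'   negentropy (each also re-seeds components on non-convergence).
#' @param tol,max_iter fastICA stopping rule.
#' @return list of `ensemble_pattern`: each has unit-norm `weights`,
#'   `otsu_threshold` on |weights|, logical `member_mask` and
#'   `ensemble_id` (1-based rank).
#' @export
extract_patterns <- function(activity, k, seed = 1L, ica_restarts = 5L,
                             tol = 1e-6, max_iter = 1000L) {
  Z <- activity$Z
  n <- nrow(Z); N <- ncol(Z)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n_neurons")
  C <- tcrossprod(Z) / N
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors[, seq_len(k), drop = FALSE]       # n x k
  lam <- eig$values[seq_len(k)]
  if (any(lam <= 0)) stop("degenerate spectrum: non-positive leading eigenvalue")
  Y <- crossprod(V, Z)                               # k x N, row var = lam
  X <- Y / sqrt(lam)                                 # whitened
  if (k == 1L) {
    W <- matrix(1, 1, 1)
  } else {
    best <- -Inf; W <- NULL
    for (r in seq_len(max(1L, ica_restarts))) {
      Wr <- fast_ica_deflation(X, tol = tol, max_iter = max_iter,
                               inner_restarts = ica_restarts,
                               seed = seed + 1009L * (r - 1L))
      J <- negentropy_sum(Wr, X)
      if (J > best) { best <- J; W <- Wr }
    }
  }
  ## neuron-space loadings: Z ~ V diag(sqrt(lam)) t(W) S
  load <- V %*% (sqrt(lam) * t(W))                   # n x k
  patterns <- lapply(seq_len(k), function(j) {
    w <- load[, j]
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    w
  })
  ord <- order(vapply(patterns, function(w) max(abs(w)), 0), decreasing = TRUE)
  patterns <- patterns[ord]
  lapply(seq_along(patterns), function(j) {
    w <- patterns[[j]]
    ot <- otsu_members(w)
    structure(list(weights = w, otsu_threshold = ot$threshold,
                   member_mask = ot$member_mask, ensemble_id = j),
              class = "ensemble_pattern")
  })
}

#' Otsu membership threshold on absolute weights
#'
#' Splits the absolute weights into two classes at the threshold that
#' maximizes the between-class variance, evaluated over a 256-level grid
#' of candidate thresholds spanning `[0, max(|w|)]` with class statistics
#' taken from the raw values. Neurons in the high-|weight| class are
#' members. When several candidate thresholds tie (a plateau between two
#' well-separated classes), the plateau midpoint is returned, so with two
#' distinct values the threshold falls strictly between them.
#'
#' @param weights numeric weight vector (absolute values are taken).
#' @return list with `threshold` and logical `member_mask`
#'   (`|weights| > threshold`; always at least one member).
#' @export
otsu_members <- function(weights) {
  a <- abs(weights)
  if (length(unique(a)) < 2) {
    stop("degenerate-input error: Otsu threshold needs >= 2 distinct |weight| values")
  }
  edges <- seq(0, max(a), length.out = 257)
  candidates <- edges[2:256]
  n <- length(a)
  vb <- vapply(candidates, function(t) {
    lo <- a <= t
    n0 <- sum(lo)
    if (n0 == 0L || n0 == n) return(-Inf)
    p0 <- n0 / n
    p0 * (1 - p0) * (mean(a[lo]) - mean(a[!lo]))^2
  }, 0)
  top <- which(vb >= max(vb) * (1 - 1e-9))
  best_t <- (candidates[min(top)] + candidates[max(top)]) / 2
  list(threshold = best_t, member_mask = a > best_t)
}
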