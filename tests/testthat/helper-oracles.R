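# Independent brute-force oracles. These deliberately use explicit loops
# and no linear-algebra shortcuts so they stay independent of the
# implementation paths they check.

# Zero-diagonal quadratic form sum_{i != j} w_i w_j z_i z_j, explicit loops.
oracle_activation <- function(w, z) {
  w <- w / sqrt(sum(w^2))
  m <- length(w)
  acc <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) acc <- acc + w[i] * w[j] * z[i] * z[j]
    }
  }
  acc
}

# Otsu: exhaustive between-class variance maximization over the same
# 256-level candidate grid, explicit loops over the raw values.
oracle_otsu <- function(weights) {
  a <- abs(weights)
  edges <- seq(0, max(a), length.out = 257)
  candidates <- edges[2:256]
  vb <- rep(-Inf, length(candidates))
  for (k in seq_along(candidates)) {
    t <- candidates[k]
    s0 <- 0; n0 <- 0; s1 <- 0; n1 <- 0
    for (v in a) {
      if (v <= t) { s0 <- s0 + v; n0 <- n0 + 1 } else { s1 <- s1 + v; n1 <- n1 + 1 }
    }
    if (n0 == 0 || n1 == 0) next
    p0 <- n0 / length(a); p1 <- n1 / length(a)
    vb[k] <- p0 * p1 * (s0 / n0 - s1 / n1)^2
  }
  top <- which(vb >= max(vb) * (1 - 1e-9))
  (candidates[min(top)] + candidates[max(top)]) / 2
}

# Pearson correlation via explicit sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  cxy <- 0; cxx <- 0; cyy <- 0
  for (i in seq_len(n)) {
    cxy <- cxy + (x[i] - mx) * (y[i] - my)
    cxx <- cxx + (x[i] - mx)^2
    cyy <- cyy + (y[i] - my)^2
  }
  cxy / sqrt(cxx * cyy)
}

# SMD via explicit per-dimension loops (sample variances).
oracle_smd <- function(Fk, Fl) {
  D <- ncol(Fk)
  acc <- 0
  for (d in seq_len(D)) {
    xk <- Fk[, d]; xl <- Fl[, d]
    mk <- sum(xk) / length(xk); ml <- sum(xl) / length(xl)
    vk <- sum((xk - mk)^2) / (length(xk) - 1)
    vl <- sum((xl - ml)^2) / (length(xl) - 1)
    acc <- acc + ((mk - ml) / (2 * sqrt(vk + vl)))^2
  }
  sqrt(acc)
}

# Small planted-ensemble simulation used by several tests.
quick_sim <- function(seed, n_units = 60, n_ensembles = 3, duration = 1200,
                      event_rate = 0.1, p_participate = 0.8, ...) {
  cfg <- sim_config(n_units = n_units, n_ensembles = n_ensembles,
                    event_rate = event_rate, p_participate = p_participate,
                    sessions = data.frame(day_stamp = 0L, duration = duration),
                    rng_seed = seed, ...)
  list(cfg = cfg, sim = simulate_spike_trains(cfg))
}

# Best one-to-one Jaccard matching of detected member sets to truth.
member_jaccards <- function(patterns, activity, truth_members) {
  det <- lapply(patterns, function(p) activity$unit_ids[p$member_mask])
  vapply(truth_members, function(m) {
    max(vapply(det, function(d) {
      length(intersect(d, m)) / length(union(d, m))
    }, 0))
  }, 0)
}
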