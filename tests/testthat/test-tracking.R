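test_that("SNR is the peak amplitude over RMS noise at the center contact", {
  wf <- matrix(0, 4, 10)
  wf[2, 5] <- -100  # center contact 2 (0-based: 1), peak 100 uV
  expect_equal(unit_snr(wf, 10), 10)
  # scale invariance
  expect_equal(unit_snr(wf * 3.7, 10 * 3.7), 10)
  # per-contact RMS vector uses the center contact's value
  expect_equal(unit_snr(wf, c(1, 20, 1, 1)), 5)
  expect_error(unit_snr(matrix(0, 2, 3), 1), "all-zero")
})

test_that("synthetic units built at a known SNR measure within 10%", {
  cfg <- sim_config(rng_seed = 83)
  out <- simulate_waveform_blocks(cfg, n_track_units = 4, n_blocks = 1,
                                  n_contacts = 16, peak_uv = 100, snr = 5,
                                  spikes_per_block = 1000)
  noise_sd <- out$ground_truth$noise_sd
  for (b in out$blocks) {
    # the mean of 1000 spikes suppresses noise; RMS of the raw noise is its s.d.
    expect_equal(unit_snr(b$mean_waveform, noise_sd), 5, tolerance = 0.1)
  }
})

test_that("ISI violation percentage matches hand counts and closed forms", {
  # intervals 1, 9, 1, 989 ms -> 2 of 4 below 2 ms -> 50%
  res <- isi_violation_rate(c(0, 0.001, 0.010, 0.011, 1.0))
  expect_equal(res$percent, 50)
  expect_true(res$flagged)
  # regular 10 Hz train: no violations
  expect_equal(isi_violation_rate(seq(0, 10, by = 0.1))$percent, 0)
  # Poisson train at 5 Hz: P(ISI < 2 ms) = 1 - exp(-0.01) ~ 1.0%
  pct <- vapply(1:10, function(seed) {
    set.seed(seed)
    isi_violation_rate(cumsum(rexp(3000, 5)))$percent
  }, 0)
  expect_equal(mean(pct), 100 * (1 - exp(-5 * 0.002)), tolerance = 0.1)
  # under 2 spikes: undefined sentinel
  expect_true(is.na(isi_violation_rate(c(0.5))$percent))
})

test_that("per-contact PCA keeps 3 ordered components per contact", {
  set.seed(91)
  nc <- 6; ns <- 20; nspk <- 50
  spikes <- matrix(rnorm(nspk * nc * ns), nspk)
  cf <- pca_features(spikes, nc, ns)
  expect_equal(ncol(cf$features), 3 * nc)
  # variance ordering within each contact triple
  v <- apply(cf$features, 2, var)
  for (ct in seq_len(nc)) {
    tri <- v[3 * (ct - 1) + 1:3]
    expect_true(all(diff(tri) <= 1e-12))
  }
  # identical spikes -> identical (all-zero-variance) feature rows
  same <- matrix(rep(rnorm(nc * ns), each = 8), 8)
  cf2 <- pca_features(same, nc, ns)
  expect_true(all(apply(cf2$features, 2, var) < 1e-20))
  expect_error(pca_features(spikes[1:3, ], nc, ns), ">= 4")
})

test_that("nearest-neighbor Mahalanobis distance behaves on constructed clusters", {
  set.seed(93)
  mk_cluster <- function(center, n = 400, d = 3) {
    structure(list(features = sweep(matrix(rnorm(n * d), n), 2, center, "+")),
              class = "cluster_features")
  }
  target <- mk_cluster(c(0, 0, 0))
  same <- mk_cluster(colMeans(target$features))
  # coincident centers -> distance ~ 0
  res0 <- nearest_neighbor_distance(target, list(same), 10L, 10L)
  expect_lt(res0$distance, 0.2)
  # unit-variance spherical neighbor 5 away in one dimension -> ~5
  far <- mk_cluster(c(5, 0, 0))
  res5 <- nearest_neighbor_distance(target, list(far), 10L, 11L)
  expect_equal(res5$distance, 5, tolerance = 0.4)
  # adding another cluster never decreases the minimum distance
  res_both <- nearest_neighbor_distance(target, list(far, mk_cluster(c(20, 0, 0))),
                                        10L, c(11L, 12L))
  expect_gte(res5$distance, res_both$distance - 1e-12)
  expect_equal(res_both$nearest, 1L)
  # nothing within +/-3 contacts -> sentinel
  none <- nearest_neighbor_distance(target, list(far), 10L, 20L)
  expect_true(is.na(none$distance))
})

test_that("waveform Pearson correlation follows its covariance definition", {
  set.seed(95)
  wf <- matrix(rnorm(8 * 30), 8)
  expect_equal(waveform_pearson(wf, 2 * wf + 5), 1)
  expect_equal(waveform_pearson(wf, -wf), -1)
  # matches the explicit-sum oracle on random pairs
  for (i in 1:100) {
    a <- matrix(rnorm(6 * 10), 6); b <- matrix(rnorm(6 * 10), 6)
    expect_equal(waveform_pearson(a, b),
                 oracle_pearson(as.numeric(t(a)), as.numeric(t(b))),
                 tolerance = 1e-10)
  }
  # independent 64 x 41 waveforms decorrelate
  r <- vapply(1:20, function(seed) {
    set.seed(seed)
    waveform_pearson(matrix(rnorm(64 * 41), 64), matrix(rnorm(64 * 41), 64))
  }, 0)
  expect_lt(max(abs(r)), 0.1)
  expect_true(is.na(waveform_pearson(matrix(1, 2, 2), wf[1:2, 1:2])))
})

test_that("SMD matches its formula, hand cases and the loop oracle", {
  set.seed(97)
  F1 <- matrix(rnorm(50 * 4), 50)
  expect_equal(smd(F1, F1), 0)
  # 1-D clusters: means 0 and 2, variances 0.5 each -> 2 / (2 * sqrt(1)) = 1
  xk <- scale(1:9)[, 1]; xk <- xk / sd(xk) * sqrt(0.5)        # mean 0, var 0.5
  xl <- xk + 2                                                # mean 2, var 0.5
  expect_equal(smd(matrix(xk, ncol = 1), matrix(xl, ncol = 1)), 1)
  # loop oracle on random instances
  for (i in 1:100) {
    d <- sample(2:6, 1)
    Fa <- matrix(rnorm(20 * d), 20); Fb <- matrix(rnorm(20 * d, 1), 20)
    expect_equal(smd(Fa, Fb), oracle_smd(Fa, Fb), tolerance = 1e-10)
  }
  # monotone in the mean shift along any dimension
  base <- smd(Fa, Fb)
  Fb2 <- Fb; Fb2[, 1] <- Fb2[, 1] + 3
  expect_gt(smd(Fa, Fb2), base)
  expect_error(smd(matrix(1, 5, 1), matrix(2, 5, 1)), "degenerate-variance")
})

test_that("pair categories partition all cross-block pairs with the right counts", {
  cfg <- sim_config(rng_seed = 99)
  out <- simulate_waveform_blocks(cfg, n_track_units = 4, n_blocks = 3,
                                  n_contacts = 16, spikes_per_block = 10)
  res <- pair_category_analysis(out$blocks)
  U <- 4; B <- 3
  total <- choose(U * B, 2)
  expect_equal(nrow(res$pairs), total)
  expect_equal(sum(res$summary$n), total)
  expect_equal(sum(res$pairs$category == "same_unit"), U * choose(B, 2))
})

test_that("same-unit pairs are tighter than neighboring different-unit pairs", {
  cfg <- sim_config(rng_seed = 103)
  # force neighbors: centers drawn from a short 12-contact span
  out <- simulate_waveform_blocks(cfg, n_track_units = 6, n_blocks = 4,
                                  n_contacts = 12, spatial_sd = 2,
                                  snr = 5, drift_per_block = 0.02,
                                  spikes_per_block = 25)
  res <- pair_category_analysis(out$blocks)
  s <- res$summary
  r_same <- s$median_r[s$category == "same_unit"]
  r_neigh <- s$median_r[s$category == "neighboring_different_unit"]
  smd_same <- s$median_smd[s$category == "same_unit"]
  smd_neigh <- s$median_smd[s$category == "neighboring_different_unit"]
  expect_gt(r_same, r_neigh)
  expect_lt(smd_same, smd_neigh)
  expect_lt(res$tests$r_same_vs_neighboring, 0.01)
  expect_lt(res$tests$smd_same_vs_neighboring, 0.01)
})

test_that("waveform noise monotonically erodes same-unit correlation", {
  med_r <- vapply(c(10, 40, 120), function(nsd) {
    cfg <- sim_config(rng_seed = 107)
    out <- simulate_waveform_blocks(cfg, n_track_units = 4, n_blocks = 3,
                                    n_contacts = 12, peak_uv = 100,
                                    snr = 100 / nsd, spikes_per_block = 4,
                                    drift_per_block = 0)
    res <- pair_category_analysis(out$blocks)
    s <- res$summary
    s$median_r[s$category == "same_unit"]
  }, 0)
  expect_true(all(diff(med_r) < 0))
})
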