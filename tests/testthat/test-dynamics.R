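mk_trace_activity <- function(Z, bin_width = 0.025,
                              slices = list(c(first = 1L, last = ncol(Z)))) {
  structure(list(Z = Z, n_bins = ncol(Z), bin_width = bin_width,
                 unit_ids = seq_len(nrow(Z)) - 1L,
                 areas = rep("dHPC", nrow(Z)),
                 session_slices = slices),
            class = "binned_activity")
}

mk_pattern <- function(weights, members) {
  structure(list(weights = weights, otsu_threshold = NA_real_,
                 member_mask = seq_along(weights) %in% members,
                 ensemble_id = 1L),
            class = "ensemble_pattern")
}

test_that("activation strength evaluates the zero-diagonal quadratic form exactly", {
  # two members, w = (1,1)/sqrt(2), z = (1,1): A = 2 * 1 * 0.5 * 1 = 1
  Z <- cbind(c(1, 1), c(1, 0), c(-1, -1), c(2, -2))
  act <- mk_trace_activity(Z)
  pat <- mk_pattern(c(1, 1) / sqrt(2), members = 1:2)
  tr <- activation_strength(act, pat)
  expect_equal(tr$A[1], 1)
  # exactly one member nonzero -> zero-diagonal kills the bin
  expect_identical(tr$A[2], 0)
  # quadratic parity: negating z leaves A unchanged
  expect_equal(tr$A[3], tr$A[1])
  # anti-correlated members go negative and are NOT clipped
  expect_equal(tr$A[4], -4)
})

test_that("activation strength matches the explicit double-loop oracle", {
  set.seed(51)
  for (i in 1:100) {
    m <- sample(2:8, 1)
    nb <- sample(5:30, 1)
    w <- rnorm(m)
    Z <- matrix(rnorm(m * nb), m)
    act <- mk_trace_activity(Z)
    pat <- mk_pattern(w, members = seq_len(m))
    tr <- activation_strength(act, pat)
    for (b in sample(nb, 3)) {
      expect_equal(tr$A[b], oracle_activation(w, Z[, b]), tolerance = 1e-10)
    }
  }
})

test_that("retaining the diagonal adds exactly the single-neuron terms", {
  set.seed(53)
  m <- 5; nb <- 40
  w <- rnorm(m); w <- w / sqrt(sum(w^2))
  Z <- matrix(rnorm(m * nb), m)
  act <- mk_trace_activity(Z)
  tr <- activation_strength(act, mk_pattern(w, 1:m))
  with_diag <- as.vector(crossprod(w, Z))^2
  expect_equal(with_diag - tr$A, colSums((w * Z)^2), tolerance = 1e-10)
})

test_that("activation threshold modes and the single-member guard behave", {
  set.seed(55)
  Z <- matrix(rnorm(3 * 500), 3)
  act <- mk_trace_activity(Z)
  pat <- mk_pattern(c(0.7, 0.7, 0.14), 1:3)
  tr_all <- activation_strength(act, pat, threshold_mode = "all")
  expect_equal(tr_all$threshold, mean(tr_all$A) + 2 * sd(tr_all$A))
  tr_sb <- activation_strength(act, pat, threshold_mode = "supra_baseline")
  expect_equal(tr_sb$threshold,
               mean(tr_sb$A) + 2 * sd(tr_sb$A[tr_sb$A > mean(tr_sb$A)]))
  expect_identical(tr_all$active_bins, tr_all$A > tr_all$threshold)
  expect_error(activation_strength(act, mk_pattern(c(1, 0, 0), 1)),
               "single-member")
})

test_that("SWR-triggered tuning is zero for a flat trace and separates coupled ensembles", {
  flat <- structure(list(A = rep(3.3, 2000), threshold = 3.3,
                         active_bins = rep(FALSE, 2000),
                         session_slices = list(c(first = 1L, last = 2000L)),
                         bin_width = 0.025),
                    class = "activation_trace")
  res <- swr_triggered_activation(flat, c(5, 20, 30))
  expect_equal(res$tuning, 0)

  # planted: one coupled, one uncoupled ensemble in the same recording
  cfg <- sim_config(n_units = 30, n_ensembles = 2, members_per_ensemble = 6,
                    event_rate = 0.15, swr_rate = 0.15, swr_coupling_prob = 0.5,
                    sessions = data.frame(day_stamp = 0L, duration = 1200),
                    rng_seed = 101)
  out <- simulate_spike_trains(cfg)
  coupled <- vapply(out$ground_truth$ensembles, function(e) e$swr_coupled, NA)
  # seed 101 yields one coupled + one uncoupled (guaranteed by construction here)
  expect_setequal(coupled, c(TRUE, FALSE))
  ba <- bin_and_zscore(out$spike_tables, durations = 1200)
  swr <- out$ground_truth$swr_times[[1]]
  tun <- vapply(1:2, function(e) {
    mem <- match(out$ground_truth$ensembles[[e]]$members, ba$unit_ids)
    w <- rep(1 / sqrt(length(mem)), length(mem))
    pat <- mk_pattern(replace(rep(0, nrow(ba$Z)), mem, w), mem)
    tr <- activation_strength(ba, pat)
    swr_triggered_activation(tr, swr)$tuning
  }, 0)
  expect_gt(tun[which(coupled)], tun[which(!coupled)])

  # circular-shift surrogates: the real tuning beats every shifted control,
  # and the surrogate tunings collapse toward 0
  mem <- match(out$ground_truth$ensembles[[which(coupled)]]$members, ba$unit_ids)
  w <- rep(1 / sqrt(length(mem)), length(mem))
  tr <- activation_strength(ba, mk_pattern(replace(rep(0, nrow(ba$Z)), mem, w), mem))
  set.seed(7)
  null_tun <- vapply(1:20, function(i) {
    shift <- runif(1, 60, 1140)
    swr_triggered_activation(tr, (swr + shift) %% 1200)$tuning
  }, 0)
  expect_gt(tun[which(coupled)], max(null_tun))
  expect_lt(abs(mean(null_tun)), tun[which(coupled)] / 5)
})

test_that("member firing rates exceed non-member rates during ensemble activation", {
  out <- quick_sim(61, n_units = 40, n_ensembles = 1, members_per_ensemble = 8,
                   duration = 1200, event_rate = 0.15,
                   area_assignment = rep(c("dHPC", "PrL"), each = 20))
  ba <- bin_and_zscore(out$sim$spike_tables, durations = 1200)
  pats <- extract_patterns(ba, 1, seed = 61)
  tr <- activation_strength(ba, pats[[1]])
  res <- member_rate_contrast(ba, pats[[1]], tr)
  member_areas <- unique(ba$areas[pats[[1]]$member_mask])
  pa <- res$per_area[res$per_area$area %in% member_areas, ]
  expect_true(all(pa$member_mean > pa$nonmember_mean))
  expect_true(any(pa$p < 0.01))
  # degenerate grouping: all neurons members -> every area skipped, with warnings
  all_pat <- mk_pattern(rep(1 / sqrt(nrow(ba$Z)), nrow(ba$Z)), seq_len(nrow(ba$Z)))
  w <- testthat::capture_warnings(res2 <- member_rate_contrast(ba, all_pat, tr))
  expect_true(all(grepl("skipped", w)) && length(w) >= 1)
  expect_null(res2$per_area)
})

test_that("ensemble lifetime is the active-session day span, dormancy allowed", {
  manifest <- as_session_manifest(data.frame(
    session_id = paste0("s", 1:4), day_stamp = c(0L, 3L, 7L, 10L),
    duration_s = 10, spike_table = "x", lfp = NA))
  nb <- 10L  # bins per session
  mk_tr <- function(active_sessions) {
    act <- rep(FALSE, 4 * nb)
    for (s in active_sessions) act[(s - 1L) * nb + seq_len(6)] <- TRUE
    structure(list(A = as.numeric(act), threshold = 0.5, active_bins = act,
                   session_slices = lapply(1:4, function(s) {
                     c(first = (s - 1L) * nb + 1L, last = s * nb)
                   }),
                   bin_width = 0.025),
              class = "activation_trace")
  }
  expect_equal(ensemble_lifetime(mk_tr(1:4), manifest)$lifetime_days, 10)
  expect_equal(ensemble_lifetime(mk_tr(2), manifest)$lifetime_days, 0)
  gap <- ensemble_lifetime(mk_tr(c(1, 4)), manifest)
  expect_equal(gap$lifetime_days, 10)
  expect_equal(gap$dormant_sessions, c(2L, 3L))
  none <- ensemble_lifetime(mk_tr(integer(0)), manifest)
  expect_true(is.na(none$lifetime_days))
  # fewer than min_active_bins supra-threshold bins does not activate a session
  tr1 <- mk_tr(1)
  tr1$active_bins[1:6] <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_true(is.na(ensemble_lifetime(tr1, manifest)$lifetime_days))
})

test_that("member detectability applies the strict > 2/3 rule over consecutive days", {
  manifest <- as_session_manifest(data.frame(
    session_id = paste0("s", 1:5), day_stamp = c(0L, 6L, 12L, 18L, 24L),
    duration_s = 10, spike_table = "x", lfp = NA))
  members <- 1:9
  full <- lapply(1:5, function(s) 1:9)
  expect_equal(member_detectability(full, members, manifest), 24)
  # exactly 6/9 = 2/3 in the middle session is NOT > 2/3: span breaks
  broken <- full
  broken[[3]] <- 1:6
  expect_equal(member_detectability(broken, members, manifest), 6)
  # hand-computed dropout fixture: ok pattern T T F T T -> best span 6 days
  fix <- list(1:9, 1:7, 1:5, 1:9, 1:8)
  expect_equal(member_detectability(fix, members, manifest), 6)
  none <- lapply(1:5, function(s) integer(0))
  expect_true(is.na(member_detectability(none, members, manifest)))
})

test_that("classification cutoffs follow the mean + s.d. rule", {
  rec <- data.frame(ensemble_id = 1:5,
                    swr_tuning = c(0, 0, 0, 0, 10),
                    lifetime_days = c(1, 1, 1, 1, 50))
  out <- classify_ensembles(rec)
  expect_equal(attr(out, "cutoff_life"), mean(rec$lifetime_days) + sd(rec$lifetime_days))
  expect_equal(attr(out, "cutoff_life"), 10.8 + 21.9135, tolerance = 1e-4)
  expect_equal(sum(rec$lifetime_days > attr(out, "cutoff_life")), 1)
  # record 5 exceeds BOTH cutoffs (tuning 10 > 6.47, lifetime 50 > 32.7):
  # neither quadrant applies, so it is "other"
  expect_equal(out$class_label[5], "other")
  # with low tuning instead, the 50-day record is long_lived_low_tuning
  rec2 <- transform(rec, swr_tuning = c(0, 0, 0, 10, 0))
  out2 <- classify_ensembles(rec2)
  expect_equal(out2$class_label[5], "long_lived_low_tuning")
  expect_equal(out2$class_label[4], "short_lived_high_tuning")
})

test_that("degenerate and undersized classification inputs are handled", {
  same <- data.frame(ensemble_id = 1:3, swr_tuning = c(2, 2, 2),
                     lifetime_days = c(4, 4, 4))
  out <- classify_ensembles(same)
  expect_true(all(out$class_label == "other"))  # sd 0: nothing strictly exceeds
  expect_error(classify_ensembles(data.frame(ensemble_id = 1, swr_tuning = 1,
                                             lifetime_days = 1)),
               ">= 2")
  # records with undefined tuning are excluded from cutoffs and labelled NA
  rec <- data.frame(ensemble_id = 1:3, swr_tuning = c(NA, 1, 5),
                    lifetime_days = c(2, 3, 4))
  out2 <- classify_ensembles(rec)
  expect_true(is.na(out2$class_label[1]))
})
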