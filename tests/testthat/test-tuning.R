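test_that("plug-in mutual information matches closed forms and brute force", {
  # constant response carries no information
  set.seed(20)
  b <- sample(1:30, 2000, replace = TRUE)
  expect_equal(mutual_information(b, rep(1, 2000)), 0)
  expect_equal(mutual_information(b, rep(0, 2000)), 0)
  # balanced indicator of one bin: exactly one bit
  b2 <- rep(c(1L, 2L), 500)
  expect_equal(mutual_information(b2, as.numeric(b2 == 1), n_levels = 30), 1)
  # brute-force double-loop agreement on random pairs
  for (i in 1:3) {
    bb <- sample(1:30, 1000, replace = TRUE)
    rr <- rbinom(1000, 1, plogis(scale(bb)))
    expect_lt(abs(mutual_information(bb, rr, 30) - brute_mi(bb, rr, 30)),
              1e-12)
  }
  expect_error(mutual_information(integer(0), numeric(0)), "empty")
  # probabilistic responses interpolate the binary histogram
  expect_equal(mutual_information(b2, rep(0.5, 1000), n_levels = 30), 0)
})

test_that("a lagged threshold unit recovers its construction lag", {
  st <- lds_preset("no_spring")
  n_traj <- 8
  trs <- simulate_lds(st, 600, n_traj, seed = 26)
  angle <- unlist(lapply(trs, function(tr) tr$theta[, 1]))
  trajid <- rep(seq_len(n_traj), each = 600)
  for (lag in c(0L, 7L)) {
    z <- lagged_threshold_unit(angle, trajid, lag)
    lt <- lagged_mi_profile(z, angle, trajid, seed = 2)
    expect_false(lt$untuned[1])
    expect_equal(lt$pref_lag[1], lag)
    expect_equal(lt$pref_lag_s[1], lag * 0.05)
  }
})

test_that("shuffle censoring behaves as its null model predicts", {
  # the 95th-percentile rule admits ~5% of lags per unit under the null;
  # with 41 lags tested per unit, most noise units keep >= 1 lag, but the
  # per-(unit, lag) false-positive rate must stay near the nominal level,
  # and surviving noise MI is far below genuinely tuned MI
  st <- lds_preset("no_spring")
  fp_rates <- tuned_ratio <- numeric(3)
  for (sd in 1:3) {
    trs <- simulate_lds(st, 500, 20, seed = 200 + sd)
    angle <- unlist(lapply(trs, function(tr) tr$theta[, 1]))
    trajid <- rep(1:20, each = 500)
    set.seed(100 + sd)
    Z <- matrix(as.numeric(runif(length(angle) * 15) < 0.3), ncol = 15)
    lt <- lagged_mi(Z, angle, trajid, seed = 300 + sd)
    fp_rates[sd] <- mean(lt$mi_sig > 0)
    tuned <- lagged_threshold_unit(angle, trajid, 5L)
    lt_t <- lagged_mi_profile(tuned, angle, trajid, seed = 300 + sd)
    tuned_ratio[sd] <- max(lt_t$mi_sig) / max(lt$mi_sig)
  }
  expect_true(all(fp_rates < 0.15))      # nominal ~5% per (unit, lag)
  expect_true(all(tuned_ratio > 20))     # real tuning dwarfs censored noise
})

test_that("untuned responses carry no significant information", {
  # a response independent of the stimulus either loses every lag or keeps
  # only near-noise MI; censored MI is zero by construction at masked lags
  st <- lds_preset("no_spring")
  trs <- simulate_lds(st, 500, 10, seed = 33)
  angle <- unlist(lapply(trs, function(tr) tr$theta[, 1]))
  trajid <- rep(1:10, each = 500)
  set.seed(17)
  z <- as.numeric(runif(5000) < 0.4)
  lt <- lagged_mi_profile(z, angle, trajid, seed = 4)
  expect_true(all(lt$mi_sig[lt$mi_sig == 0] == 0))
  expect_lt(max(lt$mi), 0.02)            # bits; pure noise at n = 5000
  expect_true(all(lt$mi >= 0))
})

test_that("receptive-field grids flag empty cells and keep probabilities", {
  st <- lds_preset("no_spring")
  trs <- simulate_lds(st, 500, 4, seed = 52)
  states <- do.call(rbind, lapply(trs, function(tr) tr$theta))
  # constant half-active unit: flat field at 0.5 on occupied cells
  rf <- pv_receptive_field(rep(0.5, nrow(states)), states)
  occ <- !is.na(rf$prob)
  expect_true(all(rf$prob[occ] == 0.5))
  expect_true(all(rf$count[!occ] == 0))
  expect_true(all(rf$prob[occ] >= 0 & rf$prob[occ] <= 1))
  # oscillator states rarely visit the corners: those cells stay flagged
  st2 <- lds_preset("uncontrolled")
  trs2 <- simulate_lds(st2, 1000, 4, seed = 53)
  states2 <- do.call(rbind, lapply(trs2, function(tr) tr$theta))
  rf2 <- pv_receptive_field(rep(1, nrow(states2)), states2)
  expect_gt(sum(is.na(rf2$prob)), 0)
})

test_that("predicted receptive fields match measured ones for a constructed unit", {
  st <- lds_preset("no_spring")
  n_traj <- 10
  trs <- simulate_lds(st, 1000, n_traj, seed = 61)
  angle <- unlist(lapply(trs, function(tr) tr$theta[, 1]))
  states <- do.call(rbind, lapply(trs, function(tr) tr$theta))
  trajid <- rep(seq_len(n_traj), each = 1000)
  z <- lagged_threshold_unit(angle, trajid, 7L)
  lt <- lagged_mi_profile(z, angle, trajid, seed = 3)
  expect_equal(lt$pref_lag[1], 7L)
  ve <- default_rf_vel_edges(states)
  rf <- pv_receptive_field(z, states, vel_edges = ve)
  prf <- predicted_pv_rf(lt$tuning[, 1], lt$pref_lag[1], angle, states,
                         trajid, vel_edges = ve)
  expect_gt(rf_correlation(rf, prf), 0.9)
  # a flat tuning curve predicts a flat field
  flat <- predicted_pv_rf(rep(0.3, 30), 0L, angle, states, trajid,
                          vel_edges = ve)
  expect_true(all(abs(flat$prob[!is.na(flat$prob)] - 0.3) < 1e-12))
})

test_that("data processing: shuffling cannot increase information", {
  st <- lds_preset("no_spring")
  trs <- simulate_lds(st, 500, 10, seed = 71)
  angle <- unlist(lapply(trs, function(tr) tr$theta[, 1]))
  trajid <- rep(1:10, each = 500)
  z <- lagged_threshold_unit(angle, trajid, 0L)
  bins <- refh:::bin_angle(angle, -pi / 3, 2 * pi / 3, 30)
  mi0 <- mutual_information(bins, z, 30)
  set.seed(5)
  sh <- replicate(20, mutual_information(bins, sample(z), 30))
  expect_gt(mi0, median(sh))
  expect_gt(mi0, max(sh))
})

test_that("circular autocorrelation tracks the damping coefficient", {
  ints <- vapply(1:5, function(i) {
    st <- lds_preset("damping_variants", i)
    trs <- simulate_lds(st, 1000, 10, seed = 42)
    angle <- unlist(lapply(trs, function(tr) tr$theta[, 1]))
    sum(zar_autocorrelation(angle, rep(1:10, each = 1000), 1:40))
  }, numeric(1))
  expect_true(all(diff(ints) > 0))       # heavier damping, longer memory
  # r(0) = 1 for any non-degenerate sequence
  st <- lds_preset("no_spring")
  tr <- simulate_lds(st, 400, 1, seed = 2)[[1]]
  r <- zar_autocorrelation(tr$theta[, 1], rep(1, 400), 0:5)
  expect_equal(r[1], 1, tolerance = 1e-12)
  expect_true(all(abs(r) <= 1 + 1e-12))
})

test_that("histogram-autocorrelation overlay preserves the integral", {
  st <- lds_preset("no_spring")
  trs <- simulate_lds(st, 500, 5, seed = 81)
  angle <- unlist(lapply(trs, function(tr) tr$theta[, 1]))
  trajid <- rep(1:5, each = 500)
  pl <- c(0L, 1L, 1L, 2L, 5L, NA)
  out <- lag_histogram_vs_autocorrelation(pl, angle, trajid, lags = 0:10)
  expect_equal(sum(out$hist), 5)          # NA (untuned) dropped
  expect_equal(sum(out$acf_scaled), sum(out$hist), tolerance = 1e-10)
})

test_that("weight sorting is a joint permutation of hidden and recurrent", {
  set.seed(91)
  p <- refh_params_init(6, 4, w_sd = 0.5)
  pa <- c(0.3, -0.1, 0.5, 0, -0.4, 0.2)
  sw <- sort_weight_matrix(p, "preferred_angle", pref_angle = pa)
  expect_true(all(sort(sw$perm) == 1:6))   # a bijection
  expect_equal(sum(sw$W_fb), sum(p$W_fb))  # mass preserved
  expect_equal(sw$W_prop, p$W_prop[sw$perm, ])
  expect_equal(sw$W_fb, p$W_fb[sw$perm, sw$perm])
  # already-sorted keys give the identity permutation
  sw2 <- sort_weight_matrix(p, "preferred_lag", pref_lag = 1:6)
  expect_equal(sw2$perm, 1:6)
  expect_equal(sw2$W_fb, p$W_fb)
  expect_error(sort_weight_matrix(p, "preferred_lag", pref_lag = 1:3),
               "per hidden unit")
})
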