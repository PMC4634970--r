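# Trained models and derived analyses are expensive, so they are built once
# per test run and shared across test files through a cache.  Desk-scale
# problem sizes throughout: 60-unit / 20-epoch uncontrolled networks,
# 90-unit / 30-epoch no-spring networks, 20-trajectory test sets.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

get_unctrl_fit <- function(seed) {
  memo(paste0("unctrl_fit_", seed),
       refh(n_hidden = 60, epochs = 20, seed = seed))
}

get_unctrl_untrained <- function(seed) {
  memo(paste0("unctrl_un_", seed),
       refh(n_hidden = 60, epochs = 20, seed = seed, train = FALSE))
}

get_unctrl_test <- function(seed = 777) {
  memo(paste0("unctrl_test_", seed),
       encode_dataset(lds_preset("uncontrolled"), 1000, 20, seed = seed))
}

get_nospring_fit <- function(seed) {
  memo(paste0("nospring_fit_", seed),
       refh(preset = "no_spring", n_hidden = 90, epochs = 30, seed = seed,
            checkpoints = c(100, 200, 1000)))
}

# Full tuning analysis of a trained no-spring network on a common test set
get_nospring_analysis <- function(seed) {
  memo(paste0("nospring_an_", seed), {
    fit <- get_nospring_fit(seed)
    st <- lds_preset("no_spring")
    n_traj <- 20
    test <- encode_dataset(st, 1000, n_traj, seed = 999)
    Z <- do.call(rbind, lapply(test$traj, function(tr)
      filter_forward(fit, tr$r_prop)))
    angle <- unlist(lapply(test$traj, function(tr) tr$theta[, 1]))
    states <- do.call(rbind, lapply(test$traj, function(tr) tr$theta))
    trajid <- rep(seq_len(n_traj), each = 1000)
    lt <- lagged_mi(Z, angle, trajid, seed = 1)
    vel_edges <- default_rf_vel_edges(states)
    sig <- which(!lt$untuned)
    cors <- vapply(sig, function(u) {
      rf <- pv_receptive_field(Z[, u], states, vel_edges = vel_edges)
      prf <- predicted_pv_rf(lt$tuning[, u], lt$pref_lag[u], angle, states,
                             trajid, vel_edges = vel_edges)
      rf_correlation(rf, prf)
    }, numeric(1))
    list(fit = fit, test = test, Z = Z, angle = angle, states = states,
         trajid = trajid, lt = lt, vel_edges = vel_edges, sig = sig,
         cors = cors)
  })
}

default_rf_vel_edges <- function(states) {
  lim <- stats::quantile(states[, 2], c(0.01, 0.99), names = FALSE)
  seq(lim[1], lim[2], length.out = 16)
}

# Preferred-lag emergence across training checkpoints (fewer trajectories:
# the checkpoint analysis is qualitative)
get_emergence <- function(seed) {
  memo(paste0("emergence_", seed), {
    fit <- get_nospring_fit(seed)
    an <- get_nospring_analysis(seed)
    n_use <- 6000L
    vapply(c("100", "200", "1000"), function(cp) {
      Zc <- do.call(rbind, lapply(an$test$traj[1:6], function(tr)
        filter_forward(fit$checkpoints[[cp]], tr$r_prop)))
      ltc <- lagged_mi(Zc, an$angle[seq_len(n_use)],
                       an$trajid[seq_len(n_use)], seed = 1)
      mean(abs(ltc$pref_lag), na.rm = TRUE)
    }, numeric(1))
  })
}

# EM benchmarks on the uncontrolled system: best-of-5 EM^1 and EM^2 fits on
# a 40 x 1000 training set, evaluated on a 20-trajectory test set
get_unctrl_benchmarks <- function(seed) {
  memo(paste0("bench_", seed), {
    st <- lds_preset("uncontrolled")
    train <- encode_dataset(st, 1000, 40, seed = 500 + seed)
    obs <- lapply(train$traj, pseudo_obs_seq, code_prop = train$code_prop)
    truth <- lapply(train$traj, function(tr) tr$theta[, 1])
    test <- encode_dataset(st, 1000, 20, seed = 600 + seed)
    obs_t <- lapply(test$traj, pseudo_obs_seq, code_prop = test$code_prop)
    truth_t <- lapply(test$traj, function(tr) tr$theta[, 1])
    L <- train$code_prop$L
    val <- list(obs = obs, truth = truth)
    em1 <- em_lds(obs, 1, wrapL = L, n_restarts = 5, seed = 70 + seed,
                  val = val)
    em2 <- em_lds(obs, 2, wrapL = L, n_restarts = 5, seed = 80 + seed,
                  val = val)
    mse_of <- function(m) error_stats(lapply(obs_t, function(o)
      predict(m, o)), truth_t, L)$mse
    list(
      em1 = em1, em2 = em2, st = st, L = L,
      mse = c(
        PROP = error_stats(estimator_naive(test$code_prop)(test),
                           truth_t, L)$mse,
        EM1 = mse_of(em1), EM2 = mse_of(em2),
        OPT = error_stats(estimator_kf(kf_model(st))(test), truth_t, L)$mse)
    )
  })
}

# Controlled-system benchmarks: best-of-5 EM^3 versus the controls-blind
# regression filter (OBS), on a common 40 x 1000 data set
get_ctrl_benchmarks <- function(seed) {
  memo(paste0("ctrl_bench_", seed), {
    st <- lds_preset("controlled")
    data <- encode_dataset(st, 1000, 40, seed = 800 + seed)
    obs <- lapply(data$traj, pseudo_obs_seq, code_prop = data$code_prop,
                  code_efcp = data$code_efcp)
    obs_angle <- lapply(data$traj, pseudo_obs_seq,
                        code_prop = data$code_prop)
    truth <- lapply(data$traj, function(tr) tr$theta[, 1])
    L <- data$code_prop$L
    em3 <- em_lds(obs, 3, wrapL = c(L, data$code_efcp$L), n_restarts = 5,
                  seed = 90 + seed, val = list(obs = obs, truth = truth))
    ob <- obs_fit(data$traj, wrapL = L)
    list(
      em3 = em3, obs_model = ob,
      mse = c(
        EM3 = error_stats(lapply(obs, function(o) predict(em3, o)),
                          truth, L)$mse,
        OBS = error_stats(lapply(obs_angle, function(o) predict(ob, o)),
                          truth, L)$mse)
    )
  })
}

# a synthetic unit that fires as a deterministic threshold on the (wrapped,
# i.e. encoded) angle at a fixed lag into the past (within trajectories)
lagged_threshold_unit <- function(angle, trajid, lag) {
  z <- as.numeric(wrap_to_range(angle, -pi / 3, 2 * pi / 3) > 0)
  unlist(lapply(split(seq_along(angle), trajid), function(ix) {
    zi <- z[ix]
    if (lag > 0) c(rep(0, lag), zi[seq_len(length(ix) - lag)]) else zi
  }), use.names = FALSE)
}
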