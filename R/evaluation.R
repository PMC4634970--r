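#' Wrapped error statistics for a sequence of estimates
#'
#' The error at each step is the wrapped difference between estimate and
#' truth, mapped to `(-L/2, L/2]`; statistics are pooled over everything
#' passed in (time steps and trajectories alike).  The variance is the
#' population variance, so `mse = mean^2 + var` exactly.  `NA` estimates
#' (missing observations) are dropped and counted.
#'
#' @param est estimate vector (or list of vectors, one per trajectory).
#' @param truth matching truth vector (or list).
#' @param L wrap length of the stimulus space.
#' @param model optional label carried through to the result.
#' @return an object of class `"error_stats"`: list with `model`, `mean`,
#'   `var`, `mse`, `n`, `n_missing`.
#' @export
error_stats <- function(est, truth, L, model = NA_character_) {
  est <- unlist(est); truth <- unlist(truth)
  stopifnot(length(est) == length(truth))
  e <- wrap_diff(est - truth, L)
  miss <- is.na(e)
  e <- e[!miss]
  m <- mean(e)
  structure(list(model = model, mean = m, var = mean((e - m)^2),
                 mse = mean(e^2), n = length(e),
                 n_missing = sum(miss)),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats>%s mean %.4g, var %.4g, MSE %.4g (n = %d%s)\n",
              if (is.na(x$model)) "" else paste0(" [", x$model, "]"),
              x$mean, x$var, x$mse, x$n,
              if (x$n_missing > 0) sprintf(", %d missing", x$n_missing)
              else ""))
  invisible(x)
}

#' Estimator closures for the standard model families
#'
#' Convenience constructors turning a fitted object into a function that
#' maps a test set (from [encode_dataset()]) to a list of per-trajectory
#' angle-estimate vectors, the common currency of [run_protocol()],
#' [reliability_experiment()] and the error statistics.
#'
#' @param model an `"lds_model"` (true-parameter OPT, EM fit, or
#'   regression fit).
#' @param fit a `"refh"` fit.
#' @param code a [population_code()] (for the naive decoder).
#' @param channel observation channel to read out (1 = angle, 2 = torque).
#' @param fixed_v if non-`NULL`, the filter is blinded to instantaneous
#'   reliability: every pseudo-observation variance is replaced by this
#'   constant (a negative control for the reliability experiment).
#' @return a function `f(test_set) -> list of estimate vectors`.
#' @name estimators
NULL

#' @rdname estimators
#' @export
estimator_kf <- function(model, channel = 1, fixed_v = NULL) {
  function(test) {
    lapply(test$traj, function(tr) {
      obs <- pseudo_obs_seq(tr, test$code_prop, test$code_efcp)
      if (!is.null(fixed_v)) obs$v[is.finite(obs$v)] <- fixed_v
      predict.lds_model(model, obs, channel = channel)
    })
  }
}

#' @rdname estimators
#' @export
estimator_refh <- function(fit, channel = 1) {
  function(test) {
    lapply(test$traj, function(tr) {
      est <- decode_hidden(fit, filter_forward(fit, tr$r_prop, tr$r_efcp))
      if (channel == 1) est$angle else est$torque
    })
  }
}

#' @rdname estimators
#' @export
estimator_naive <- function(code, field = "r_prop") {
  function(test) {
    lapply(test$traj, function(tr) naive_decode(code, tr[[field]]))
  }
}

truth_angles <- function(test) lapply(test$traj, function(tr) tr$theta[, 1])
truth_torque <- function(test) lapply(test$traj, function(tr) tr$u)

#' Pooled MSE of an estimator on a test set
#'
#' @param estimator a closure from [estimators].
#' @param test a data set from [encode_dataset()].
#' @param channel 1 for angle, 2 for torque.
#' @return the pooled mean squared (wrapped) error.
#' @export
estimator_mse <- function(estimator, test, channel = 1) {
  truth <- if (channel == 1) truth_angles(test) else truth_torque(test)
  L <- if (channel == 1) test$code_prop$L else test$code_efcp$L
  error_stats(estimator(test), truth, L)$mse
}

#' Best-of-K / token replication protocol
#'
#' For each of `n_tokens` tokens: fit `K` models per family from scratch
#' (seeded from the token and restart indices), evaluate every model on the
#' token's test set, and keep the best MSE per family.  The *same* test set
#' is used for matching tokens of different families.  Across tokens the
#' median and quartiles are reported.
#'
#' @param families named list of functions `f(fit_seed, test_set) -> mse`.
#' @param n_tokens number of protocol repetitions.
#' @param K models trained per token per family.
#' @param make_test function `f(seed) -> test set`.
#' @param seed root seed.
#' @return object of class `"protocol_result"`: `best` (family x token MSE
#'   matrix) and `summary` (data frame of median and quartiles).
#' @export
run_protocol <- function(families, n_tokens, K, make_test, seed = 1) {
  stopifnot(length(names(families)) == length(families))
  best <- matrix(NA_real_, length(families), n_tokens,
                 dimnames = list(names(families), NULL))
  for (j in seq_len(n_tokens)) {
    test <- make_test(traj_seed(seed, 7000 + j))
    for (f in seq_along(families)) {
      mses <- vapply(seq_len(K), function(r)
        families[[f]](traj_seed(seed, 1000 * j + r), test), numeric(1))
      best[f, j] <- min(mses)
    }
  }
  q <- t(apply(best, 1, stats::quantile, probs = c(0.25, 0.5, 0.75)))
  structure(list(
    best = best,
    summary = data.frame(model = rownames(best), q1 = q[, 1],
                         median = q[, 2], q3 = q[, 3], row.names = NULL)
  ), class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result> best-of-K MSE quartiles across tokens\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Instantaneous-reliability experiment
#'
#' Tests filters on *noiseless* sensory data (mean spike counts instead of
#' Poisson samples) at a grid of fixed gains.  On such data the sensory
#' signal is perfectly reliable at every gain, so a filter that has learned
#' to up-weight high-count (nominally more reliable) input achieves lower
#' error at higher gain; a filter blind to instantaneous reliability shows a
#' flat profile.
#'
#' @param estimators named list of estimator closures (see [estimators]).
#' @param st the dynamical system to simulate.
#' @param gains gain grid; the default spans 4.8 to 12.8 in twelve steps,
#'   bracketing the training gain range.
#' @param n_sets test sets per gain.
#' @param n_traj,T trajectories per set and steps per trajectory.
#' @param seed root seed; the same trajectories are reused across gains so
#'   that gain is the only varying factor.
#' @return long data frame with columns `model`, `gain`, `set`, `mse`.
#' @export
reliability_experiment <- function(estimators, st,
                                   gains = seq(4.8, 12.8, length.out = 12),
                                   n_sets = 4, n_traj = 40, T = 1000,
                                   seed = 1) {
  rows <- list()
  for (s in seq_len(n_sets)) {
    for (g in gains) {
      test <- encode_dataset(st, T, n_traj,
                             seed = traj_seed(seed, 3000 + s),
                             fixed_gain = g, noiseless = TRUE)
      for (nm in names(estimators)) {
        rows[[length(rows) + 1]] <- data.frame(
          model = nm, gain = g, set = s,
          mse = estimator_mse(estimators[[nm]], test))
      }
    }
  }
  do.call(rbind, rows)
}
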