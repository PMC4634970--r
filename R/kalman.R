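#' Pseudo-observations from a Poisson population response
#'
#' For independent Poisson units with Gaussian tuning, the likelihood over
#' the stimulus is an unnormalized Gaussian; the Kalman-filter benchmarks
#' therefore consume each population response as a single scalar
#' pseudo-measurement: the center of mass \eqn{\sum_i \xi_i r_i / \sum_i r_i}
#' (computed circularly, see [com_decode()]) with variance
#' \eqn{\sigma_{tc}^2 / \sum_i r_i}.  A response with zero total count
#' carries no information and is flagged missing.
#'
#' @param code a [population_code()].
#' @param counts length-`n` vector or `T x n` matrix of counts (real-valued
#'   responses are allowed, as in the noiseless reliability test).
#' @return data frame with columns `s_hat`, `v`, `missing`.
#' @export
make_pseudo_obs <- function(code, counts) {
  if (is.vector(counts)) counts <- matrix(counts, 1)
  tot <- rowSums(counts)
  data.frame(
    s_hat = com_decode(code, counts),
    v = ifelse(tot > 0, code$sigma_tc^2 / tot, NA_real_),
    missing = tot == 0
  )
}

#' Linear-Gaussian state-space model for the filtering benchmarks
#'
#' Container consumed by [kf_filter()] / [rts_smooth()].  `Ups0` may carry
#' `Inf` diagonal entries for diffuse prior directions (the uniform initial
#' joint angle is treated as an infinite-variance Gaussian).
#'
#' @param Gamma n x n transition matrix.
#' @param mu_x length-n transition bias.
#' @param Sigma_x n x n process-noise covariance.
#' @param nu0,Ups0 initial mean and covariance.
#' @param H p x n observation matrix (one row per pseudo-observation
#'   channel).
#' @param wrapL length-p wrap lengths (0 = linear channel); observations on
#'   a wrapped channel are unwrapped to the branch nearest the filter's
#'   prediction.
#' @return an object of class `"lds_model"`.
#' @export
lds_model <- function(Gamma, mu_x, Sigma_x, nu0, Ups0, H, wrapL = 0) {
  n <- nrow(Gamma)
  H <- matrix(H, ncol = n)
  structure(list(Gamma = Gamma, mu_x = mu_x, Sigma_x = Sigma_x,
                 nu0 = nu0, Ups0 = Ups0, H = H,
                 wrapL = rep_len(wrapL, nrow(H)), order = n),
            class = "lds_model")
}

#' Optimal-filter model from the true generative parameters
#'
#' @param st an `"lds"` or `"lds_aug"` object.
#' @param code_prop,code_efcp population codes (their wrap lengths are
#'   attached to the observation channels).
#' @return an `"lds_model"` using the true parameters (the OPT benchmark).
#' @export
kf_model <- function(st, code_prop = population_code(15, st$angle_range),
                     code_efcp = if (st$controlled)
                       population_code(15, st$torque_range) else NULL) {
  ag <- if (inherits(st, "lds_aug")) st else augment_lds(st)
  H <- matrix(ag$C, 1)
  wrapL <- code_prop$L
  if (ag$controlled) {
    H <- rbind(H, ag$h)
    wrapL <- c(wrapL, code_efcp$L)
  }
  lds_model(ag$Gamma, ag$mu_x, ag$Sigma_x, ag$nu0, ag$Ups0, H, wrapL)
}

#' Pseudo-observation sequences for one encoded trajectory
#'
#' @param tr one trajectory from [encode_dataset()].
#' @param code_prop,code_efcp the population codes used to encode it.
#' @return list with `y` and `v`, `T x p` matrices (`p` = 1 or 2 channels).
#' @export
pseudo_obs_seq <- function(tr, code_prop, code_efcp = NULL) {
  po <- make_pseudo_obs(code_prop, tr$r_prop)
  y <- cbind(po$s_hat); v <- cbind(po$v)
  if (!is.null(tr$r_efcp) && !is.null(code_efcp)) {
    pu <- make_pseudo_obs(code_efcp, tr$r_efcp)
    y <- cbind(y, pu$s_hat); v <- cbind(v, pu$v)
  }
  list(y = y, v = v)
}

#' Kalman filtering with Poisson-population pseudo-observations
#'
#' Standard predict/update recursion in which each available
#' pseudo-observation contributes one scalar measurement with its own
#' variance; missing observations trigger prediction only.  Infinite prior
#' variances are handled in information form (zero prior precision), so no
#' arbitrary large-variance constants enter the recursion.
#'
#' @param model an `"lds_model"`.
#' @param obs list with `y`, `v` (`T x p`), e.g. from [pseudo_obs_seq()];
#'   `NA` entries are missing.
#' @return an object of class `"kf_beliefs"`: filtered `mean` (`T x n`),
#'   `cov` (`n x n x T`), one-step `pred_mean` / `pred_cov`, and the data
#'   `loglik` (which omits the t = 0 term under a diffuse prior).
#' @export
kf_filter <- function(model, obs) {
  res <- kf_rts_cpp(model$Gamma, model$mu_x, model$Sigma_x, model$nu0,
                    model$Ups0, model$H, as.matrix(obs$y), as.matrix(obs$v),
                    model$wrapL, FALSE)
  if (!all(is.finite(res$mean)))
    stop_invalid("numerical failure in kf_filter at t = %d",
                 which(!stats::complete.cases(res$mean))[1])
  structure(res, class = "kf_beliefs")
}

#' Fixed-interval (RTS) smoothing
#'
#' Runs the filter and the backward Rauch-Tung-Striebel pass, returning
#' smoothed marginals plus the lag-one cross-covariances that the EM M-step
#' needs.
#'
#' @inheritParams kf_filter
#' @return a `"kf_beliefs"` list with additional `smooth_mean`
#'   (`T x n`), `smooth_cov` (`n x n x T`) and `cross_cov`
#'   (`n x n x (T-1)`, slice `t` holding `cov(x_{t+1}, x_t)`).
#' @export
rts_smooth <- function(model, obs) {
  res <- kf_rts_cpp(model$Gamma, model$mu_x, model$Sigma_x, model$nu0,
                    model$Ups0, model$H, as.matrix(obs$y), as.matrix(obs$v),
                    model$wrapL, TRUE)
  structure(res, class = "kf_beliefs")
}

#' @export
print.lds_model <- function(x, ...) {
  cat(sprintf("<lds_model> order %d, %d observation channel(s)\n",
              x$order, nrow(x$H)))
  cat("Gamma =\n"); print(x$Gamma)
  invisible(x)
}

#' Filtered stimulus estimates from a state-space model
#'
#' @param object an `"lds_model"` (or EM / regression fit).
#' @param newdata observation list (`y`, `v`) or a data set from
#'   [encode_dataset()] together with codes taken from `attr`ibutes.
#' @param channel which observation channel to read out (1 = angle).
#' @param ... unused.
#' @return filtered estimate sequence (vector), or a list of them for a
#'   multi-trajectory data set.
#' @export
predict.lds_model <- function(object, newdata, channel = 1, ...) {
  read_out <- function(obs) {
    kf <- kf_filter(object, obs)
    est <- drop(kf$mean %*% object$H[channel, ])
    if (object$wrapL[channel] > 0) {
      L <- object$wrapL[channel]
      est <- wrap_to_range(est, -L / 2, L)
    }
    est
  }
  if (!is.null(newdata$y)) read_out(newdata) else lapply(newdata, read_out)
}

#' Unwrap circular observation sequences by continuity
#'
#' Shifts each observation by whole periods so that consecutive (available)
#' observations never jump by more than half a period.  The EM benchmarks
#' are fit on such non-wrapped sequences, which keeps the linear-Gaussian
#' likelihood well defined independently of the current parameter estimate.
#'
#' @param obs list with `y`, `v` (`T x p`).
#' @param wrapL per-channel wrap lengths (0 = already linear).
#' @return the observation list with unwrapped `y`.
#' @export
unwrap_obs <- function(obs, wrapL) {
  y <- as.matrix(obs$y)
  wrapL <- rep_len(wrapL, ncol(y))
  for (j in seq_len(ncol(y))) {
    L <- wrapL[j]
    if (L <= 0) next
    ref <- NA_real_
    for (t in seq_len(nrow(y))) {
      if (!is.finite(y[t, j])) next
      if (is.finite(ref))
        y[t, j] <- y[t, j] - L * round((y[t, j] - ref) / L)
      ref <- y[t, j]
    }
  }
  obs$y <- y
  obs
}

random_stable_matrix <- function(n, sr_range = c(0.5, 0.999)) {
  M <- matrix(stats::rnorm(n * n), n, n)
  target <- stats::runif(1, sr_range[1], sr_range[2])
  M * (target / max(Mod(eigen(M, only.values = TRUE)$values)))
}

#' Learn a linear dynamical system by expectation-maximization
#'
#' Fits the unconstrained transition parameters (`Gamma`, `mu_x`, `Sigma_x`,
#' `nu0`, `Ups0`) of an order-`order` linear-Gaussian system to
#' pseudo-observation sequences whose emission statistics (observation
#' matrix and per-step variances) are *given*, not learned.  Wrapped
#' channels are first unwrapped by continuity (see [unwrap_obs()]),
#' mirroring how the benchmark filters receive non-wrapped trajectories;
#' the E-step is then Kalman filtering plus RTS smoothing on fixed linear
#' data and the M-step the closed-form maximizer of the expected
#' complete-data log-likelihood, so the likelihood ascent is monotone.
#' The procedure is
#' repeated from `n_restarts` random stable initializations and the restart
#' with the best held-out filtering MSE (or, lacking validation data, the
#' best training log-likelihood) is returned.
#'
#' @param obs_list list of observation lists (`y`, `v`), one per trajectory.
#' @param order latent state dimension (the algorithm must be told it).
#' @param H observation matrix; default reads channel 1 from state 1 and
#'   (if a second channel is present) channel 2 from the last state.
#' @param wrapL per-channel wrap lengths (see [lds_model()]).
#' @param n_restarts random restarts.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed root seed for the restarts.
#' @param val list with `obs` (observation lists) and `truth` (matching list
#'   of true angle sequences) used to rank restarts by filtering MSE.
#' @return object of classes `"em_lds"` and `"lds_model"`, with the fitted
#'   parameters of the best restart, `loglik_trace` per restart, per-restart
#'   `val_mse`, and `restart` (the selected index).
#' @export
em_lds <- function(obs_list, order, H = NULL, wrapL = 0, n_restarts = 5,
                   max_iter = 50, tol = 1e-6, seed = 1, val = NULL) {
  p <- ncol(obs_list[[1]]$y)
  if (is.null(H)) {
    H <- matrix(0, p, order)
    H[1, 1] <- 1
    if (p > 1) H[2, order] <- 1
  }
  wrapL <- rep_len(wrapL, p)
  # fit on continuity-unwrapped sequences: with fixed (linear) data the EM
  # likelihood ascent is exactly monotone
  fit_obs <- lapply(obs_list, unwrap_obs, wrapL = wrapL)
  y1 <- unlist(lapply(fit_obs, function(o) o$y[, 1]))
  s2_diff <- stats::var(diff(y1), na.rm = TRUE)
  s2_obs <- stats::var(y1, na.rm = TRUE)

  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(traj_seed(seed, r))
    Gamma <- random_stable_matrix(order)
    mu_x <- numeric(order)
    Sigma <- diag(order) * max(s2_diff, 1e-8)
    nu0 <- numeric(order)
    for (j in seq_len(p)) {
      yj0 <- fit_obs[[1]]$y[1, j]
      if (is.finite(yj0)) nu0 <- nu0 + H[j, ] * yj0
    }
    Ups0 <- diag(order) * max(s2_obs, 1e-6)
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      model <- lds_model(Gamma, mu_x, Sigma, nu0, Ups0, H, wrapL = 0)
      stats_acc <- em_estep(model, fit_obs)
      ll <- stats_acc$loglik
      ll_trace <- c(ll_trace, ll)
      upd <- em_mstep(stats_acc, order)
      Gamma <- upd$Gamma; mu_x <- upd$mu_x; Sigma <- upd$Sigma
      nu0 <- upd$nu0; Ups0 <- upd$Ups0
      if (is.finite(ll_prev) && (ll - ll_prev) < tol * (abs(ll_prev) + 1))
        break
      ll_prev <- ll
    }
    fits[[r]] <- list(Gamma = Gamma, mu_x = mu_x, Sigma = Sigma,
                      nu0 = nu0, Ups0 = Ups0, loglik_trace = ll_trace)
  }
  if (all(vapply(fits, function(f) !any(is.finite(f$loglik_trace)),
                 logical(1))))
    stop_invalid("all EM restarts diverged; log-likelihood traces: %s",
                 paste(vapply(fits, function(f)
                   paste(signif(f$loglik_trace, 4), collapse = ","),
                   character(1)), collapse = " | "))

  val_mse <- rep(NA_real_, n_restarts)
  if (!is.null(val)) {
    for (r in seq_len(n_restarts)) {
      f <- fits[[r]]
      model <- lds_model(f$Gamma, f$mu_x, f$Sigma, f$nu0, f$Ups0, H, wrapL)
      errs <- unlist(lapply(seq_along(val$obs), function(i) {
        est <- predict.lds_model(model, val$obs[[i]])
        e <- est - val$truth[[i]]
        if (wrapL[1] > 0) e <- wrap_diff(e, wrapL[1])
        e
      }))
      val_mse[r] <- mean(errs^2, na.rm = TRUE)
    }
    best <- which.min(val_mse)
    if (length(best) == 0)
      best <- which.max(vapply(fits, function(f)
        utils::tail(f$loglik_trace, 1), numeric(1)))
  } else {
    best <- which.max(vapply(fits, function(f)
      utils::tail(f$loglik_trace, 1), numeric(1)))
  }
  f <- fits[[best]]
  out <- lds_model(f$Gamma, f$mu_x, f$Sigma, f$nu0, f$Ups0, H, wrapL)
  out$loglik_trace <- f$loglik_trace
  out$all_traces <- lapply(fits, `[[`, "loglik_trace")
  out$val_mse <- val_mse
  out$restart <- best
  out$n_restarts <- n_restarts
  class(out) <- c("em_lds", "lds_model")
  out
}

# E-step: smoothed sufficient statistics pooled over trajectories
em_estep <- function(model, obs_list) {
  n <- model$order
  Exx_past <- Exx_next <- Eyx <- matrix(0, n, n)
  sx <- sy <- numeric(n)
  N <- 0L
  loglik <- 0
  m0 <- matrix(0, n, length(obs_list))
  P0 <- matrix(0, n, n)
  for (i in seq_along(obs_list)) {
    sm <- rts_smooth(model, obs_list[[i]])
    T <- nrow(sm$smooth_mean)
    M <- t(sm$smooth_mean)                     # n x T
    Psum_past <- rowSums(sm$smooth_cov[, , seq_len(T - 1), drop = FALSE],
                         dims = 2)
    Psum_next <- rowSums(sm$smooth_cov[, , 2:T, drop = FALSE], dims = 2)
    Csum <- rowSums(sm$cross_cov, dims = 2)
    Mp <- M[, seq_len(T - 1), drop = FALSE]
    Mn <- M[, 2:T, drop = FALSE]
    Exx_past <- Exx_past + Psum_past + tcrossprod(Mp)
    Exx_next <- Exx_next + Psum_next + tcrossprod(Mn)
    Eyx <- Eyx + Csum + tcrossprod(Mn, Mp)
    sx <- sx + rowSums(Mp)
    sy <- sy + rowSums(Mn)
    N <- N + (T - 1L)
    loglik <- loglik + sm$loglik
    m0[, i] <- M[, 1]
    P0 <- P0 + sm$smooth_cov[, , 1]
  }
  list(Exx_past = Exx_past, Exx_next = Exx_next, Eyx = Eyx,
       sx = sx, sy = sy, N = N, loglik = loglik,
       m0 = m0, P0 = P0 / length(obs_list))
}

# M-step: closed-form maximizers for unconstrained Gamma, mu, Sigma, nu0, Ups0
em_mstep <- function(s, order) {
  Phi <- rbind(cbind(s$Exx_past, s$sx), c(s$sx, s$N))
  Yx <- cbind(s$Eyx, s$sy)
  B <- Yx %*% solve(Phi + diag(1e-10, order + 1))
  Gamma <- B[, seq_len(order), drop = FALSE]
  mu_x <- B[, order + 1]
  Sigma <- (s$Exx_next - B %*% t(Yx)) / s$N
  Sigma <- (Sigma + t(Sigma)) / 2
  e <- eigen(Sigma, symmetric = TRUE)
  Sigma <- e$vectors %*% (t(e$vectors) * pmax(e$values, 1e-12))
  nu0 <- rowMeans(s$m0)
  D <- s$m0 - nu0
  Ups0 <- s$P0 + tcrossprod(D) / ncol(s$m0)
  Ups0 <- (Ups0 + t(Ups0)) / 2 + diag(1e-12, order)
  list(Gamma = Gamma, mu_x = mu_x, Sigma = Sigma, nu0 = nu0, Ups0 = Ups0)
}

#' @export
print.em_lds <- function(x, ...) {
  cat(sprintf(
    "<em_lds> order %d, best of %d restart(s) (#%d), loglik %.4g (%d iter)\n",
    x$order, x$n_restarts, x$restart, utils::tail(x$loglik_trace, 1),
    length(x$loglik_trace)))
  cat(sprintf("eigenvalue moduli of Gamma: %s\n",
              paste(signif(Mod(eigen(x$Gamma, only.values = TRUE)$values), 5),
                    collapse = ", ")))
  invisible(x)
}

#' @export
logLik.em_lds <- function(object, ...) {
  structure(utils::tail(object$loglik_trace, 1),
            class = "logLik", df = NA_integer_)
}

#' @export
coef.em_lds <- function(object, ...) {
  object[c("Gamma", "mu_x", "Sigma_x", "nu0", "Ups0")]
}

#' Regression-trained filter that ignores the controls
#'
#' The "best filter without efference copy": an order-2 model whose
#' transition matrix is learned by least squares of the true state at `t+1`
#' on the state at `t` (full access to the states), with the residual
#' covariance as process noise.  Because the regression cannot see the
#' control, the missing drive is absorbed into an overestimated
#' state-transition noise.  Filtering then uses the angle channel only.
#'
#' @param trajs list of trajectories (`theta` matrices) from
#'   [simulate_lds()] or [encode_dataset()].
#' @param wrapL angle wrap length for filtering.
#' @return object of classes `"obs_lds"` and `"lds_model"`.
#' @export
obs_fit <- function(trajs, wrapL = 2 * pi / 3) {
  X <- do.call(rbind, lapply(trajs, function(tr)
    tr$theta[-nrow(tr$theta), , drop = FALSE]))
  Y <- do.call(rbind, lapply(trajs, function(tr)
    tr$theta[-1, , drop = FALSE]))
  fit <- stats::lm.fit(cbind(X, 1), Y)
  B <- t(unname(fit$coefficients))
  A <- B[, 1:2]
  mu <- B[, 3]
  Sigma <- unname(crossprod(fit$residuals)) / nrow(X)
  th0 <- do.call(rbind, lapply(trajs, function(tr) tr$theta[1, ]))
  nu0 <- colMeans(th0)
  Ups0 <- stats::cov(th0) * (nrow(th0) - 1) / nrow(th0) + diag(1e-12, 2)
  out <- lds_model(A, mu, Sigma, nu0, Ups0, H = c(1, 0), wrapL = wrapL)
  class(out) <- c("obs_lds", "lds_model")
  out
}

#' Naive (dynamics-free) population decoding
#'
#' The PROP / EfCp benchmark: the center of mass of the current population
#' response at every time step, with no temporal pooling.  Optimal for data
#' with no temporal dependencies.
#'
#' @param code a [population_code()].
#' @param counts `T x n` response matrix.
#' @return estimate sequence (`NA` where the response is empty).
#' @export
naive_decode <- function(code, counts) {
  com_decode(code, counts)
}
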