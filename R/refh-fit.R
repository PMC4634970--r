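#' Simulate and encode a data set for training or testing
#'
#' Draws trajectories from the dynamical system and encodes the angle (and,
#' for controlled systems, the torque) as Poisson population responses, one
#' gain draw per population per time step.
#'
#' @param st an `"lds"` object (see [lds_preset()]).
#' @param T number of time steps per trajectory.
#' @param n_traj number of trajectories.
#' @param seed root seed; trajectory `i` uses derived streams for both the
#'   state noise and the spiking noise.
#' @param code_prop,code_efcp population codes; defaults build the standard
#'   15-unit codes over the feasible angle / torque ranges.
#' @param gain_range per-step uniform gain range.
#' @param fixed_gain if non-`NULL`, a single gain used at every time step of
#'   every trajectory (the reliability experiment fixes the gain per set).
#' @param noiseless if `TRUE`, responses are the Poisson means rather than
#'   samples.
#' @return list with `traj` (per-trajectory lists holding `theta`, `u`,
#'   `r_prop`, `gains_prop` and, when controlled, `r_efcp`, `gains_efcp`),
#'   plus the codes and the generating system.
#' @export
encode_dataset <- function(st, T, n_traj, seed = 1,
                           code_prop = population_code(15, st$angle_range),
                           code_efcp = if (st$controlled)
                             population_code(15, st$torque_range) else NULL,
                           gain_range = c(6.4, 9.6), fixed_gain = NULL,
                           noiseless = FALSE) {
  trajs <- simulate_lds(st, T, n_traj, seed = seed)
  out <- lapply(seq_len(n_traj), function(i) {
    tr <- trajs[[i]]
    set.seed(traj_seed(seed, 50000 + i))
    if (noiseless) {
      g <- rep_len(fixed_gain %||% mean(gain_range), T)
      tr$r_prop <- encode_noiseless(code_prop, tr$theta[, 1], g)
      tr$gains_prop <- g
      if (st$controlled) {
        tr$r_efcp <- encode_noiseless(code_efcp, tr$u, g)
        tr$gains_efcp <- g
      }
    } else {
      enc <- encode_pop(code_prop, tr$theta[, 1], gain_range,
                        gains = fixed_gain)
      tr$r_prop <- enc$counts
      tr$gains_prop <- enc$gains
      if (st$controlled) {
        enc_u <- encode_pop(code_efcp, tr$u, gain_range, gains = fixed_gain)
        tr$r_efcp <- enc_u$counts
        tr$gains_efcp <- enc_u$gains
      }
    }
    tr
  })
  list(traj = out, st = st, code_prop = code_prop, code_efcp = code_efcp)
}

#' Fit a recurrent exponential-family harmonium
#'
#' Trains the harmonium as an unsupervised density estimator on population
#' responses augmented with a one-step-delayed copy of its own hidden layer.
#' Each epoch presents `n_traj` trajectories of `T` usable time steps
#' (`n_traj * T` training vectors); the weight update at time `t` uses the
#' minibatch of all `n_traj` vectors at that time index, so there are `T`
#' CD-1 updates per epoch.  On the initial time step of every trajectory the
#' recurrent units are all zero and drive no weight change.  Fresh
#' trajectories are generated every `fresh_every` epochs, and the learning
#' rate decays across epochs according to `schedule` (see
#' [learning_rate()]).
#'
#' @param preset name of a shipped dynamical system (see [lds_preset()]),
#'   ignored when `st` is given.
#' @param n_hidden number of hidden units; the number of recurrent units is
#'   always equal to it.
#' @param epochs number of training epochs.
#' @param T usable time steps per trajectory (trajectories carry one extra
#'   initial step).
#' @param n_traj trajectories per data set (= minibatch size).
#' @param fresh_every regenerate the data set every this many epochs.
#' @param eps0,schedule,momentum,weight_decay,cd_final_means,rate_ceiling
#'   training hyperparameters; see [cd1_update()] and [learning_rate()].
#'   `schedule = NULL` selects exponential for uncontrolled systems and
#'   sigmoidal for controlled ones.
#' @param gain_range per-step uniform gain range of the encoders.
#' @param checkpoints integer vector of update (minibatch) counts at which a
#'   snapshot of the parameters is stored, e.g. `c(100, 200, 1000)` for
#'   emergence analyses.
#' @param seed root seed for initialization, data generation and sampling.
#' @param st optional `"lds"` object overriding `preset`.
#' @param train if `FALSE`, return the initialized but untrained network.
#' @param verbose print per-epoch progress?
#' @return an object of class `"refh"`.
#' @export
refh <- function(preset = "uncontrolled", n_hidden = 240, epochs = 120,
                 T = 1000, n_traj = 40, fresh_every = 5,
                 eps0 = 5e-4, schedule = NULL, momentum = 0.9,
                 weight_decay = 2e-4, cd_final_means = TRUE,
                 rate_ceiling = 40, gain_range = c(6.4, 9.6),
                 checkpoints = integer(0), seed = 1, st = NULL,
                 train = TRUE, verbose = FALSE) {
  st <- st %||% lds_preset(preset)
  schedule <- schedule %||% (if (st$controlled) "sigmoidal" else "exponential")
  code_prop <- population_code(15, st$angle_range)
  code_efcp <- if (st$controlled) population_code(15, st$torque_range)
  n_efcp <- if (st$controlled) code_efcp$n else 0L

  make_data <- function(refresh) {
    encode_dataset(st, T + 1, n_traj, seed = traj_seed(seed, 900000 + refresh),
                   code_prop = code_prop, code_efcp = code_efcp,
                   gain_range = gain_range)
  }
  data <- make_data(0)
  # arrays (units x traj x time) for fast minibatch slicing
  stack <- function(field, n_units) {
    a <- array(0, c(n_units, n_traj, T + 1))
    for (i in seq_len(n_traj)) a[, i, ] <- t(data$traj[[i]][[field]])
    a
  }
  Rp <- stack("r_prop", code_prop$n)
  Ru <- if (st$controlled) stack("r_efcp", code_efcp$n)

  set.seed(traj_seed(seed, 0))
  params <- refh_params_init(
    n_hidden, code_prop$n, n_efcp,
    mean_prop = rowMeans(Rp, dims = 1),
    mean_efcp = if (st$controlled) rowMeans(Ru, dims = 1) else 1)
  init_params <- params

  fit <- structure(list(
    params = params, init_params = init_params,
    st = st, code_prop = code_prop, code_efcp = code_efcp,
    config = list(n_hidden = n_hidden, epochs = epochs, T = T,
                  n_traj = n_traj, fresh_every = fresh_every, eps0 = eps0,
                  schedule = schedule, momentum = momentum,
                  weight_decay = weight_decay,
                  cd_final_means = cd_final_means,
                  rate_ceiling = rate_ceiling, gain_range = gain_range,
                  seed = seed, preset = st$preset %||% "custom"),
    checkpoints = list(), n_updates = 0L, trained = FALSE
  ), class = "refh")
  if (!train || epochs == 0 || eps0 == 0) {
    if (train && epochs > 0) fit$trained <- TRUE
    return(fit)
  }

  opt_state <- NULL
  n_updates <- 0L
  checkpoints <- sort(unique(as.integer(checkpoints)))
  snaps <- list()
  set.seed(traj_seed(seed, 1))
  for (k in seq_len(epochs) - 1L) {
    if (k > 0 && k %% fresh_every == 0) {
      data <- make_data(k %/% fresh_every)
      Rp <- stack("r_prop", code_prop$n)
      if (st$controlled) Ru <- stack("r_efcp", code_efcp$n)
    }
    lr <- learning_rate(k, eps0, schedule)
    z_prev <- up_pass(params, matrix(0, n_hidden, n_traj),
                      Rp[, , 1], if (st$controlled) Ru[, , 1],
                      sample = TRUE)$sample
    for (t in seq_len(T)) {
      res <- cd1_update(params, z_prev, Rp[, , t + 1],
                        if (st$controlled) Ru[, , t + 1],
                        opt_state, lr = lr, momentum = momentum,
                        weight_decay = weight_decay,
                        cd_final_means = cd_final_means,
                        rate_ceiling = rate_ceiling)
      params <- res$params
      opt_state <- res$opt_state
      z_prev <- res$sample
      n_updates <- n_updates + 1L
      if (length(checkpoints) && n_updates == checkpoints[1]) {
        snaps[[as.character(n_updates)]] <- params
        checkpoints <- checkpoints[-1]
      }
    }
    if (verbose)
      message(sprintf("epoch %d/%d (lr = %.3g, %d updates)",
                      k + 1, epochs, lr, n_updates))
  }
  fit$params <- params
  fit$checkpoints <- snaps
  fit$n_updates <- n_updates
  fit$trained <- TRUE
  fit
}

resolve_params <- function(object) {
  if (inherits(object, "refh")) object$params
  else if (inherits(object, "refh_params")) object
  else stop_invalid("expected a 'refh' fit or 'refh_params' object")
}

#' Deterministic forward filtering through the harmonium
#'
#' Runs the trained network over one trajectory of responses without any
#' sampling: at each step the hidden means are computed from the current
#' sensory responses and the *mean* recurrent vector from the previous step
#' (zeros at the first step).  Feeding means back is equivalent to averaging
#' many sampled runs and gives the network's maximum achievable performance.
#'
#' @param object a `"refh"` fit or `"refh_params"`.
#' @param r_prop `T x n_prop` response matrix.
#' @param r_efcp `T x n_efcp` response matrix for controlled networks.
#' @return `T x n_hidden` matrix of hidden firing probabilities.
#' @export
filter_forward <- function(object, r_prop, r_efcp = NULL) {
  params <- resolve_params(object)
  T <- nrow(r_prop)
  Z <- matrix(0, T, params$n_hidden)
  z <- numeric(params$n_hidden)
  for (t in seq_len(T)) {
    z <- drop(up_pass(params, z, r_prop[t, ],
                      if (params$n_efcp > 0) r_efcp[t, ])$means)
    Z[t, ] <- z
  }
  Z
}

#' Decode stimulus estimates from hidden activity
#'
#' The hidden representation is decoded by passing the real-valued hidden
#' vector back down through the network into the input space (down-pass
#' means, no sampling) and taking the circular center of mass of each
#' reconstructed hill of activity.
#'
#' @param object a `"refh"` fit (codes are taken from it) or
#'   `"refh_params"` (then supply `code_prop` / `code_efcp`).
#' @param Z `T x n_hidden` matrix of hidden firing probabilities.
#' @param code_prop,code_efcp population codes for the decode.
#' @param rate_ceiling clip for the reconstruction rates.
#' @return data frame with column `angle` and, for controlled networks,
#'   `torque`.
#' @export
decode_hidden <- function(object, Z, code_prop = NULL, code_efcp = NULL,
                          rate_ceiling = 40) {
  params <- resolve_params(object)
  if (inherits(object, "refh")) {
    code_prop <- code_prop %||% object$code_prop
    code_efcp <- code_efcp %||% object$code_efcp
  }
  dn <- down_pass(params, t(Z), sample = FALSE, rate_ceiling = rate_ceiling)
  out <- data.frame(angle = com_decode(code_prop, t(dn$prop_rates)))
  if (params$n_efcp > 0)
    out$torque <- com_decode(code_efcp, t(dn$efcp_rates))
  out
}

#' @export
print.refh <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<refh> %s harmonium (%s)\n",
              if (x$params$n_efcp > 0) "controlled" else "uncontrolled",
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  layers: %d hidden = %d recurrent, %d proprioceptive%s\n",
              x$params$n_hidden, x$params$n_hidden, x$params$n_prop,
              if (x$params$n_efcp > 0)
                sprintf(", %d efference-copy", x$params$n_efcp) else ""))
  cat(sprintf("  input width: %d\n",
              x$params$n_hidden + x$params$n_prop + x$params$n_efcp))
  cat(sprintf("  training: %d epochs x %d updates (%s schedule, eps0 = %g)\n",
              cfg$epochs, cfg$T, cfg$schedule, cfg$eps0))
  invisible(x)
}

#' @export
summary.refh <- function(object, ...) {
  print(object)
  w <- unlist(lapply(coef(object), as.vector))
  cat(sprintf("  %d parameters, |w|_max = %.3g, updates done: %d\n",
              length(w), max(abs(w)), object$n_updates))
  invisible(object)
}

#' @export
coef.refh <- function(object, ...) {
  p <- object$params
  p[c("W_fb", "W_prop", "W_efcp", "b_hid", "b_fb", "b_prop", "b_efcp")]
}

#' Filter new response data with a trained harmonium
#'
#' @param object a `"refh"` fit.
#' @param newdata either a data set from [encode_dataset()] (estimates are
#'   returned per trajectory) or a list with `r_prop` (and `r_efcp`).
#' @param type `"estimate"` for decoded stimulus estimates, `"hidden"` for
#'   the hidden trajectories, `"both"` for both.
#' @param ... unused.
#' @return for a single trajectory, a data frame of estimates (and/or the
#'   hidden matrix); for a data set, a list of them.
#' @export
predict.refh <- function(object, newdata,
                         type = c("estimate", "hidden", "both"), ...) {
  type <- match.arg(type)
  one <- function(tr) {
    Z <- filter_forward(object, tr$r_prop, tr$r_efcp)
    switch(type,
      hidden = Z,
      estimate = decode_hidden(object, Z),
      both = list(hidden = Z, estimate = decode_hidden(object, Z)))
  }
  if (!is.null(newdata$traj)) lapply(newdata$traj, one) else one(newdata)
}

#' @export
plot.refh <- function(x, which = c("W_prop", "W_fb"), ...) {
  which <- match.arg(which)
  W <- x$params[[which]]
  graphics::image(t(W), xlab = "input unit", ylab = "hidden unit",
                  main = which, useRaster = TRUE, ...)
  invisible(x)
}
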