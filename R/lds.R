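#' Physical parameters of the single-joint plant
#'
#' The tracked stimulus is the angle of a single rotational joint modelled as
#' a damped harmonic oscillator, \eqn{m\ddot\theta + c\dot\theta + k\theta = u},
#' discretized with an Euler step of length `dt`.
#'
#' @param m moment of inertia (J s^2 / rad^2), `m > 0`.
#' @param c viscous damping (J s / rad^2), `c >= 0`.
#' @param k spring stiffness (J / rad^2), `k >= 0`.
#' @param dt sampling interval in seconds, `dt > 0`.
#' @return an object of class `"oscillator_params"`.
#' @export
oscillator_params <- function(m = 5, c = 0.25, k = 3, dt = 0.05) {
  for (v in list(m = m, c = c, k = k, dt = dt)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_invalid("oscillator parameters must be finite scalars")
  }
  if (m <= 0) stop_invalid("moment of inertia m must be > 0")
  if (dt <= 0) stop_invalid("sampling interval dt must be > 0")
  if (c < 0 || k < 0) stop_invalid("damping c and stiffness k must be >= 0")
  structure(list(m = m, c = c, k = k, dt = dt), class = "oscillator_params")
}

#' Discrete-time state-transition model of the joint
#'
#' Builds the linear state-transition model for the (angle, angular velocity)
#' state: `A = [[1, dt], [-(k/m) dt, 1 - (c/m) dt]]`, control-input vector
#' `b = [0, dt/m]`, zero biases.  Optionally attaches first-order control
#' (torque) dynamics `u' = alpha u + noise`, which makes the combined system
#' third-order.
#'
#' @param p an [oscillator_params()] object.
#' @param Sigma_theta 2x2 state-noise covariance (or length-2 diagonal).
#' @param alpha control decay per step (`NULL` for an uncontrolled system).
#' @param sigma_u2 control-noise variance per step.
#' @param angle_range feasible joint range in radians.
#' @param torque_range feasible torque range in J/rad.
#' @param init_margin margin (rad) kept from the joint limits when drawing
#'   initial positions.
#' @param init_sd standard deviation of the initial velocity (and control).
#' @return an object of class `"lds"` holding `A`, `b`, the noise covariance,
#'   the control dynamics (if any), the initial distribution (`nu0`, `Ups0`,
#'   with an infinite variance on the position entry standing for the uniform
#'   initial-position draw) and the feasible ranges.
#' @export
oscillator_transition <- function(p, Sigma_theta = diag(c(5e-7, 5e-5)),
                                  alpha = NULL, sigma_u2 = NULL,
                                  angle_range = c(-pi / 3, pi / 3),
                                  torque_range = c(-1.25, 1.25),
                                  init_margin = 0.05, init_sd = 5e-5) {
  stopifnot(inherits(p, "oscillator_params"))
  if (is.vector(Sigma_theta) && length(Sigma_theta) == 2L)
    Sigma_theta <- diag(Sigma_theta)
  stopifnot(identical(dim(Sigma_theta), c(2L, 2L)))
  if (any(eigen(Sigma_theta, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop_invalid("Sigma_theta must be positive semi-definite")
  controlled <- !is.null(alpha)
  if (controlled && is.null(sigma_u2))
    stop_invalid("a controlled system needs sigma_u2")
  A <- matrix(c(1, -(p$k / p$m) * p$dt,
                p$dt, 1 - (p$c / p$m) * p$dt), 2, 2)
  b <- c(0, p$dt / p$m)
  nu0 <- if (controlled) c(0, 0, 0) else c(0, 0)
  ups0 <- if (controlled) c(Inf, init_sd^2, init_sd^2) else c(Inf, init_sd^2)
  structure(list(
    params = p, A = A, b = b, mu_theta = c(0, 0), Sigma_theta = Sigma_theta,
    controlled = controlled, alpha = alpha, mu_u = 0, sigma_u2 = sigma_u2,
    nu0 = nu0, Ups0 = diag(ups0),
    angle_range = angle_range, torque_range = torque_range,
    init_margin = init_margin, init_sd = init_sd, dt = p$dt
  ), class = "lds")
}

#' Augmented (state + control) linear dynamical system
#'
#' For a controlled plant the pair (state, control) is jointly an
#' *uncontrolled* third-order linear system: the control enters the velocity
#' row through `dt/m` and decays with `alpha` in its own row.  This is the
#' form in which the Kalman-filter benchmarks consume the controlled presets.
#'
#' @param st an `"lds"` object from [oscillator_transition()].
#' @return an object of class `"lds_aug"` with fields `Gamma` (n x n
#'   transition), `mu_x`, `Sigma_x`, `C` (row reading the angle out of the
#'   state), `h` (scalar reading the control), `nu0`, `Ups0`.
#' @export
augment_lds <- function(st) {
  stopifnot(inherits(st, "lds"))
  if (st$controlled) {
    Gamma <- rbind(cbind(st$A, st$b), c(0, 0, st$alpha))
    Sigma_x <- rbind(cbind(st$Sigma_theta, c(0, 0)), c(0, 0, st$sigma_u2))
    mu_x <- c(st$mu_theta, st$mu_u)
    C <- c(1, 0, 0); h <- c(0, 0, 1)
  } else {
    Gamma <- st$A
    Sigma_x <- st$Sigma_theta
    mu_x <- st$mu_theta
    C <- c(1, 0); h <- NULL
  }
  structure(list(
    Gamma = Gamma, mu_x = mu_x, Sigma_x = Sigma_x, C = C, h = h,
    nu0 = st$nu0, Ups0 = st$Ups0, order = nrow(Gamma),
    angle_range = st$angle_range, torque_range = st$torque_range,
    dt = st$dt, controlled = st$controlled
  ), class = "lds_aug")
}

#' Named dynamical-system presets
#'
#' Shipped parameterizations of the plant:
#' \describe{
#'   \item{`"uncontrolled"`}{underdamped oscillator, m = 5, c = 0.25, k = 3,
#'     dt = 0.05 s, state noise `diag(c(5e-7, 5e-5))`, no torque input.}
#'   \item{`"controlled"`}{same oscillator driven by a near-random-walk torque
#'     (`alpha` = 0.9994, `sigma_u2` = 7.5e-4), state noise
#'     `diag(c(5e-5, 1e-6))`.}
#'   \item{`"no_spring"`}{stiffness set to zero and state noise scaled up by
#'     50, used for receptive-field analyses where full coverage of
#'     position-velocity space is wanted.}
#'   \item{`"sweep_stiffness"`, `"sweep_damping"`, `"sweep_inertia"`}{twelve
#'     variants of the uncontrolled oscillator with k, c or m multiplied by
#'     log-spaced factors in \[1/4, 4\]; `index` in 1..12 selects one.}
#'   \item{`"damping_variants"`}{the no-spring system with
#'     c = 0.25 x (1/4, 1/2, 1, 2, 4); `index` in 1..5.}
#' }
#'
#' @param name preset name.
#' @param index variant index for the sweep presets.
#' @return an `"lds"` object.
#' @export
lds_preset <- function(name = c("uncontrolled", "controlled", "no_spring",
                                "sweep_stiffness", "sweep_damping",
                                "sweep_inertia", "damping_variants"),
                       index = NULL) {
  name <- match.arg(name)
  sweep_mult <- exp(seq(log(1 / 4), log(4), length.out = 12))
  pick <- function(nmax) {
    if (is.null(index) || index < 1 || index > nmax)
      stop_invalid("preset '%s' needs an index in 1..%d", name, nmax)
    index
  }
  st <- switch(name,
    uncontrolled = oscillator_transition(oscillator_params()),
    controlled = oscillator_transition(
      oscillator_params(), Sigma_theta = diag(c(5e-5, 1e-6)),
      alpha = 0.9994, sigma_u2 = 7.5e-4),
    no_spring = oscillator_transition(
      oscillator_params(k = 0), Sigma_theta = 50 * diag(c(5e-7, 5e-5))),
    sweep_stiffness = oscillator_transition(
      oscillator_params(k = 3 * sweep_mult[pick(12)])),
    sweep_damping = oscillator_transition(
      oscillator_params(c = 0.25 * sweep_mult[pick(12)])),
    sweep_inertia = oscillator_transition(
      oscillator_params(m = 5 * sweep_mult[pick(12)])),
    damping_variants = oscillator_transition(
      oscillator_params(k = 0, c = 0.25 * c(1 / 4, 1 / 2, 1, 2, 4)[pick(5)]),
      Sigma_theta = 50 * diag(c(5e-7, 5e-5)))
  )
  st$preset <- name
  st$preset_index <- index
  st
}

#' @export
print.lds <- function(x, ...) {
  cat(sprintf("<lds> %s system (dt = %g s)\n",
              if (x$controlled) "controlled" else "uncontrolled", x$dt))
  cat("A =\n"); print(x$A)
  if (x$controlled)
    cat(sprintf("control: alpha = %g, sigma_u2 = %g\n", x$alpha, x$sigma_u2))
  invisible(x)
}

#' Simulate joint (and torque) trajectories
#'
#' Draws `n_traj` trajectories of `T` steps from the model.  The initial angle
#' is uniform over the feasible range up to `init_margin` from the limits; the
#' initial velocity (and control, if any) are Gaussian with standard deviation
#' `init_sd`.  States are never clipped: the dynamics are stable but the noise
#' is unbounded, so trajectories may leave the feasible range (the population
#' codes wrap them when encoding).
#'
#' @param st an `"lds"` object.
#' @param T number of steps (`T >= 1`).
#' @param n_traj number of trajectories.
#' @param seed root seed; trajectory `i` uses the derived stream `(seed, i)`,
#'   so earlier trajectories are unchanged when `n_traj` grows.
#' @return a list of trajectories, each a list with `theta` (`T x 2` matrix of
#'   angle and angular velocity) and `u` (length-`T` torque, or `NULL`).
#' @export
simulate_lds <- function(st, T, n_traj = 1, seed = 1) {
  stopifnot(inherits(st, "lds"), T >= 1)
  lo <- st$angle_range[1] + st$init_margin
  hi <- st$angle_range[2] - st$init_margin
  R <- chol_psd(st$Sigma_theta)
  lapply(seq_len(n_traj), function(i) {
    set.seed(traj_seed(seed, i))
    th <- matrix(0, T, 2)
    th[1, ] <- c(stats::runif(1, lo, hi), stats::rnorm(1, 0, st$init_sd))
    # state-noise draws come before any control draws, so a controlled run
    # with sigma_u2 = 0 reproduces the uncontrolled trajectory bit for bit
    eps <- if (T > 1) matrix(stats::rnorm(2 * (T - 1)), T - 1, 2) %*% R
    u <- NULL
    if (st$controlled) {
      u <- numeric(T)
      u[1] <- stats::rnorm(1, 0, st$init_sd)
      eta <- stats::rnorm(T - 1, 0, sqrt(st$sigma_u2))
    }
    if (T > 1) {
      for (t in seq_len(T - 1)) {
        drive <- if (st$controlled) st$b * u[t] else 0
        th[t + 1, ] <- drop(st$A %*% th[t, ]) + drive + st$mu_theta + eps[t, ]
        if (st$controlled) u[t + 1] <- st$alpha * u[t] + st$mu_u + eta[t]
      }
    }
    list(theta = th, u = u)
  })
}

#' @rdname simulate_lds
#' @param object,nsim,... for the [stats::simulate()] method: the model, the
#'   number of trajectories, and further arguments (`T`) passed on.
#' @export
simulate.lds <- function(object, nsim = 1, seed = 1, T = 1000, ...) {
  simulate_lds(object, T = T, n_traj = nsim, seed = seed)
}

# upper-triangular factor that also accepts semi-definite matrices
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Spectral radius of a transition matrix
#'
#' @param A square matrix (or an `"lds"` / `"lds_aug"` object, in which case
#'   its transition matrix is used).
#' @return the largest eigenvalue modulus.
#' @export
spectral_radius <- function(A) {
  if (inherits(A, "lds")) A <- A$A
  if (inherits(A, "lds_aug")) A <- A$Gamma
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Hankel singular values of a noise-driven preset
#'
#' Treats the state noise as the input (input matrix = a square root of the
#' process-noise covariance) and the joint angle as the output, and returns
#' the Hankel singular values of the resulting state-space system.  Values
#' within one order of magnitude of each other indicate that no state mode is
#' negligible, i.e. that the system is "truly" of its nominal order.
#'
#' @param st an `"lds"` or `"lds_aug"` object.
#' @return numeric vector of Hankel singular values, decreasing.
#' @export
hankel_singular_values <- function(st) {
  ag <- if (inherits(st, "lds_aug")) st else augment_lds(st)
  A <- ag$Gamma
  B <- chol_psd(ag$Sigma_x)  # input matrix: unit white noise -> state noise
  C <- matrix(ag$C, 1)
  n <- nrow(A)
  # discrete Lyapunov equations via Kronecker solve (n <= 3)
  lyap <- function(A, Q) {
    matrix(solve(diag(n * n) - kronecker(A, A), as.vector(Q)), n, n)
  }
  P <- lyap(A, t(B) %*% B)          # controllability Gramian (B rows = noise)
  Q <- lyap(t(A), t(C) %*% C)       # observability Gramian
  ev <- eigen(P %*% Q, only.values = TRUE)$values
  sort(sqrt(pmax(Re(ev), 0)), decreasing = TRUE)
}
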