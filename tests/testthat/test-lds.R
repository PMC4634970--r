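test_that("discretized oscillator matrices match the closed form", {
  st <- oscillator_transition(oscillator_params(m = 5, c = 0.25, k = 3,
                                                dt = 0.05))
  expect_equal(st$A, matrix(c(1, -0.03, 0.05, 0.9975), 2, 2))
  expect_equal(st$b, c(0, 0.01))
  expect_equal(st$mu_theta, c(0, 0))
  # vanishing step: A -> identity, b -> 0
  st0 <- oscillator_transition(oscillator_params(dt = 1e-12))
  expect_equal(st0$A, diag(2), tolerance = 1e-10)
  expect_equal(st0$b, c(0, 0), tolerance = 1e-10)
  # invalid physical parameters are rejected
  expect_error(oscillator_params(m = 0), "moment of inertia")
  expect_error(oscillator_params(dt = -1), "sampling interval")
  expect_error(oscillator_params(m = NaN), "finite")
})

test_that("base oscillator is stable and underdamped", {
  st <- lds_preset("uncontrolled")
  ev <- eigen(st$A, only.values = TRUE)$values
  expect_true(all(Im(ev) != 0))                 # complex-conjugate pair
  expect_equal(Mod(ev), rep(sqrt(det(st$A)), 2))
  expect_equal(Mod(ev)[1], sqrt(0.999), tolerance = 1e-12)
  expect_lt(spectral_radius(st), 1)
})

test_that("augmented controlled system has the third-order block structure", {
  ag <- augment_lds(lds_preset("controlled"))
  expect_equal(ag$order, 3L)
  expect_equal(ag$Gamma,
               matrix(c(1, -0.03, 0, 0.05, 0.9975, 0, 0, 0.01, 0.9994),
                      3, 3))
  expect_equal(ag$Sigma_x, diag(c(5e-5, 1e-6, 7.5e-4)))
  expect_equal(ag$C, c(1, 0, 0))
  expect_equal(ag$h, c(0, 0, 1))
  # uncontrolled: order 2, no control row
  ag2 <- augment_lds(lds_preset("uncontrolled"))
  expect_equal(ag2$order, 2L)
  expect_null(ag2$h)
})

test_that("shipped presets carry the printed parameterizations", {
  un <- lds_preset("uncontrolled")
  expect_equal(un$params[c("m", "c", "k", "dt")],
               list(m = 5, c = 0.25, k = 3, dt = 0.05))
  expect_equal(un$Sigma_theta, diag(c(5e-7, 5e-5)))
  expect_equal(un$angle_range, c(-pi / 3, pi / 3))
  expect_equal(un$init_margin, 0.05)

  ns <- lds_preset("no_spring")
  expect_equal(ns$params$k, 0)
  expect_equal(ns$Sigma_theta, 50 * diag(c(5e-7, 5e-5)))

  co <- lds_preset("controlled")
  expect_equal(co$alpha, 0.9994)
  expect_equal(co$sigma_u2, 7.5e-4)
  expect_equal(co$torque_range, c(-1.25, 1.25))

  dv <- lds_preset("damping_variants", 1)
  expect_equal(dv$params$c, 0.25 / 4)
  expect_equal(dv$params$k, 0)

  # sweep grids: 12 log-spaced multipliers spanning [1/4, 4] of the base
  ks <- vapply(1:12, function(i) lds_preset("sweep_stiffness", i)$params$k,
               numeric(1))
  expect_equal(length(unique(ks)), 12L)
  expect_equal(range(ks / 3), c(1 / 4, 4))
  expect_error(lds_preset("sweep_damping"), "index")
  expect_error(lds_preset("bogus"))
})

test_that("preset stability follows the discretization's c > k dt criterion", {
  # the Euler-style discretization of the underdamped oscillator has
  # det(A) = 1 + dt (k dt - c) / m: strictly stable iff c > k dt, so the
  # extreme ends of the stiffness and damping sweeps drift marginally
  # (bounded on the encoding circle by the wrap), exactly as the printed
  # matrices dictate
  sweeps <- c(lapply(c("uncontrolled", "controlled"), lds_preset),
              lapply(1:12, function(i) lds_preset("sweep_stiffness", i)),
              lapply(1:12, function(i) lds_preset("sweep_damping", i)),
              lapply(1:12, function(i) lds_preset("sweep_inertia", i)))
  for (st in sweeps) {
    p <- st$params
    sr <- spectral_radius(st)
    expect_equal(sr, sqrt(abs(det(st$A))), tolerance = 1e-9)
    if (p$c > p$k * p$dt) {
      expect_lt(sr, 1)
      expect_lt(spectral_radius(augment_lds(st)), 1)
    } else {
      expect_gte(sr, 1)
      expect_lt(sr, 1.0025)              # drift per step stays tiny
    }
  }
  marginal <- c(list(lds_preset("no_spring")),
                lapply(1:5, function(i) lds_preset("damping_variants", i)))
  for (st in marginal) {
    ev <- sort(Mod(eigen(st$A, only.values = TRUE)$values))
    expect_equal(ev[2], 1)               # position integrates
    expect_lt(ev[1], 1)                  # velocity still decays
  }
})

test_that("Hankel singular values are within one order of magnitude", {
  for (nm in c("uncontrolled", "controlled")) {
    h <- hankel_singular_values(lds_preset(nm))
    expect_lte(max(h) / min(h), 10)
  }
})

test_that("noiseless undriven point mass stays put", {
  st <- oscillator_transition(oscillator_params(c = 0, k = 0),
                              Sigma_theta = matrix(0, 2, 2), init_sd = 0)
  tr <- simulate_lds(st, 50, 1, seed = 3)[[1]]
  expect_equal(tr$theta[, 1], rep(tr$theta[1, 1], 50))
  expect_equal(tr$theta[, 2], rep(0, 50))
})

test_that("one-step residual covariance matches the generating noise", {
  st <- lds_preset("uncontrolled")
  trs <- simulate_lds(st, 1000, 200, seed = 12)
  res <- do.call(rbind, lapply(trs, function(tr) {
    tr$theta[-1, ] - tr$theta[-nrow(tr$theta), ] %*% t(st$A)
  }))
  n <- nrow(res)
  S <- crossprod(res) / n
  truth <- st$Sigma_theta
  for (i in 1:2) {
    se <- truth[i, i] * sqrt(2 / n)
    expect_lt(abs(S[i, i] - truth[i, i]), 3 * se)
  }
  expect_lt(abs(S[1, 2]), 3 * sqrt(truth[1, 1] * truth[2, 2] / n))
})

test_that("zero control noise reduces to the uncontrolled system", {
  p <- oscillator_params()
  S <- diag(c(5e-7, 5e-5))
  stc <- oscillator_transition(p, S, alpha = 0.9994, sigma_u2 = 0,
                               init_sd = 0)
  stu <- oscillator_transition(p, S, init_sd = 0)
  a <- simulate_lds(stc, 300, 2, seed = 9)
  b <- simulate_lds(stu, 300, 2, seed = 9)
  expect_true(all(a[[1]]$u == 0))
  expect_identical(a[[1]]$theta, b[[1]]$theta)
  expect_identical(a[[2]]$theta, b[[2]]$theta)
})

test_that("simulation is seed-deterministic with per-trajectory streams", {
  st <- lds_preset("uncontrolled")
  a <- simulate_lds(st, 200, 3, seed = 5)
  b <- simulate_lds(st, 200, 3, seed = 5)
  expect_identical(a, b)
  # growing n_traj leaves earlier trajectories untouched
  c5 <- simulate_lds(st, 200, 5, seed = 5)
  expect_identical(a, c5[1:3])
  # initial conditions respect the margin and tight velocity prior
  th0 <- vapply(simulate_lds(st, 1, 500, seed = 8),
                function(tr) tr$theta[1, 1], numeric(1))
  expect_true(all(th0 >= -pi / 3 + 0.05 & th0 <= pi / 3 - 0.05))
  om0 <- vapply(simulate_lds(st, 1, 500, seed = 8),
                function(tr) tr$theta[1, 2], numeric(1))
  expect_lt(max(abs(om0)), 5 * 5e-5)
})
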