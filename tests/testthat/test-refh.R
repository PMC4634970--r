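zero_params <- function(nh = 4, np = 3, ne = 0) {
  p <- refh_params_init(nh, np, ne, w_sd = 0)
  p$b_prop <- numeric(np)
  if (ne > 0) p$b_efcp <- numeric(ne)
  p
}

test_that("up pass is the logistic of the weighted inputs", {
  p <- zero_params()
  up <- up_pass(p, numeric(4), c(1, 2, 3))
  expect_equal(drop(up$means), rep(0.5, 4))
  # bias ln 3 -> mean 3/4
  p$b_hid <- rep(log(3), 4)
  expect_equal(drop(up_pass(p, numeric(4), c(5, 0, 1))$means), rep(0.75, 4))
  # pre-activation is linear in the counts: adding to one input moves the
  # logit by exactly the corresponding weight entry
  set.seed(1)
  p2 <- refh_params_init(4, 3, w_sd = 0.5)
  r <- c(2, 1, 0)
  a1 <- up_pass(p2, numeric(4), r)$means
  r2 <- r; r2[2] <- r2[2] + 2
  a2 <- up_pass(p2, numeric(4), r2)$means
  logit <- function(x) log(x / (1 - x))
  expect_equal(logit(drop(a2)) - logit(drop(a1)), 2 * p2$W_prop[, 2])
  expect_error(up_pass(p2, numeric(4), c(1, 2)), "dimension mismatch")
})

test_that("down pass produces logistic means and clipped Poisson rates", {
  p <- zero_params(4, 3)
  dn <- down_pass(p, rep(0.5, 4))
  expect_equal(drop(dn$fb_means), rep(0.5, 4))
  expect_equal(drop(dn$prop_rates), rep(1, 3))   # exp(0)
  p$b_prop <- rep(log(8), 3)
  expect_equal(drop(down_pass(p, numeric(4))$prop_rates), rep(8, 3))
  # rate ceiling bounds the reconstruction
  p$b_prop <- rep(10, 3)
  expect_equal(drop(down_pass(p, numeric(4))$prop_rates), rep(40, 3))
  # zero-weight composition: down then up leaves hidden means at 1/2
  p0 <- zero_params(4, 3)
  dn0 <- down_pass(p0, c(0.9, 0.1, 0.5, 0.2), sample = TRUE)
  expect_equal(drop(up_pass(p0, dn0$fb_sample, dn0$prop_sample)$means),
               rep(0.5, 4))
})

test_that("CD-1 raw gradients replay the four pass stages exactly", {
  set.seed(3)
  p <- refh_params_init(1, 2, w_sd = 0.3)
  z_prev <- matrix(c(1, 0, 1), 1)           # batch of 3
  r <- matrix(rpois(6, 4), 2, 3)
  seed <- 99
  set.seed(seed)
  out <- cd1_update(p, z_prev, r, lr = 0, momentum = 0, weight_decay = 0)
  # independent scripted enumeration with the shared RNG stream
  set.seed(seed)
  sig <- function(x) 1 / (1 + exp(-x))
  m1 <- sig(p$W_fb %*% z_prev + p$W_prop %*% r + p$b_hid)
  z <- matrix(as.numeric(runif(length(m1)) < m1), nrow(m1), ncol(m1))
  fbm <- sig(crossprod(p$W_fb, z) + p$b_fb)
  rates <- pmin(exp(crossprod(p$W_prop, z) + p$b_prop), 40)
  yfb <- matrix(as.numeric(runif(length(fbm)) < fbm), nrow(fbm), ncol(fbm))
  yp <- matrix(rpois(length(rates), rates), nrow(rates), ncol(rates))
  zh <- sig(p$W_fb %*% yfb + p$W_prop %*% yp + p$b_hid)
  B <- 3
  expect_equal(out$grads$W_prop,
               (tcrossprod(z, r) - tcrossprod(zh, yp)) / B)
  expect_equal(out$grads$W_fb,
               (tcrossprod(z, z_prev) - tcrossprod(zh, yfb)) / B)
  expect_equal(out$grads$b_hid, rowMeans(z - zh))
  expect_equal(out$grads$b_prop, rowMeans(r - yp))
  expect_equal(out$grads$b_fb, rowMeans(z_prev - yfb))
  expect_equal(out$sample, z)
})

test_that("plain CD-1 step adds lr times the raw gradient", {
  set.seed(5)
  p <- refh_params_init(3, 4, w_sd = 0.2)
  z_prev <- matrix(rbinom(6, 1, 0.5), 3, 2)
  r <- matrix(rpois(8, 3), 4, 2)
  out <- cd1_update(p, z_prev, r, lr = 0.1, momentum = 0, weight_decay = 0)
  expect_equal(out$params$W_prop, p$W_prop + 0.1 * out$grads$W_prop)
  expect_equal(out$params$b_hid, p$b_hid + 0.1 * out$grads$b_hid)
  # weight decay shrinks weights but not biases
  set.seed(5)
  out2 <- cd1_update(p, z_prev, r, lr = 0.1, momentum = 0,
                     weight_decay = 0.5)
  expect_equal(out2$params$W_prop,
               p$W_prop + 0.1 * (out2$grads$W_prop - 0.5 * p$W_prop))
  expect_equal(out2$params$b_hid, p$b_hid + 0.1 * out2$grads$b_hid)
})

test_that("CD-1 gradients vanish in expectation at the model distribution", {
  # with all-zero weights the harmonium factorizes, so data drawn from the
  # factorized marginals sit at a fixed point of the learning rule
  p <- zero_params(2, 2)
  p$b_hid <- c(0.4, -0.3)
  p$b_fb <- c(-0.2, 0.1)
  p$b_prop <- log(c(3, 5))
  set.seed(11)
  B <- 40
  n_batch <- 1500
  acc <- NULL
  for (i in seq_len(n_batch)) {
    z_prev <- matrix(rbinom(2 * B, 1, rep(plogis(p$b_fb), B)), 2)
    r <- matrix(rpois(2 * B, rep(exp(p$b_prop), B)), 2)
    g <- cd1_update(p, z_prev, r, lr = 0)$grads
    v <- c(g$W_fb, g$W_prop, g$b_hid, g$b_fb, g$b_prop)
    acc <- rbind(acc, v)
  }
  m <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(n_batch)
  expect_true(all(abs(m) < 3.5 * pmax(se, 1e-12)))
})

test_that("learning-rate schedules follow the printed reciprocal forms", {
  e0 <- 5e-4
  expect_equal(learning_rate(0, e0), e0)
  expect_equal(learning_rate(1, e0), e0 / 1.1)
  expect_equal(learning_rate(10, e0), e0 / 1.1^10)
  k <- 0:60
  for (sch in c("exponential", "sigmoidal")) {
    eps <- learning_rate(k, e0, sch)
    expect_true(all(diff(eps) < 0))
  }
  expect_equal(learning_rate(20, e0, "sigmoidal"),
               e0 / (1000 / (1 + exp(-20 / 8 + 7.5)) + 12))
})

test_that("training accounting matches the epoch structure", {
  fit <- refh(n_hidden = 8, epochs = 2, T = 25, n_traj = 6, seed = 2,
              checkpoints = c(10, 30))
  expect_equal(fit$n_updates, 50L)              # T updates per epoch
  expect_named(fit$checkpoints, c("10", "30"))
  expect_equal(fit$config$n_traj * fit$config$T, 150)
  # zero learning rate: parameters stay at their initialization
  f0 <- refh(n_hidden = 8, epochs = 2, T = 25, n_traj = 6, seed = 2,
             eps0 = 0)
  expect_identical(f0$params, f0$init_params)
})

test_that("deterministic filtering is reproducible and sample-free", {
  fit <- get_unctrl_fit(1)
  tr <- get_unctrl_test()$traj[[1]]
  Z1 <- filter_forward(fit, tr$r_prop)
  Z2 <- filter_forward(fit, tr$r_prop)
  expect_identical(Z1, Z2)
  expect_true(all(Z1 >= 0 & Z1 <= 1))
  # zero-weight parameters pin every hidden mean at 1/2
  p0 <- zero_params(5, 15)
  Z0 <- filter_forward(p0, tr$r_prop[1:20, ])
  expect_equal(Z0, matrix(0.5, 20, 5))
})

test_that("temporal information flows through the recurrent pathway", {
  fit <- get_nospring_fit(11)
  tr <- encode_dataset(lds_preset("no_spring"), 60, 1, seed = 31)$traj[[1]]
  Z <- filter_forward(fit, tr$r_prop)
  t_probe <- 50
  for (k in 1:3) {
    r2 <- tr$r_prop
    r2[t_probe - k, ] <- r2[t_probe - k, ] + 5   # perturb a past response
    Z2 <- filter_forward(fit, r2)
    expect_gt(max(abs(Z2[t_probe, ] - Z[t_probe, ])), 1e-6)
  }
})

test_that("decoding the hidden layer reproduces a constructed code", {
  # hidden unit j writes the log mean-count profile of stimulus xi_j into
  # its outgoing sensory weights, so a one-hot hidden vector must decode to
  # exactly xi_j
  code <- population_code()
  p <- refh_params_init(15, 15, w_sd = 0)
  p$b_prop <- rep(0, 15)
  p$W_prop <- t(vapply(seq_len(15), function(j)
    log(tuning_mean(code, code$xi[j], 8)), numeric(15)))
  for (j in c(1, 7, 15)) {
    z <- numeric(15); z[j] <- 1
    dec <- decode_hidden(p, matrix(z, 1), code_prop = code)
    expect_lt(abs(dec$angle - code$xi[j]), 1e-9)
  }
  # all-zero hidden vector with calibrated biases decodes the mean profile
  p$b_prop <- log(tuning_mean(code, 0.1, 8))
  dec0 <- decode_hidden(p, matrix(0, 1, 15), code_prop = code)
  expect_lt(abs(dec0$angle - 0.1), 1e-6)
})

test_that("training improves filtering over the untrained network and PROP", {
  wins <- vapply(1:3, function(sd) {
    fit <- get_unctrl_fit(sd)
    un <- get_unctrl_untrained(sd)
    test <- get_unctrl_test()
    truth <- lapply(test$traj, function(tr) tr$theta[, 1])
    L <- test$code_prop$L
    m_fit <- error_stats(estimator_refh(fit)(test), truth, L)$mse
    m_un <- error_stats(estimator_refh(un)(test), truth, L)$mse
    m_prop <- error_stats(estimator_naive(test$code_prop)(test), truth,
                          L)$mse
    (m_fit < m_un) && (m_fit < m_prop)
  }, logical(1))
  expect_gte(sum(wins), 2)
})

test_that("lag tuning emerges gradually across training checkpoints", {
  # position tuning appears first (lag ~ 0); deeper lags need the recurrent
  # pathway to start feeding learned position information back
  ok <- vapply(c(11, 12, 13), function(sd) {
    mean_abs_lag <- get_emergence(sd)
    all(diff(mean_abs_lag) >= 0)
  }, logical(1))
  expect_gte(sum(ok), 2)
})
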