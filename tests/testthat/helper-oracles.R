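# Independent oracles, written before and kept independent of the package
# implementations they check.

# Plain-R textbook Kalman filter (covariance form, joint vector update),
# finite priors only.  Used as the independent cross-check for kf_filter.
textbook_kf <- function(A, mu, Q, nu0, P0, H, y, v) {
  Tn <- nrow(y)
  n <- nrow(A)
  means <- matrix(NA_real_, Tn, n)
  covs <- array(NA_real_, c(n, n, Tn))
  m <- nu0
  P <- P0
  for (t in seq_len(Tn)) {
    if (t > 1) {
      m <- drop(A %*% m) + mu
      P <- A %*% P %*% t(A) + Q
    }
    obs <- which(is.finite(y[t, ]) & is.finite(v[t, ]))
    if (length(obs)) {
      Ht <- H[obs, , drop = FALSE]
      Rt <- diag(v[t, obs], length(obs))
      S <- Ht %*% P %*% t(Ht) + Rt
      K <- P %*% t(Ht) %*% solve(S)
      m <- m + drop(K %*% (y[t, obs] - Ht %*% m))
      P <- P - K %*% Ht %*% P
    }
    means[t, ] <- m
    covs[, , t] <- (P + t(P)) / 2
  }
  list(mean = means, cov = covs)
}

# Brute-force double-loop plug-in MI (bits) over an explicit joint histogram
brute_mi <- function(bins, response, n_levels = max(bins)) {
  Tn <- length(bins)
  mi <- 0
  for (b in seq_len(n_levels)) {
    for (r in 0:1) {
      pj <- sum((bins == b) * (if (r == 1) response else 1 - response)) / Tn
      pb <- mean(bins == b)
      pr <- if (r == 1) mean(response) else 1 - mean(response)
      if (pj > 0) mi <- mi + pj * log2(pj / (pb * pr))
    }
  }
  mi
}

# Brute-force grid-integration posterior for the uncontrolled plant:
# propagates a discretized joint density over (angle, velocity) through the
# linear-Gaussian dynamics and multiplies in the *exact* Poisson likelihood
# of the spike counts at each step.  Returns posterior mean angle per step.
grid_posterior_oracle <- function(counts, g, code, A, Sig, th_grid, om_grid,
                                  om_sd0) {
  nth <- length(th_grid)
  nom <- length(om_grid)
  Tn <- nrow(counts)
  # prior: flat over angle (locally diffuse), Gaussian over velocity
  P <- outer(rep(1, nth), stats::dnorm(om_grid, 0, om_sd0))
  P <- P / sum(P)
  # transition kernels against all (angle, velocity) source cells
  src_th <- rep(th_grid, times = nom)
  src_om <- rep(om_grid, each = nth)
  mu_th <- A[1, 1] * src_th + A[1, 2] * src_om
  mu_om <- A[2, 1] * src_th + A[2, 2] * src_om
  T1 <- stats::dnorm(outer(th_grid, mu_th, "-"), 0, sqrt(Sig[1, 1]))
  T2 <- stats::dnorm(outer(om_grid, mu_om, "-"), 0, sqrt(Sig[2, 2]))
  # exact Poisson log-likelihood of each count vector on the angle grid
  FY <- t(sapply(th_grid, function(th) tuning_mean(code, th, 1)))  # nth x N
  means_out <- numeric(Tn)
  for (t in seq_len(Tn)) {
    if (t > 1) {
      w <- as.vector(P)
      Pn <- matrix(0, nth, nom)
      for (j in seq_len(nom)) Pn[, j] <- T1 %*% (w * T2[j, ])
      P <- Pn
    }
    ll <- drop(log(FY) %*% counts[t, ]) - g * rowSums(FY)
    lik <- exp(ll - max(ll))
    P <- P * as.vector(lik)
    P <- P / sum(P)
    means_out[t] <- sum(th_grid * rowSums(P))
  }
  means_out
}
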