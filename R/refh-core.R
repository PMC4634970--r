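# Core conditional distributions and the CD-1 update of the recurrent
# exponential-family harmonium.  Layer conventions: hidden and recurrent
# units are Bernoulli, sensory populations are Poisson.  All passes accept a
# minibatch as a matrix with one column per case.

#' Initialize harmonium parameters
#'
#' Weights are drawn from a zero-mean Gaussian with standard deviation
#' `w_sd`; hidden and recurrent biases start at zero; the Poisson biases
#' start at the log of the mean training count per unit so that the initial
#' reconstruction rates are calibrated and do not blow up early in training.
#'
#' @param n_hidden number of hidden units (= number of recurrent units).
#' @param n_prop number of proprioceptive (angle-coding) units.
#' @param n_efcp number of efference-copy units, 0 for uncontrolled systems.
#' @param mean_prop,mean_efcp mean training spike count per unit (scalar or
#'   per-unit vector) used to set the Poisson biases.
#' @param w_sd initialization standard deviation for all weights.
#' @return an object of class `"refh_params"`.
#' @export
refh_params_init <- function(n_hidden, n_prop, n_efcp = 0,
                             mean_prop = 1, mean_efcp = 1, w_sd = 0.01) {
  rmat <- function(r, c) matrix(stats::rnorm(r * c, 0, w_sd), r, c)
  p <- list(
    W_fb = rmat(n_hidden, n_hidden),
    W_prop = rmat(n_hidden, n_prop),
    W_efcp = if (n_efcp > 0) rmat(n_hidden, n_efcp) else NULL,
    b_hid = numeric(n_hidden),
    b_fb = numeric(n_hidden),
    b_prop = rep_len(log(pmax(mean_prop, 1e-3)), n_prop),
    b_efcp = if (n_efcp > 0) rep_len(log(pmax(mean_efcp, 1e-3)), n_efcp)
             else NULL,
    n_hidden = as.integer(n_hidden), n_prop = as.integer(n_prop),
    n_efcp = as.integer(n_efcp)
  )
  structure(p, class = "refh_params")
}

as_batch <- function(x, nrow) {
  if (is.null(x)) return(NULL)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != nrow) stop_invalid("dimension mismatch: expected %d rows, got %d",
                                    nrow, nrow(x))
  x
}

#' Up pass: hidden means (and samples) given the inputs
#'
#' The hidden pre-activation is the weighted sum of the recurrent activity,
#' the sensory spike counts and the hidden bias; the mean is its logistic.
#'
#' @param params a `"refh_params"` object.
#' @param z_prev recurrent input, `n_hidden` vector or `n_hidden x B` matrix
#'   (binary during training, real-valued means during testing).
#' @param r_prop proprioceptive counts, `n_prop x B`.
#' @param r_efcp efference-copy counts, `n_efcp x B` (or `NULL`).
#' @param sample draw Bernoulli samples as well?
#' @return list with `means` (in `[0, 1]`) and, if requested, `sample`.
#' @export
up_pass <- function(params, z_prev, r_prop, r_efcp = NULL, sample = FALSE) {
  z_prev <- as_batch(z_prev, params$n_hidden)
  r_prop <- as_batch(r_prop, params$n_prop)
  a <- params$W_fb %*% z_prev + params$W_prop %*% r_prop + params$b_hid
  if (params$n_efcp > 0) {
    r_efcp <- as_batch(r_efcp, params$n_efcp)
    a <- a + params$W_efcp %*% r_efcp
  }
  means <- logistic(a)
  out <- list(means = means)
  if (sample)
    out$sample <- matrix(as.numeric(stats::runif(length(means)) < means),
                         nrow(means), ncol(means))
  out
}

#' Down pass: input-layer means (and samples) given hidden activity
#'
#' Recurrent units are Bernoulli with logistic means through the transposed
#' feedback weights; the sensory populations are Poisson with exponential
#' rates through the transposed sensory weights.  Rates are clipped at
#' `rate_ceiling` before sampling so that transiently large weights cannot
#' produce overflow-scale counts.
#'
#' @param params a `"refh_params"` object.
#' @param z hidden activity, `n_hidden` vector or `n_hidden x B` matrix.
#' @param sample draw Bernoulli / Poisson samples as well?
#' @param rate_ceiling upper clip for the Poisson rates (counts per bin).
#' @return list with `fb_means`, `prop_rates`, `efcp_rates` and, if
#'   requested, `fb_sample`, `prop_sample`, `efcp_sample`.
#' @export
down_pass <- function(params, z, sample = FALSE, rate_ceiling = 40) {
  z <- as_batch(z, params$n_hidden)
  out <- list(
    fb_means = logistic(crossprod(params$W_fb, z) + params$b_fb),
    prop_rates = pmin(exp(crossprod(params$W_prop, z) + params$b_prop),
                      rate_ceiling)
  )
  if (params$n_efcp > 0)
    out$efcp_rates <- pmin(exp(crossprod(params$W_efcp, z) + params$b_efcp),
                           rate_ceiling)
  if (sample) {
    out$fb_sample <- matrix(
      as.numeric(stats::runif(length(out$fb_means)) < out$fb_means),
      nrow(out$fb_means), ncol(out$fb_means))
    out$prop_sample <- matrix(stats::rpois(length(out$prop_rates),
                                           out$prop_rates),
                              nrow(out$prop_rates), ncol(out$prop_rates))
    if (params$n_efcp > 0)
      out$efcp_sample <- matrix(stats::rpois(length(out$efcp_rates),
                                             out$efcp_rates),
                                nrow(out$efcp_rates), ncol(out$efcp_rates))
  }
  out
}

new_opt_state <- function(params) {
  zero_like <- function(x) if (is.null(x)) NULL else x * 0
  lapply(params[c("W_fb", "W_prop", "W_efcp",
                  "b_hid", "b_fb", "b_prop", "b_efcp")], zero_like)
}

#' One-step contrastive-divergence update
#'
#' Runs the four stages of CD-1 on one minibatch: sample the hidden layer
#' from the data (`z`), reconstruct the inputs from those samples
#' (`yhat`), and drive the hidden layer once more (`zhat`).  Raw gradients
#' are the Hebbian difference of outer products, averaged over the
#' minibatch:
#' \deqn{\Delta W \propto z y^T - \hat z \hat y^T,\quad
#'       \Delta b_y \propto y - \hat y,\quad \Delta b_z \propto z - \hat z.}
#' Gradients pass through a momentum accumulator and (for weights) an L2
#' weight-decay term before being applied with learning rate `lr`.
#'
#' @param params a `"refh_params"` object.
#' @param z_prev,r_prop,r_efcp the minibatch (columns = cases at a common
#'   time index).
#' @param opt_state momentum accumulator from the previous call (or `NULL`).
#' @param lr learning rate applied to the filtered mean gradient.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 decay coefficient on the weights (not biases).
#' @param cd_final_means if `TRUE` (default) the final up pass uses means
#'   rather than samples, the standard variance-reduction choice; set
#'   `FALSE` to sample at every stage.
#' @param rate_ceiling Poisson rate clip for the reconstruction.
#' @return list with updated `params`, `opt_state`, the positive-phase
#'   hidden `sample` (the activity copied to the next time step), and the
#'   raw mean gradients `grads`.
#' @export
cd1_update <- function(params, z_prev, r_prop, r_efcp = NULL,
                       opt_state = NULL, lr = 5e-4, momentum = 0.9,
                       weight_decay = 2e-4, cd_final_means = TRUE,
                       rate_ceiling = 40) {
  z_prev <- as_batch(z_prev, params$n_hidden)
  r_prop <- as_batch(r_prop, params$n_prop)
  if (params$n_efcp > 0) r_efcp <- as_batch(r_efcp, params$n_efcp)
  B <- ncol(r_prop)

  up <- up_pass(params, z_prev, r_prop, r_efcp, sample = TRUE)
  z <- up$sample
  dn <- down_pass(params, z, sample = TRUE, rate_ceiling = rate_ceiling)
  yhat_fb <- dn$fb_sample
  yhat_prop <- dn$prop_sample
  yhat_efcp <- if (params$n_efcp > 0) dn$efcp_sample else NULL
  up2 <- up_pass(params, yhat_fb, yhat_prop, yhat_efcp,
                 sample = !cd_final_means)
  zhat <- if (cd_final_means) up2$means else up2$sample

  grads <- list(
    W_fb = (tcrossprod(z, z_prev) - tcrossprod(zhat, yhat_fb)) / B,
    W_prop = (tcrossprod(z, r_prop) - tcrossprod(zhat, yhat_prop)) / B,
    W_efcp = if (params$n_efcp > 0)
      (tcrossprod(z, r_efcp) - tcrossprod(zhat, yhat_efcp)) / B else NULL,
    b_hid = rowMeans(z - zhat),
    b_fb = rowMeans(z_prev - yhat_fb),
    b_prop = rowMeans(r_prop - yhat_prop),
    b_efcp = if (params$n_efcp > 0) rowMeans(r_efcp - yhat_efcp) else NULL
  )
  if (!all(vapply(grads, function(g) is.null(g) || all(is.finite(g)),
                  logical(1))))
    stop_invalid("non-finite CD-1 gradient (learning rate too large?)")

  if (is.null(opt_state)) opt_state <- new_opt_state(params)
  decayed <- c("W_fb", "W_prop", "W_efcp")
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    g <- grads[[nm]]
    if (nm %in% decayed) g <- g - weight_decay * params[[nm]]
    opt_state[[nm]] <- momentum * opt_state[[nm]] + g
    params[[nm]] <- params[[nm]] + lr * opt_state[[nm]]
  }
  list(params = params, opt_state = opt_state, sample = z, grads = grads)
}

#' Learning-rate schedules
#'
#' Both schedules are stated through the reciprocal rate: exponential,
#' \eqn{\epsilon_k^{-1} = 1.1^k \epsilon_0^{-1}}, used for the uncontrolled
#' training runs; and sigmoidal,
#' \eqn{\epsilon_k^{-1} = (1000 / (1 + e^{-k/8 + 7.5}) + 12)\epsilon_0^{-1}},
#' used for the longer controlled runs.  Both are strictly decreasing in the
#' epoch index `k` (0-based).
#'
#' @param k epoch index, starting at 0.
#' @param eps0 base learning rate.
#' @param schedule `"exponential"` or `"sigmoidal"`.
#' @return the learning rate for epoch `k`.
#' @export
learning_rate <- function(k, eps0 = 5e-4,
                          schedule = c("exponential", "sigmoidal")) {
  schedule <- match.arg(schedule)
  switch(schedule,
    exponential = eps0 / 1.1^k,
    sigmoidal = eps0 / (1000 / (1 + exp(-k / 8 + 7.5)) + 12)
  )
}
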