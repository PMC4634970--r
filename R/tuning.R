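#' Plug-in mutual information between a binned stimulus and a unit response
#'
#' Empirical mutual information (bits) of the joint histogram of a discrete
#' stimulus (levels `1..n_levels`) and a binary response, with the
#' convention `0 log 0 = 0`.  Real-valued responses in `[0, 1]` are treated
#' as per-step firing probabilities: each step contributes `z` to the
#' "spike" cell and `1 - z` to the "no spike" cell of its stimulus bin.
#'
#' @param bins integer stimulus levels in `1..n_levels`.
#' @param response binary response or firing probabilities in `[0, 1]`.
#' @param n_levels number of stimulus levels.
#' @return mutual information in bits (non-negative).
#' @export
mutual_information <- function(bins, response, n_levels = max(bins)) {
  if (length(bins) == 0) stop_invalid("empty input")
  stopifnot(length(bins) == length(response))
  drop(mi_binary_many(matrix(response, ncol = 1), bins, n_levels))
}

# rowsum over integer levels 1..n, keeping empty levels as zero rows
rowsum_levels <- function(x, idx, n) {
  s <- rowsum(x, idx)
  out <- matrix(0, n, ncol(s))
  out[as.integer(rownames(s)), ] <- s
  out
}

# vectorized MI of many binary/probabilistic responses against one binning;
# Z is T x U, returns length-U vector of bits
mi_binary_many <- function(Z, bins, n_levels) {
  T <- nrow(Z)
  n1 <- rowsum_levels(Z, bins, n_levels)
  nb <- tabulate(bins, n_levels)
  n0 <- nb - n1
  p1 <- colSums(n1) / T
  plogp <- function(p, q) ifelse(p > 0, p * log2(p / q), 0)
  mi <- numeric(ncol(Z))
  pb <- nb / T
  for (u in seq_len(ncol(Z))) {
    j1 <- n1[, u] / T
    j0 <- n0[, u] / T
    mi[u] <- sum(plogp(j1, pb * p1[u])) + sum(plogp(j0, pb * (1 - p1[u])))
  }
  pmax(mi, 0)
}

bin_angle <- function(angle, lo, L, n_bins) {
  a <- wrap_to_range(angle, lo, L)
  pmin(floor((a - lo) / L * n_bins) + 1L, n_bins)
}

#' Lagged mutual-information tuning of hidden units
#'
#' For every unit and every lag in `lags`, computes the mutual information
#' between the (30-bin) discretized stimulus at `t - lag` and the unit's
#' response at `t`, pairing only within trajectories.  A shuffle control
#' rejects spurious information: the response is randomly permuted in time
#' (within trajectory) `n_shuffles` times, and any lag whose unshuffled MI
#' falls below the 95th percentile of its shuffled MIs is set to zero.  The
#' preferred lag is the surviving lag with maximal MI; units with no
#' surviving lag are flagged untuned.  The lagged tuning curve (mean
#' response per stimulus bin at the preferred lag) and its peak location
#' (the preferred angle) are also returned.
#'
#' @param Z `T x U` matrix of unit responses (firing probabilities).
#' @param angle length-`T` stimulus sequence.
#' @param traj length-`T` trajectory index (lags never cross trajectory
#'   boundaries; the first `lag` samples of each trajectory are dropped).
#' @param lo,L lower edge and wrap length of the stimulus space.
#' @param n_bins stimulus bins for the MI computation.
#' @param lags lag grid in steps.
#' @param n_shuffles shuffles for the significance test.
#' @param seed seed for the shuffles.
#' @param dt bin width in seconds, used to report lags in seconds.
#' @return an object of class `"lag_tuning"`: `mi` (lags x U), `mi_sig`
#'   (shuffle-censored), `pref_lag`, `pref_lag_s`, `untuned`, `pref_angle`,
#'   `tuning` (n_bins x U lagged tuning curves), `bin_centers`, `lags`.
#' @export
lagged_mi <- function(Z, angle, traj, lo = -pi / 3, L = 2 * pi / 3,
                      n_bins = 30, lags = 0:40, n_shuffles = 20, seed = 1,
                      dt = 0.05) {
  if (is.vector(Z)) Z <- matrix(Z, ncol = 1)
  T <- nrow(Z); U <- ncol(Z)
  stopifnot(length(angle) == T, length(traj) == T)
  bins <- bin_angle(angle, lo, L, n_bins)
  idx_by_traj <- split(seq_len(T), traj)
  set.seed(seed)

  mi <- mi_sig <- matrix(0, length(lags), U)
  for (li in seq_along(lags)) {
    lag <- lags[li]
    win <- lapply(idx_by_traj, function(ix)
      if (length(ix) > lag) ix[(lag + 1):length(ix)] else integer(0))
    resp_idx <- unlist(win, use.names = FALSE)
    stim_idx <- resp_idx - lag
    Zsub <- Z[resp_idx, , drop = FALSE]
    b_l <- bins[stim_idx]
    mi_obs <- mi_binary_many(Zsub, b_l, n_bins)
    # response shuffled in time within trajectory: permuting the responses
    # over a window pairs the same values as inversely permuting the
    # stimulus labels, so only the labels are shuffled (no matrix copies)
    lens <- lengths(win)
    offs <- cumsum(c(0L, lens[-length(lens)]))
    thr <- matrix(0, n_shuffles, U)
    for (k in seq_len(n_shuffles)) {
      perm <- unlist(lapply(seq_along(lens), function(j)
        offs[j] + sample.int(lens[j])), use.names = FALSE)
      thr[k, ] <- mi_binary_many(Zsub, b_l[perm], n_bins)
    }
    cut <- apply(thr, 2, stats::quantile, probs = 0.95, names = FALSE)
    mi[li, ] <- mi_obs
    mi_sig[li, ] <- ifelse(mi_obs >= cut, mi_obs, 0)
  }

  untuned <- colSums(mi_sig > 0) == 0
  pref_lag <- ifelse(untuned, NA_integer_, lags[apply(mi_sig, 2, which.max)])
  tuning <- matrix(NA_real_, n_bins, U)
  pref_angle <- rep(NA_real_, U)
  centers <- lo + (seq_len(n_bins) - 0.5) * L / n_bins
  for (u in seq_len(U)) {
    lag <- if (is.na(pref_lag[u])) 0L else pref_lag[u]
    resp_idx <- unlist(lapply(idx_by_traj, function(ix)
      if (length(ix) > lag) ix[(lag + 1):length(ix)] else integer(0)),
      use.names = FALSE)
    b <- bins[resp_idx - lag]
    sums <- rowsum_levels(matrix(Z[resp_idx, u], ncol = 1), b, n_bins)
    cnt <- tabulate(b, n_bins)
    tuning[, u] <- ifelse(cnt > 0, drop(sums) / pmax(cnt, 1), NA)
    if (!is.na(pref_lag[u])) pref_angle[u] <- centers[which.max(tuning[, u])]
  }
  structure(list(mi = mi, mi_sig = mi_sig, pref_lag = pref_lag,
                 pref_lag_s = pref_lag * dt, untuned = untuned,
                 pref_angle = pref_angle, tuning = tuning,
                 bin_centers = centers, lags = lags),
            class = "lag_tuning")
}

#' @rdname lagged_mi
#' @param response single-unit response vector (convenience wrapper).
#' @param ... passed on to [lagged_mi()].
#' @export
lagged_mi_profile <- function(response, angle, traj, ...) {
  lagged_mi(matrix(response, ncol = 1), angle, traj, ...)
}

#' @export
print.lag_tuning <- function(x, ...) {
  U <- ncol(x$mi)
  cat(sprintf("<lag_tuning> %d unit(s), lags %d..%d; %d untuned\n",
              U, min(x$lags), max(x$lags), sum(x$untuned)))
  if (U <= 5 && any(!x$untuned))
    cat(sprintf("preferred lag(s): %s\n",
                paste(x$pref_lag, collapse = ", ")))
  invisible(x)
}

rf_cell_index <- function(states, pos_edges, vel_edges) {
  np <- length(pos_edges) - 1L
  nv <- length(vel_edges) - 1L
  pi_ <- findInterval(states[, 1], pos_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  vi <- findInterval(states[, 2], vel_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ok <- states[, 1] >= pos_edges[1] & states[, 1] <= pos_edges[np + 1] &
    states[, 2] >= vel_edges[1] & states[, 2] <= vel_edges[nv + 1]
  list(cell = (vi - 1L) * np + pi_, ok = ok, np = np, nv = nv)
}

default_vel_edges <- function(vel, n_bins) {
  lim <- stats::quantile(vel, c(0.01, 0.99), names = FALSE)
  seq(lim[1], lim[2], length.out = n_bins + 1)
}

#' Position-velocity receptive field of a unit
#'
#' Mean firing probability on a grid over (angular) position and velocity.
#' Position bins span the feasible joint range; velocity bins span the
#' central 98% of the empirical velocities (states outside the grid are
#' dropped).  Cells with zero occupancy are `NA`, never zero-filled.
#'
#' @param z response vector (firing probabilities).
#' @param states `T x 2` matrix of (position, velocity).
#' @param n_bins grid resolution per axis.
#' @param pos_range position range (defaults to the feasible joint space).
#' @param vel_edges optional explicit velocity bin edges.
#' @return an object of class `"rf_grid"`: `prob` (position x velocity,
#'   `NA` where unoccupied), `count`, `pos_edges`, `vel_edges`.
#' @export
pv_receptive_field <- function(z, states, n_bins = 15,
                               pos_range = c(-pi / 3, pi / 3),
                               vel_edges = NULL) {
  pos_edges <- seq(pos_range[1], pos_range[2], length.out = n_bins + 1)
  vel_edges <- vel_edges %||% default_vel_edges(states[, 2], n_bins)
  ci <- rf_cell_index(states, pos_edges, vel_edges)
  ncell <- ci$np * ci$nv
  z <- z[ci$ok]; cell <- ci$cell[ci$ok]
  sums <- rowsum_levels(matrix(z, ncol = 1), cell, ncell)
  cnt <- tabulate(cell, ncell)
  prob <- matrix(ifelse(cnt > 0, drop(sums) / pmax(cnt, 1), NA),
                 ci$np, ci$nv)
  structure(list(prob = prob, count = matrix(cnt, ci$np, ci$nv),
                 pos_edges = pos_edges, vel_edges = vel_edges),
            class = "rf_grid")
}

#' @export
print.rf_grid <- function(x, ...) {
  cat(sprintf("<rf_grid> %d x %d (position x velocity), %d empty cell(s)\n",
              nrow(x$prob), ncol(x$prob), sum(is.na(x$prob))))
  invisible(x)
}

#' @export
plot.rf_grid <- function(x, ...) {
  graphics::image(x$vel_edges, x$pos_edges, t(x$prob)[, nrow(x$prob):1],
                  xlab = "velocity", ylab = "position (top = low)",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Predicted receptive field from lagged-position tuning alone
#'
#' Tests whether a unit's position-velocity receptive field is explained by
#' pure tuning to position at a delay: apply the unit's lagged tuning curve
#' to every stimulus, delay the resulting responses by the unit's preferred
#' lag, and compute a receptive field from these idealized responses.
#' Roughly constant velocity over `n` steps gives
#' \eqn{\theta_t \approx n\Delta\,\omega_{t-1} + \theta_{t-n}}, a line in
#' position-velocity space, so delayed position tuning shows up as sloped
#' stripes.
#'
#' @param tuning length-`n_bins` tuning curve (mean response per stimulus
#'   bin at the preferred lag).
#' @param pref_lag preferred lag in steps.
#' @param angle,states,traj stimulus sequence, `T x 2` state matrix and
#'   trajectory index, as in [lagged_mi()].
#' @param lo,L stimulus-space edge and wrap length.
#' @param n_bins grid resolution of the output receptive field.
#' @param vel_edges optional velocity bin edges (use the measured RF's edges
#'   to compare cell by cell).
#' @return an `"rf_grid"` of the predicted receptive field.
#' @export
predicted_pv_rf <- function(tuning, pref_lag, angle, states, traj,
                            lo = -pi / 3, L = 2 * pi / 3, n_bins = 15,
                            vel_edges = NULL) {
  nb <- length(tuning)
  bins <- bin_angle(angle, lo, L, nb)
  idx_by_traj <- split(seq_along(angle), traj)
  resp_idx <- unlist(lapply(idx_by_traj, function(ix)
    if (length(ix) > pref_lag) ix[(pref_lag + 1):length(ix)] else integer(0)),
    use.names = FALSE)
  z_pred <- tuning[bins[resp_idx - pref_lag]]
  keep <- !is.na(z_pred)
  pv_receptive_field(z_pred[keep], states[resp_idx[keep], , drop = FALSE],
                     n_bins = n_bins, pos_range = c(lo, lo + L),
                     vel_edges = vel_edges)
}

#' Correlation between two receptive fields
#'
#' Pearson correlation of firing probabilities over the cells occupied in
#' both grids.
#'
#' @param a,b `"rf_grid"` objects on the same grid.
#' @return correlation coefficient (NA if fewer than 3 shared cells).
#' @export
rf_correlation <- function(a, b) {
  ok <- !is.na(a$prob) & !is.na(b$prob)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(a$prob[ok], b$prob[ok])
}

#' Circular (angular-angular) autocorrelation of the stimulus
#'
#' Zar's angular-angular correlation between the wrapped joint angle and
#' itself at lag \eqn{\tau}:
#' \deqn{r(\tau) = \frac{\sum_t \sin(a_t - \bar a)\sin(a_{t+\tau} - \bar a')}
#'   {\sqrt{\sum_t \sin^2(a_t - \bar a)\sum_t \sin^2(a_{t+\tau} - \bar a')}}}
#' with \eqn{\bar a, \bar a'} the circular means of the two sequences.
#' Angles are mapped to a full circle before correlating (the feasible range
#' is one period).  Pairs never cross trajectory boundaries.
#'
#' @param angle stimulus sequence.
#' @param traj trajectory index.
#' @param lags lag grid in steps.
#' @param lo,L stimulus-space edge and wrap length.
#' @return vector of correlations, one per lag (`r(0) = 1`).
#' @export
zar_autocorrelation <- function(angle, traj, lags = 0:40,
                                lo = -pi / 3, L = 2 * pi / 3) {
  phi <- 2 * pi * (wrap_to_range(angle, lo, L) - lo) / L
  idx_by_traj <- split(seq_along(angle), traj)
  circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))
  vapply(lags, function(lag) {
    i1 <- unlist(lapply(idx_by_traj, function(ix)
      if (length(ix) > lag) ix[seq_len(length(ix) - lag)] else integer(0)),
      use.names = FALSE)
    a <- phi[i1]; b <- phi[i1 + lag]
    sa <- sin(a - circ_mean(a)); sb <- sin(b - circ_mean(b))
    sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
  }, numeric(1))
}

#' Preferred-lag histogram against the stimulus autocorrelation
#'
#' Tabulates the preferred lags of (significantly tuned) units over the lag
#' grid and superimposes the circular autocorrelation of the underlying
#' dynamical system, rescaled to have the same integral as the histogram.
#'
#' @param pref_lags preferred lags (steps); `NA` (untuned) entries dropped.
#' @param angle,traj stimulus sequence and trajectory index.
#' @param lags lag grid.
#' @param lo,L stimulus-space edge and wrap length.
#' @return list with `lags`, `hist`, `acf`, `acf_scaled`.
#' @export
lag_histogram_vs_autocorrelation <- function(pref_lags, angle, traj,
                                             lags = 0:40, lo = -pi / 3,
                                             L = 2 * pi / 3) {
  pl <- pref_lags[!is.na(pref_lags)]
  h <- vapply(lags, function(l) sum(pl == l), numeric(1))
  ac <- zar_autocorrelation(angle, traj, lags, lo, L)
  scale <- if (sum(ac) > 0) sum(h) / sum(ac) else NA_real_
  list(lags = lags, hist = h, acf = ac, acf_scaled = ac * scale)
}

#' Reorder the learned weight matrices by receptive-field parameters
#'
#' Permutes the hidden and recurrent indices jointly (rows and columns of
#' the recurrent weights, rows of the sensory weights) by preferred angle or
#' preferred lag; the sensory units keep their topographic order.  Sorted
#' views reveal the connectivity structure: units with similar preferred
#' angles (or lags) are preferentially wired together.
#'
#' @param object a `"refh"` fit or `"refh_params"`.
#' @param by `"preferred_angle"` or `"preferred_lag"`.
#' @param pref_angle,pref_lag per-unit values from [lagged_mi()].
#' @return list with the permuted `W_fb`, `W_prop` (and `W_efcp`), the
#'   permutation, and `by`.
#' @export
sort_weight_matrix <- function(object, by = c("preferred_angle",
                                              "preferred_lag"),
                               pref_angle = NULL, pref_lag = NULL) {
  by <- match.arg(by)
  params <- resolve_params(object)
  key <- if (by == "preferred_angle") pref_angle else pref_lag
  if (is.null(key) || length(key) != params$n_hidden)
    stop_invalid("need one %s value per hidden unit", by)
  perm <- order(key, na.last = TRUE)
  list(W_fb = params$W_fb[perm, perm, drop = FALSE],
       W_prop = params$W_prop[perm, , drop = FALSE],
       W_efcp = if (!is.null(params$W_efcp))
         params$W_efcp[perm, , drop = FALSE],
       perm = perm, by = by)
}
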