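---
title: "Learning to filter dynamical state with a recurrent harmonium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning to filter dynamical state with a recurrent harmonium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refh)
```

## The problem

Tracking a moving stimulus — here the angle of a single joint — from noisy
spike counts is a *filtering* problem: at every time step, combine the
current sensory evidence with everything implied by the past, each weighted
by its reliability.  When the dynamics are linear with additive Gaussian
noise and the observations carry a Gaussian-shaped likelihood over the
state, the optimal filter is a (slightly modified) Kalman filter, and its
parameters can be learned from data by expectation-maximization.  The
question this package explores is whether a neural-style learner can reach
the same solution *without supervision and without being told the model
class*: a recurrent exponential-family harmonium (rEFH) — a two-layer
undirected network with Poisson visible units and Bernoulli hidden units —
whose input at each step includes a one-step-delayed copy of its own hidden
layer.  Density estimation on that augmented input forces the hidden layer
to accumulate the information of the filtering posterior.

## The generative model

The plant is a damped harmonic oscillator,
$m\ddot\theta + c\dot\theta + k\theta = u$, discretized with step
$\Delta$:

$$
\theta_{t+1} \sim \mathcal N(A\theta_t + b u_t,\ \Sigma_\theta),\qquad
A = \begin{pmatrix}1 & \Delta\\ -\tfrac{k}{m}\Delta & 1-\tfrac{c}{m}\Delta
\end{pmatrix},\quad b = \begin{pmatrix}0\\ \Delta/m\end{pmatrix},
$$

with $\theta_t$ the (angle, angular velocity) state.  The shipped presets
use $m = 5$, $c = 0.25$, $k = 3$, $\Delta = 0.05$ s, which makes the system
stable and underdamped (complex eigenvalues of modulus $\sqrt{0.999}$).
For the controlled preset the torque follows its own first-order dynamics
$u_{t+1} \sim \mathcal N(\alpha u_t, \sigma_u^2)$ with $\alpha = 0.9994$
and $\sigma_u^2 = 7.5\times10^{-4}$ — nearly a random walk — so the joint
(state, control) system is an uncontrolled third-order system.  Process
noise is $\mathrm{diag}(5\times10^{-7}, 5\times10^{-5})$ for the
uncontrolled preset and $\mathrm{diag}(5\times10^{-5}, 1\times10^{-6})$
for the controlled one; these values keep the Hankel singular values of
the noise-to-angle map within one order of magnitude of each other, i.e.
no state mode is negligible, so the systems are genuinely second- and
third-order:

```{r hankel}
hankel_singular_values(lds_preset("uncontrolled"))
hankel_singular_values(lds_preset("controlled"))
```

Initial angles are uniform over the feasible range $[-\pi/3, \pi/3]$ up to
a 0.05 rad margin (treated by the filters as a zero-precision, diffuse
prior on position); initial velocity and control are Gaussian with
standard deviation $5\times10^{-5}$.  Trajectories are *not* clipped: the
dynamics are stable but the noise is unbounded, and stimuli that leave the
feasible range simply wrap, because the encoders tile their space
periodically.

A third, "no-spring" preset sets $k = 0$ and scales the process noise by
50.  It is used for receptive-field analyses because the spring couples
position to velocity and leaves the corners of position–velocity space
unvisited.  Note that $k = 0$ makes position a pure integrator: this
preset is marginally stable by construction, and the wrap then matters.

## Population codes

Each scalar stimulus is encoded by 15 independent Poisson units with
Gaussian tuning curves $f_i(s) = \exp\{-d(s,\xi_i)^2/2\sigma_{tc}^2\}$,
where $d$ is the wrapped distance on the feasible interval and the
full width at half maximum is one sixth of that interval.  The preferred
stimuli $\xi_i$ are cell-centered on the circle (spacing $L/15$, first
center at $lo + L/30$); the paper-level description says only that the
curves "smoothly tile" the space, and the cell-centered circular layout
makes the wrap handling exact.  Mean counts are $g_t f_i(s_t)$ with a
*gain* $g_t \sim \mathcal U(6.4, 9.6)$ drawn independently per population
per 0.05 s bin — peak rates of 128–192 spikes/s — so the instantaneous
reliability of each population fluctuates the way it would under, e.g.,
attentional modulation.  For independent Poisson units with Gaussian
tuning, the likelihood over the stimulus is itself an unnormalized
Gaussian with mean at the population center of mass
$\sum_i \xi_i r_i / \sum_i r_i$ and variance
$\sigma_{tc}^2/\sum_i r_i$: reliability is *implicit* in the total spike
count, which is what makes it learnable.

The decoder is the circular (population-vector) center of mass rather than
the linear formula: on a uniform circular tiling the circular decode is
exactly unbiased, the two agree closely (within ~1e-5 rad) whenever the
activity hill sits away from the wrap seam, and the linear formula is
ill-defined across the seam.  A response with zero total count decodes to
`NA` — a missing observation, never a zero — and the filters skip the
corresponding update.

## The harmonium and its training

The rEFH's conditionals are logistic for the hidden and recurrent
(Bernoulli) layers and exponential for the Poisson sensory layers, with a
single weight matrix per input block used transposed on the way down.
Training is one-step contrastive divergence: drive the hidden layer from
the data, reconstruct the inputs from the sampled hiddens, drive the
hidden layer once more, and change each weight in proportion to the
difference of the paired outer products.  Choices worth stating:

* **Epoch structure.** 40 trajectories × 1000 usable steps = 40,000
  vectors per epoch; each weight update uses the 40-vector minibatch at a
  common time index, so there are exactly 1000 updates per epoch.  Each
  trajectory carries one extra initial step on which the recurrent units
  are zero and no weights change.  Fresh trajectories every 5 epochs.
* **Schedules.** The reciprocal learning rate grows by 1.1 per epoch for
  uncontrolled runs (120 epochs at full scale) and sigmoidally for the
  longer controlled runs (1200 epochs), both strictly decreasing.
* **Values the source leaves open.** The base rate, momentum and weight
  decay are not printed anywhere; we use $\epsilon_0 = 5\times10^{-4}$ on
  minibatch-mean gradients, momentum 0.9 and L2 decay $2\times10^{-4}$
  (standard harmonium practice; all config-exposed).  Weights initialize
  from $\mathcal N(0, 0.01^2)$; Poisson biases start at the log mean
  training count so early reconstruction rates are calibrated.
  Reconstruction rates are clipped at 40 counts/bin so a transiently large
  weight cannot overflow the Poisson sampler.
* **Sampling vs means.** During training the recurrent copy is the
  *sampled* binary hidden vector and the final CD pass uses means (the
  usual variance-reduction choice; a switch restores all-samples).  At
  test time nothing is sampled: the real-valued hidden means are fed back,
  equivalent to averaging many sampled runs.

Decoding a trained network exploits the down pass: the hidden vector is
pushed back into the input space, where the optimal decoder (center of
mass) is known.

## Benchmarks

All benchmarks consume the *pseudo-observations* (center of mass plus
scaled tuning-curve width) rather than raw spike counts — an advantage
over the harmonium, which must learn what to do with counts:

* **PROP / EfCp** — center of mass of the current population only; optimal
  when there are no dynamics.
* **OPT** — the modified Kalman filter run with the true generative
  parameters.  The modification is exact, not a Gaussian approximation of
  the spiking noise: the Poisson likelihood *is* Gaussian in the angle.
* **EM^n^** — Kalman filters of order $n$ whose parameters are learned by
  EM (filtering + RTS smoothing E-step, closed-form M-step, emission
  given).  Observation sequences are unwrapped by continuity before
  fitting, mirroring the practice of handing benchmark models non-wrapped
  trajectories; this also keeps the EM ascent exactly monotone, which we
  assert in tests.  Restarts are ranked by held-out filtering error
  (selection by training likelihood is available); initial transition
  matrices are random with spectral radius uniform on $[0.5, 0.999]$.
* **OBS** — the best filter that ignores the control: transition matrix
  regressed on the *true* states, residual covariance absorbing the
  missing control.

Infinite prior variances (the uniform initial angle) are handled in
information form — a zero prior precision — rather than with a large
arbitrary constant.

## Tuning analyses

Receptive fields of hidden units are mean firing probabilities on a
15 × 15 grid over position (feasible range) and velocity (central 98% of
the empirical distribution; the source does not specify velocity limits).
Lagged tuning uses 30 position bins and lags 0–40 steps, pairing stimulus
and response only within trajectories; the plug-in mutual information of
each (lag, unit) pair is censored at the 95th percentile of 20
within-trajectory time-shuffles, the preferred lag is the surviving
argmax, and a unit with no surviving lag is flagged untuned.  One caution
we document from the null model itself: with 41 lags each tested at a
~5% level, a pure-noise unit retains *some* lag about 86% of the time;
the shuffle test controls the per-lag rate, not the per-unit rate, and
surviving noise MI is orders of magnitude below genuine tuning.  The
preferred-lag histogram is compared against the Zar angular–angular
autocorrelation of the wrapped stimulus, rescaled to the histogram's
integral.

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions exactly as printed: the
oscillator presets, gains, tuning geometry, initial distributions, and
epoch structure.  It does not emulate non-Poisson (correlated) spiking,
heterogeneous per-unit gains, nonlinear joint limits, or torque
saturation; passing tests therefore speak to the model class the network
was designed for, not to the robustness of the method under real
physiological noise.

## Problem sizes and reproducibility

The package's tests and the acceptance script run everything at desk
scale, which we chose so a full replication of every property fits an
interactive session: 60-hidden-unit networks trained 20 epochs
(uncontrolled) and 90-unit networks trained 30 epochs (no-spring),
best-of-5 restarts, 3 seeds with 2-of-3 majorities, 20-trajectory test
sets, and a reliability experiment with 3 sets of 20 noiseless
trajectories per gain.  The full-scale protocol (240/180 hidden units,
120/1200 epochs, best-of-20, twelve tokens) is available through the same
functions and `validate_config(scale = "paper")`.  Randomness is
stream-split: trajectory $i$ of an experiment with root seed $s$ draws
from the derived stream $(48271 s + i) \bmod (2^{31}-1)$, so enlarging an
experiment never reshuffles what was already simulated.

```{r example, eval = FALSE}
fit <- refh(n_hidden = 60, epochs = 20, seed = 1)
test <- encode_dataset(lds_preset("uncontrolled"), 1000, 20, seed = 777)
truth <- lapply(test$traj, function(tr) tr$theta[, 1])
L <- test$code_prop$L
error_stats(estimator_refh(fit)(test), truth, L)         # rEFH
error_stats(estimator_naive(test$code_prop)(test), truth, L)  # PROP
error_stats(estimator_kf(kf_model(lds_preset("uncontrolled")))(test),
            truth, L)                                    # OPT
```

## Known limitations

* Training curves are qualitative: the learning hyperparameters are not
  printed in the source material, so absolute error levels at full scale
  are not reproduced, only orderings and monotone patterns.
* The EM benchmarks fit unconstrained transition models; the constrained
  variant that respects the block structure of the controlled system is
  not implemented (the unconstrained one is what the reference results
  use).
* Exact numerical agreement between the circular decoder and the linear
  center-of-mass formula is guaranteed only away from the wrap seam.
* The no-spring preset is marginally stable (position integrates), so
  statements about strict stability apply to the spring-loaded presets
  only.
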