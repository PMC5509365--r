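---
title: "Divisive predictive coding: models, probes and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisive predictive coding: models, probes and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divpred)
```

## The inference problem

Sensory systems must infer which external features produced their noisy
afferent signals. `divpred` works with the simplest generative model that
makes this an interesting problem: nonnegative feature intensities
$x = (x_1,\dots,x_n)$ drive a population of $m$ inputs linearly,

$$\langle s_j \mid x\rangle \;=\; \sum_k w_{jk}\,x_k + w_0 ,$$

where $w_{jk} \ge 0$ describes how strongly feature $k$ drives input $j$
and $w_0 > 0$ is the baseline rate when nothing is present. A
`feature_basis()` object holds $W$ and $w_0$; `build_basis()` constructs
the standard geometries (paired inputs, a ring of orientation-like
features, Gaussian blobs on a retinotopic grid, distributed "olfactory"
multi-blob features, and three letter-shaped features stored as synthetic
plain-text rasters). Inputs are sampled by `sample_inputs()`, by default
as independent Poisson counts over a 1 s window so that counts equal
rates.

The noise model decides everything that follows. Neural input variability
typically scales with the mean ("signal-dependent noise", Poisson being
the paradigm). Gradient ascent on the Poisson log-likelihood
$\sum_j [s_j \log \lambda_j - \lambda_j]$, $\lambda = W\hat x + w_0$,
gives the **divisive** estimator dynamics

$$\frac{\partial \hat x_i}{\partial t}
 = \eta \sum_j w_{ji}\Big(\frac{s_j}{\sum_k w_{jk}\hat x_k + w_0} - 1\Big):$$

each input is divided by its own prediction *before* the evidence is
combined, and the drive is a sum of *fractional prediction errors*
(`fractional_errors()`), zero when the input is perfectly predicted and
never below $-1$. If the noise were instead constant Gaussian, the same
derivation gives the **subtractive** dynamics driven by absolute errors
$s_j - \langle s_j\rangle$, whose unconstrained fixed point is the linear
readout $(W^\top W)^{-1} W^\top (s - w_0)$
(`subtractive_closed_form()`; we remove the baseline first so that
noiseless inputs are recovered exactly). This difference — division by
the prediction versus subtraction of it — is the scientific contrast the
whole package is built to exhibit.

## Estimators and their solvers

`feature_estimate()` is the modelling front door: it returns a classed
`feature_fit` with `coef()` (the estimate), `fitted()` (predicted input
means), `residuals()` (fractional or absolute errors) and `logLik()`.
Four solvers reach the fixed points:

* `run_to_convergence()` integrates the gradient dynamics themselves
  (Euler steps, estimates initialized at zero, projection onto
  $\hat x \ge 0$ after each step). It is the reference implementation;
  $\eta$ defaults to $10^{-3} / \max_i \sum_j w_{ji}$, small enough for
  smooth ascent on every packaged basis, with `tol = 1e-8` on the largest
  per-step change and a $10^5$-step cap. Non-convergence is flagged on
  the returned object, never thrown.
* `divisive_ml()` solves the same nonnegative Poisson maximum-likelihood
  problem with multiplicative updates
  $x \leftarrow x \cdot \big(W^\top(s/\lambda)\big)/\mathrm{colSums}(W)$
  (the Richardson–Lucy/EM update with a known background), vectorized
  over stimulus columns as dense matrix products. An optional exponent
  `relax` $\in [1, 2)$ accelerates the geometric tail without moving the
  fixed points.
* `divisive_dynamics()` is the batched form of the gradient dynamics
  (see *Degeneracy and operating points* below for why it exists
  alongside `divisive_ml()`).
* `subtractive_nnls()` computes the clamped subtractive fixed point
  (nonnegative least squares) by FISTA with step $1/\|W\|_2^2$.

### Degeneracy and operating points

On bases whose features overlap heavily (the orientation ring, the blob
grids) the Poisson log-likelihood is concave but nearly flat along
directions that trade intensity between neighbouring features. The
maximizer set is then effectively a face, and different algorithms select
different representatives: multiplicative updates sharpen estimates onto
few features (complete explaining away), whereas the gradient dynamics
initialized at zero settle on the smooth, graded representative. Both
have the same likelihood to numerical precision — a property the test
suite asserts — but only the smooth representative produces graded,
bell-shaped tuning curves, and it is at that operating point that the
contextual phenomena (tuning-curve shifts, invariant readout) are
measured. The tuning-curve protocols therefore run
`divisive_model(engine = "dynamics")` with a fixed budget of $10^4$
gradient steps (per-step changes are below $\sim 10^{-5}$ by then), while
probes that only need steady-state response values (receptive-field
mapping, feature discrimination) use the much faster multiplicative
solver at `tol = 1e-3`–`1e-4`; at those tolerances the remaining solver
wobble lies along the flat face and is far below the probe-level effects
being measured.

## The excitatory/inhibitory network

The estimator maps onto a two-population rate circuit
(`network_params()`, `simulate_network()`): excitatory units receive one
input each and carry the fractional errors,

$$a\,\dot r^{\mathrm{exc}}_j = s_j - \Big(w_0 + \sum_k w_{jk} r^{\mathrm{inh}}_k\Big) r^{\mathrm{exc}}_j ,$$

with inhibition multiplying the leak, and inhibitory units integrate the
weighted errors and carry the feature estimates,

$$b\,\dot r^{\mathrm{inh}}_i = \sum_j w_{ji}\big(r^{\mathrm{exc}}_j - 1\big).$$

At a steady state $r^{\mathrm{exc}}_j = s_j / \langle s_j\rangle$ (unity
for a perfectly predicted input, not zero) and $r^{\mathrm{inh}} =
\hat x$, the divisive estimate. We place the $-1$ inside the weighted sum
because only that form makes the inhibitory fixed point coincide with the
estimator's stationarity condition for weights that do not sum to one.
Timescale constants default to $a = 0.08$ and $b = 40$, the background to
$w_0 = 1$ for all network-level protocols (estimator-level protocols use
$w_0 = 0.01$). Integration is explicit Euler in compiled code with
$\Delta t = 10^{-4} a$; the integrator aborts if any
$\mathrm{leak}\cdot\Delta t / a$ exceeds 1, and both populations are
clamped at zero. For "simple" stimuli that do not co-activate
overlapping detectors the steady excitatory response reduces to the
canonical divisive-normalization forms `steady_state_two_unit()`
($s_1/\max(s_1+s_2, w_0)$) and `steady_state_simple()`, up to one global
constant; comparisons against simulation are therefore ratio-based.

The subtractive comparison network is not fully specified in the
literature this package models, so we define it as the constant-leak,
additive-inhibition analogue
($a\,\dot r^{\mathrm{exc}} = s - w_0 r^{\mathrm{exc}} - W r^{\mathrm{inh}}$,
same inhibitory equation) whose steady state matches the subtractive
estimator's fixed point at $w_0 = 1$. Its excitatory error units are
left signed — clamping them would destroy the linearity that gives the
subtractive model its signature input-invariant dynamics — while
inhibitory rates stay nonnegative. Two consequences are worth noting.
First, linearity makes the time-to-peak exactly amplitude-invariant
(asserted to the recording resolution), in contrast to the divisive
network, whose effective time constant $a/(w_0 + \sum_k w_{jk}
r^{\mathrm{inh}}_k)$ shrinks with drive — shorter latencies at higher
contrast and an outward-travelling wave in the topographic network.
Second, in that topographic protocol the subtractive latencies are only
approximately distance-independent: over the strongly driven core the
70%-of-peak latencies vary by under ten percent (versus several hundred
percent for the divisive net), but weakly driven distant units relax
monotonically without a transient, so a 70%-of-maximum criterion there
measures slow relaxation rather than a wavefront and the spread grows
well beyond that. We report the faithful measurement over the window
$|j-k| \le 8$ rather than restricting to the flattering core.

## Baseline and probes

The linear–nonlinear (LN) baseline (`ln_model()`, `fit_ln()`) is
$r_i = \max(\sum_j v_{ji} s_j + v_0, 0)$ with the linear stage fitted by
ridge-regularized least squares to the divisive model's responses on the
same stimuli (ridge $10^{-6}$ relative to the Gram diagonal; an
active-set refit is available behind `refit_active` but the default fit
suffices because the divisive responses are predominantly
supra-threshold). Fitting with the rectifier in the loop is nonconvex;
applying it at evaluation only is the documented simplification.

Probes accept any deterministic response model (a matrix-in,
matrix-out function or an `ln_model`):

* `reverse_correlation_rf()` implements $\hat w = Q_{ss}^{-1} q_{rs}$
  with raw (uncentered) second moments, exactly the standard estimator;
  a `centered` flag exists but defaults off. Diagonal loading is applied
  only if the moment matrix's condition number exceeds $10^{12}$.
  `rf_from_data()` exposes the same computation on precomputed
  stimulus/response matrices so that one expensive model evaluation can
  feed several analyses.
* `tuning_curve()` presents each feature's mean input profile
  ($w_{ji} + w_0$, Poisson trials) with an optional context: either a
  receptor held constant at a fixed value (replacing its draw) or a
  constant mask vector added to the means. `rescale_curves()` puts
  curves on a zero-mean, unit-sd scale so shape changes can be compared
  across contexts independently of gain.
* `fit_readout()` estimates the linear decoder
  $U = \langle \bar s \bar r^\top\rangle \langle \bar r \bar r^\top\rangle^{-1}$
  from centered moments; `reconstruction_error()` reports rms error
  normalized by the rms of the centered stimulus, so the trivial decoder
  scores exactly 1.
* `context_shift_metrics()` locates tuning peaks by three-point parabolic
  interpolation around the argmax (resolving sub-index shifts; the
  interpolation offset is clamped to $\pm 0.5$ index), optionally on a
  circular axis, and reports the mean squared cross-context difference of
  rescaled curves.

## Preset experiments

`run_experiment()` regenerates the characteristic phenomena with fixed
parameters; `list_experiments()` names the nine presets and the thin
command-line launcher (`inst/scripts/divpred`, or `run_cli()`) drives
them from a shell. All randomness flows through one seed; a rerun with
the same configuration is bit-identical, and `scale` multiplies every
trial/presentation count. Parameters follow the standard protocol
values: sparse stimuli 0 or 100 with activation probability 0.05;
vertical gratings with 8-pixel bars of amplitude 20 and random phase;
contextual masks held at 200 three receptors from the probed neuron's
preferred input; surround-suppression stimuli of mean 50 (test) and 20
(context) averaged over 200 trials; blob features with $w_\max = 40$ and
$\sigma_w = 0.1$ on a $30\times30$ grid; topographic input
$150\,e^{-|j-k|/2}$; receptive fields from $10^4$ presentations.

Choices the protocols leave open, fixed here once: the Fig-4-style mask
contexts are sums of three randomly chosen feature columns at half the
single-feature drive; the readout protocol uses 300 trials per condition,
enough that decoder estimation error sits below the cross-context
invariance being measured (at 100 trials the measured column correlation
is still visibly depressed by estimation noise); the multiblob
("olfactory") features are four blobs of the standard width and
amplitude with uniformly random centres; the discrimination preset picks
the three most mutually overlapping features; the letters are drawn as
synthetic $20\times30$ rasters with full pairwise overlap. The
surround-suppression preset evaluates the subtractive model through the
unclamped linear readout (with a small ridge because the paired circulant
$W^\top W$ is singular): location-invariant suppression is a consequence
of linearity, which clamping would destroy.

One negative analytical result is worth recording. In the
surround-suppression protocol the *disjoint* context (drive on the far
side of the receptive field) cannot suppress the divisive model's mean
response: the only receptor shared with the context is silent on almost
every trial (mean $w_0 = 0.01$), and a zero input makes the fractional
error the constant $-1$ regardless of the prediction, decoupling the
recorded estimate from the context. The divisive contrast that is robust
in this protocol is adjoint-versus-everything (near-total explaining
away), with the disjoint condition statistically indistinguishable from
no context; the subtractive model suppresses both contexts equally, as
its linearity requires.

## What the synthetic data do and do not show

All inputs are generated from the package's own generative model, so
passing tests certify internal consistency: that the estimators maximize
what they claim to maximize, that the circuit computes the estimator,
and that the measurement probes recover what they are pointed at. The
synthetic preparations emulate trial-to-trial Poisson variability,
prescribed feature geometries and steady-state responses. They do not
emulate temporal stimulus dynamics or adaptation, spiking variability,
correlated noise across inputs, unknown or learned connectivity, or any
mismatch between the world and the network's generative model — on real
data all of those are in play, so agreement here is a necessary, not
sufficient, condition for the account to hold.

## Numerical notes and limitations

Problem sizes were chosen to keep every protocol tractable on one CPU:
the desk-scale checks run the oracle comparisons at $n \le 3$ (brute
force likelihood grids refine 8 times over 13 points per axis),
stationarity at $n = 30$, receptive fields at $10^4$ presentations, and
tuning protocols at 50–300 trials per condition; the acceptance script
additionally scales two heavy protocols down (its output records the
sizes used). Boundary ties in the estimators (zero gradient at a zero
coordinate) stay at zero. Flat tuning curves rescale to zero rather than
NaN. The two-unit and simple-stimulus closed forms carry unit
proportionality constants, so only response ratios are compared against
simulation. Known limitations: no correlated-noise corrections, no
variance-proportional-to-mean families beyond Poisson and constant
Gaussian, no spiking or conductance-based dynamics, no firing threshold,
no multi-layer hierarchy, and no learning of $W$ — connectivity is
always prescribed by the generative model.
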