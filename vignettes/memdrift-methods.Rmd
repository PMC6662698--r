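---
title: "Drift-diffusion attractor dynamics for continuous-report working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-diffusion attractor dynamics for continuous-report working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(memdrift)
```

## The scientific problem

In a delayed-estimation task a subject briefly sees one or more colored
items, waits through a memory delay, and then reproduces the cued item's
hue on a continuous color wheel. Report errors grow with the delay and
with the number of items held in memory, and the reported hues are not
uniform even when the targets are: reports pile up ("cluster") at a few
preferred colors. `memdrift` implements a dynamical account of these
phenomena: each remembered hue is a point on a circle that *diffuses*
under random noise and *drifts* toward a small set of stable attractor
colors. Attractors bias memories toward themselves but also anchor them
against diffusion, so the model jointly predicts the distribution, bias,
and precision of reports and how each evolves with time and load.

## The generative model

A memory $\theta$ (radians on the circle) evolves as the Itô SDE

$$\mathrm{d}\theta = \beta_L\, G(\theta)\,\mathrm{d}t + \sigma_L\,\mathrm{d}W,$$

where $G(\theta)$ is a drift function shared across loads, $\beta_L$ a
load-dependent drift gain, and $\sigma_L$ a load-dependent diffusion
scale. $G$ is a linear combination of the first derivatives of twelve von
Mises densities whose means are one circular SD ($2\pi/12$) apart, and is
divided by its maximum absolute value, so $\beta_L$ is interpretable as
the maximum instantaneous drift rate (rad/s). Stable fixed points of $G$
(downward zero crossings) are the attractors; upward crossings are
repellors.

The density $p(\theta, t)$ obeys the Fokker–Planck equation

$$\partial_t p = -\partial_\theta\!\left[\beta_L G(\theta)\, p\right]
  + \tfrac{\sigma_L^2}{2}\, \partial^2_\theta p,$$

which we discretize on 100 evenly spaced bins into a continuous-time
Markov generator $M_L$ and solve exactly in time as
$p(\cdot,t) = e^{M_L t}\, p(\cdot,0)$.

Encoding is a fixed 1-s period of the same kind of dynamics with its own
gains $(\beta^*_L, \sigma^*_L)$, applied to a narrow von Mises
initialization at the target (circular SD 0.1 rad). The predicted report
density for a trial with delay $t$, load $L$ and $m = L-1$ non-targets is
the mixture

$$p(\hat\theta, t) = (1 - \lambda - \alpha)\, p(\theta, t)
 + \frac{\alpha}{m} \sum_{i=1}^m p(\theta_i^*, t)
 + \frac{\lambda}{2\pi},$$

with guess probability $\lambda(t)$ and swap probability $\alpha(t)$
linear in the delay (per-load $\lambda$; $\alpha \equiv 0$ at load 1),
optionally convolved with a von Mises decoding kernel of circular SD
$\sigma^\dagger$ (the "human-style" model; the "monkey-style" model omits
it).

## Numerical choices

* **Generator discretization.** Advection–diffusion hopping rates use
  exponentially fitted (Scharfetter–Gummel) upwinding: with
  $D = \sigma^2/2$ and interface velocity $v$, the clockwise and
  counterclockwise rates across a bin interface are
  $(D/\Delta^2)\,B(\mp v\Delta/D)$ with $B(x) = x/(e^x - 1)$. This keeps
  every off-diagonal rate nonnegative (a valid generator for any gains),
  reduces to plain first-order upwinding as $\sigma \to 0$, and — unlike
  plain upwinding — adds no numerical diffusion of order $|v|\Delta/2$,
  which at 100 bins would be comparable to the physical diffusion at the
  gains of interest. The discretization is validated against an
  Euler–Maruyama particle oracle (total-variation distance below 0.02 at
  $10^5$ particles across a $3\times3$ grid of gains including
  $\beta = 0$).
* **Matrix exponentials** use dense scaling-and-squaring
  (`Matrix::expm`). One propagator is built per unique (load, delay)
  condition; delays that are integer multiples of the shortest are
  obtained by exact matrix powers.
* **Circular SD convention.** Everywhere a von Mises is parameterized by
  a circular SD $s$, the concentration is $\kappa = 1/s^2$ (the standard
  high-concentration map); with $s = 2\pi/12$ this gives smooth
  overlapping basis bumps.
* **Likelihood.** Reports are continuous; the report density (per
  radian) is linearly interpolated between bin centers, and the dataset
  log-likelihood is the sum over trials. Tiny negative densities from
  rounding are clipped at $-10^{-12}$ relative tolerance and the field
  renormalized.
* **Mixture clipping.** $\lambda(t)$ and $\alpha(t)$ are each clipped to
  $[0,1]$; if their sum exceeds 1 both are rescaled proportionally,
  preserving their ratio.
* **Angle conventions.** Radians internally, degrees at every user-facing
  surface. Positive signed error is clockwise. The ambiguous antipodal
  deviation is assigned $+180^\circ$. Grid bin $k$ (0-based) covers
  $[k\Delta, (k+1)\Delta)$ with its center at $(k+\tfrac12)\Delta$.

## Fitting

`fit_wm()` maximizes the joint likelihood with L-BFGS-B under the bound
constraints $\sigma, \sigma^* \in [10^{-3}, 3]$, $\beta, \beta^* \in
[0, 10]$, $w_j \in [-5, 5]$, intercepts $b \in [10^{-4}, 1]$, slopes
$a \in [-0.5, 0.5]$, $\sigma^\dagger \in [10^{-3}, 1]$. Three details
matter in practice:

* **Informed start.** One start seeds the drift weights from a
  ridge-regularized projection of the numerical derivative of the
  response KDE onto the basis — attractors begin at commonly reported
  colors. Plain least squares is avoided here: the basis transfers high
  harmonics of the KDE derivative very weakly, so unregularized
  coefficients blow up into near-cancelling pairs and the normalized
  field becomes hypersensitive to the weights. The remaining starts are
  Latin-hypercube draws inside the bounds (weights in $[-1, 1]$).
* **Restart cycles.** The surface has long shallow valleys (encoding and
  memory gains trade off). Each start is re-optimized up to `n_cycles`
  times from its incumbent; restarting resets the quasi-Newton Hessian
  and reliably continues progress. Recovery runs verify that the fitted
  optimum dominates the generating parameters.
* **Gradients** are one-sided finite differences (step $10^{-6}$
  relative) sharing a propagator cache, so perturbing one load's
  parameters does not recompute the other load's matrix exponentials.

Because the drift field is normalized, the likelihood is invariant to a
common rescaling of the weights; only the shape of $G$ and the gains are
identified, which is what the scientific questions require.

Model variants (`wm_variant()`) freeze $\beta$, $\beta^*$, the decoding
kernel, or simplify the guess parameterization. `compare_wm()` reports
AIC/BIC and Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$; `crossval_wm()` gives
the k-fold (default 10) cross-validated held-out log-likelihood,
stratified by load-by-delay condition. `bootstrap_wm()` implements both
trial resampling (refit per iteration) and subject-parameter resampling
(mean of resampled per-subject estimates), with percentile intervals and
one-sided contrast p-values.

## Model-free statistics

* **Clustering metric.** $C = H(\hat\theta) - H(\Theta)$ in bits, with
  $H = -\sum f \log_2 f \, \mathrm{d}\theta$ evaluated on a 360-point
  grid with densities per radian (a uniform circular density then has
  $\log_2 2\pi \approx 2.65$ bits, which anchors the scale). Densities
  come from a von Mises KDE with circular SD $10^\circ$. A uniform
  component equal in area to the guess rate is subtracted from both
  densities (floored at zero) before renormalization, and trials can be
  subsampled to equal per-condition counts under a fixed seed.
* **Nonuniformity.** Hodges–Ajne against uniformity (closed-form count
  statistic; exactly balanced configurations return $p = 1$), and a
  two-sample Kuiper statistic of reports against targets with a pooled
  permutation null.
* **Response peaks.** KDE local maxima, retained when their amplitude
  exceeds the 95th percentile of peak amplitudes from bootstrap
  resamples of the target sample. A separate global p-value compares the
  maximum observed amplitude to re-splits of the pooled reports and
  targets; pooling makes the null exchangeable, so this p-value is
  exactly uniform when reports are distributed like targets (verified by
  KS calibration in the tests).
* **Bias and precision profiles.** Per-target-bin circular mean signed
  error and circular SD (4° bins by default, 6° for coarse 64-hue
  designs); the bias slope at an anchor is an OLS fit within
  $\pm 15^\circ$, and the local SD is averaged over the same window. An
  attractor shows a negative slope and a reduced SD.
* **Fixed-point error growth.** Mean $|$error$|$ change from the
  shortest to the longest delay for targets within $\pm 15^\circ$
  (configurable) of stable versus unstable fixed points, with a
  one-sided trial bootstrap.
* **Attractor alignment.** Mean circular distance from fitted attractors
  to the nearest reference color, against a null of randomly rotated
  reference sets per unit.
* **Fixed-point pruning.** Attractors are peaks of $\int G$; within one
  fitted field, peaks whose prominence falls strictly below the 20th
  percentile of that field's peak prominences are discarded (with a
  flanking repellor, preserving alternation). Exactly tied prominences
  are never pruned, so symmetric fields keep all their attractors. The
  percentile rule is applied within the single field because a
  cross-subject pool is not available to a single fit.

## The synthetic generator and what it does (not) emulate

`task_design()` + `simulate_trials()` generate ground-truth datasets:
uniform or biased target environments (four equally spaced 20°-wide
clusters of common colors, random phase, drawn with probability 0.5),
same-trial colors at least 22° apart by rejection sampling, loads 1–3,
discrete or continuous delays. Reports can be sampled from the analytic
report distribution ("mixture" mode) or by Euler–Maruyama integration of
the underlying SDE at `dt = 0.01` s ("sde" mode); the two agree to
total-variation distance below 0.03, and halving `dt` leaves the report
histogram at the Monte-Carlo noise floor.

The representative ground truth (`wm_truth_default()`) uses a
four-attractor drift field built by projecting the derivative of a
four-mode response density onto the basis, and rates chosen once as
plausible for this task class: memory drift/diffusion increasing with
load ($\beta = 0.25/0.4/0.5$ rad/s, $\sigma = 0.25/0.33/0.4$
rad/$\sqrt{s}$ for loads 1–3), stronger encoding dynamics
($\beta^* = 0.8/1.0/1.2$, $\sigma^* = 0.25/0.3/0.35$), small
time-increasing guess and swap rates, and decoding noise
$\sigma^\dagger = 0.1$ rad for the human-style observer. These values
produce the qualitative regime the model is meant to live in — error
growing with load and delay, report clustering at attractors, an early
cost and late benefit of drift in uniform environments with a single
performance crossover, and a uniform benefit when half the targets fall
near attractors.

The generator emulates task *structure*, not subjects: it has no
reaction times, no sequential (inter-trial) dependencies, no lapses of
fixation, no perceptual inhomogeneity of the color wheel, and its
ground truth is exactly the fitted model class. Passing tests therefore
demonstrate internal consistency and recoverability, not that real
behavior obeys the model.

The normative analyses are quadrature, not simulation:
`error_over_time()` propagates each target's density and integrates
$E|\text{error}|$ exactly over a grid of 60 targets weighted by the
environment, so the curves carry no Monte-Carlo noise;
`error_heatmap()` tabulates the percent error increase of the
diffusion-only model across environment bias fractions.

The monkey reward schedule is the von Mises drop count
$r(e) = \lceil 12\, \phi(e)/\phi(0) \rceil$ with SD 22°, zero beyond
60° error.

## The warp control model

A clustered report distribution alone does not imply attractors. The
control model maps the stimulus circle radially onto the perimeter of a
square "true perceptual space" (1,024 points), lets memories take 1,000
uniform integer steps of at most 4 points per step, and maps back.
Because the walk lives on a cyclic lattice, the total displacement is
sampled from the exact n-step distribution (step pmf convolved via FFT),
which is equal in distribution to stepping one at a time and keeps
100,000 angles instant. This model clusters reports (negative $C$) where
the inverse map compresses the perimeter — the square's corners — but
produces *repulsive*, not attractive, bias at the cluster peaks: the
signature that separates perceptual warping from attractor dynamics.

## Problem sizes used by the test suite

The package's end-to-end checks run at desk scale, chosen once: the
particle oracle uses $10^5$ particles at nine (β, σ) combinations
spanning the default truth's gains; parameter recovery uses 4,000 trials
(2 loads × 2 delays) on the default 100-bin grid; the model-selection
study uses 20 replicates per scenario of 300 single-load trials on a
40-bin grid with two variants (full versus no-drift); the bias/precision
and fixed-point-stability checks use 20,000 trials; null calibrations
use 200 replicates. The fitting controls used there (single informed
start, capped restart cycles) are reported in the tests themselves.

## Known limitations

* The drift field is static within a trial and shared across loads (only
  its gain varies); slowly reshaping attractor landscapes are out of
  scope.
* Finite-difference gradients make single fits take minutes at 4,000
  trials; analytic gradients of the matrix exponential are not
  implemented.
* The Hodges–Ajne p-value uses the standard closed-form/asymptotic
  formulas, which are conservative in the far-from-significant regime.
* The EM screening mixture shares one concentration across target and
  swap components.
* With fewer than two delay levels, the time-linear guess/swap rates are
  not identifiable from data (only their value at the single delay is).
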