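---
title: "Circular auto-regressive movement models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular auto-regressive movement models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmove)
```

## The model

circmove models a regularly sampled planar trajectory as a discrete-time
process in which the direction of heading is primary and speed is coupled to
it. Fixes $X_0, X_1, \dots$ at time unit $T$ define headings
$\Theta_t = \mathrm{atan2}(Y_{t+1}-Y_t,\, X_{t+1}-X_t)$ (0 = east, $\pi/2$ =
north, wrapped to $[-\pi,\pi)$) and speeds $V_t$ = step length / $T$.
Positions accumulate as
$x_{t+1} = x_t + T\, v_t\, (\cos\theta_t, \sin\theta_t)$.

**Headings.** The circular auto-regression (CAR) steers each heading toward a
focal direction $\alpha$ through the smooth tan-half-angle circle map

$$M(\theta;\alpha,w) = \alpha + 2\arctan\!\big\{w\,\tan\tfrac{\theta-\alpha}{2}\big\},$$

so $\theta_t = M(\theta_{t-1};\alpha,w) + e_t$ with i.i.d. circular noise
$e_t$. The map is continuous on the whole circle (unlike the naive convex
combination $w\theta_{t-1} + (1-w)\alpha$, which tears at the antipode), and
the single coefficient $w$ spans the familiar regimes: $w = 1$ is the
correlated random walk (CRW), $w \to 0$ collapses every step onto $\alpha$
(strongly oriented movement), $w < 0$ reflects across $\alpha$ and produces
zigzag, reciprocating headings. For a homing animal the focal *direction* can
be replaced by a focal *point*: the attraction target becomes the bearing
from the current position to a known goal, recomputed every step.

**Noise.** Three error families are provided. The von Mises
$\mathrm{VM}(0,\kappa)$ and wrapped Cauchy $\mathrm{WC}(0,r)$ densities are
symmetric about the regression mean. Real headings are often skewed — e.g. a
bird blown sideways by wind — and for that the four-parameter asymmetric
family $\mathrm{KJ}(\mu,\kappa,r,\nu)$ is used: a $\mathrm{VM}(0,\kappa)$
variable is attracted toward $\nu$ through the same circle map with
coefficient $(1-r)/(1+r)$ and then rotated by $\mu$. In the heading model the
rotation is the per-step regression mean $\mu_t = M(\theta_{t-1};\alpha,w)$
and the attraction direction is $\nu_t = \lambda - \mu_t$, so the noise is
always skewed toward a fixed external direction $\lambda$ (interpreted as
leeward when wind is the forcing). Because $\nu_t$ moves with $\theta_{t-1}$,
the conditional density of $\theta_t$ changes shape along the trajectory —
including, for extreme parameters, bimodal or otherwise "abnormal" shapes,
which the density and `kj_summaries()` expose rather than hide.

**Speeds.** A Gaussian auto-regression

$$v_t = a\,v_{t-1} + b\cos(\theta_t - c) + d\cos(\theta_t - \theta_{t-1}) + c_0 + \eta_t,
\qquad \eta_t \sim N(0,\sigma^2),$$

with $b > 0$ and $c \in [-\pi,\pi)$: speed peaks when heading leeward
($\theta_t = c$), previous speed and the cosine of the turn enter as optional
covariates selected by AIC. Fitting uses the untruncated Gaussian likelihood
— in cruising regimes (mean speed several $\sigma$ above zero) the truncated
and untruncated MLEs are practically identical — while simulation redraws
non-positive speeds, recording how often that happens.

## Estimation

All heading models are fitted by maximizing the conditional log-likelihood
(conditioning on $\Theta_0$; for the asymmetric family the per-step density
is the closed-form KJ density at $(\mu_t, \kappa, r, \nu_t)$). Optimisation
is quasi-Newton (BFGS) on transformed parameters — $\log\kappa$,
$\mathrm{logit}\,r$, unconstrained angles and $w$ — from several starts: warm
starts built from circular moment estimates, a nested symmetric-noise prefit
for the KJ family (which also guarantees in practice that richer families
never report a worse maximum than the models they nest), and a stratified
random design ($w \in \{-0.5, 0.3, 0.7, 0.95\}$, $\kappa \in \{1,10\}$,
$r \in \{0.1, 0.5\}$, angles on a coarse circular grid). Eight starts are the
default; every start's converged objective, convergence code and
finite-difference gradient norm are recorded in the fit. Convergence uses a
relative objective tolerance of $10^{-10}$; a start is flagged "converged"
only if its gradient norm is below $10^{-4}$. AIC is $-2\ell + 2k$ with $k$
the number of free parameters (1 for CRW(VM)/CRW(WC), 3 for CAR(VM)/CAR(WC),
5 for CAR(KJ); each constraint removes exactly the parameter it fixes, and
$\sigma^2$ counts as a parameter in the speed model).

### An exact aliasing of the attraction map

The tan-half-angle map has fixed points at both $\alpha$ and its antipode,
and satisfies $M(\theta;\alpha,w) = M(\theta;\alpha+\pi,1/w)$ exactly for
every $w \neq 0$: attraction to $\alpha$ with strength $w$ *is* attraction to
$\alpha+\pi$ with strength $1/w$. With a free focal direction the likelihood
therefore has two global maxima in parameter space describing the same
process, and a multi-start optimiser lands in either. Fits with free $\alpha$
are reported in the canonical representation $|w| \le 1$, in which $\alpha$
is the attracting fixed point; this also keeps bootstrap distributions of
$\hat w$ and $\hat\alpha$ from artificially mixing the two representations.
When $\alpha$ is fixed (a known flight direction, or a focal point) the two
branches are genuinely different models, and $w$ is reported exactly as
estimated, including $|w| > 1$ and $w < 0$.

A related caution applies to the asymmetric model itself: when the skew
target $\lambda$ sits exactly antipodal to $\alpha$, the noise skew and the
map attraction trade off and the five parameters are only weakly identified
(estimates stay mutually consistent but biased, with a mirrored second
optimum). The built-in `tortuous_loop` fixture deliberately avoids that
degenerate geometry.

## Time unit and diagnostics

The i.i.d. noise assumption fails when fixes are finer than the pace at
which the animal controls its heading. `derive_steps()` resamples fixes at a
chosen time unit (anchored at the first fix; trailing partial steps are
dropped: a 500-s section at 0.5-s fixes gives 500, 250 and 166 steps at
$T = 1, 2, 3$). Residuals — wrapped differences $\Theta_t - \mu_t$ for
symmetric noise, the inverse generating transformation for KJ noise — are
screened by the lag-1 autocorrelation with the standard white-noise band
$1.96/\sqrt{n}$. `choose_time_unit()` accepts the smallest unit at which
some candidate model passes both that screen and the goodness-of-fit test
below.

Two parametric-bootstrap goodness-of-fit tests address global pattern rather
than one-step fit:

* **Heading distribution** — 1000 heading series are simulated from the
  fitted model starting at the observed first heading; counts in 24 equal
  circular classes give expected counts $E_d$ and 95% envelopes; classes with
  $E_d < 3$ are dropped and $\sum (E_d - O_d)^2/E_d$ is referred to
  $\chi^2_{(\text{classes}-1)}$. Degrees of freedom are not reduced for
  estimated parameters (they are not re-estimated per simulation); the
  calibration of this choice is itself checked empirically in the test suite,
  and a Monte-Carlo p-value (rank of the observed statistic among the
  simulated series' own statistics) is reported alongside. The chi-square
  reference is well calibrated for weakly autocorrelated heading series; for
  strongly dependent series the Monte-Carlo p-value is the safer of the two.
* **Final location** — full trajectories (headings and speeds) are simulated
  from the observed initial conditions; the simulated endpoints' mean
  $\mathbf{M}$ and covariance $\Sigma$ define a bivariate-normal
  approximation, and the probability of an endpoint at least as extreme as
  the observed one is the mass outside the density contour through it,
  $P_{FL} = \exp(-D^2/2)$ with $D^2$ the Mahalanobis distance — computed in
  closed form rather than by 2-D quadrature, exact under the normal
  approximation. $P_{FL} < 0.05$ (equivalently $D^2 > 2\ln 20$, the 95%
  point of $\chi^2_2$) rejects the model.

Sampling distributions of the MLEs are estimated by parametric bootstrap
(`bootstrap_mles()`, default 200 refits seeded at the fitted values plus
stratified random starts); $\hat\kappa$ is expected to be right-skewed when
the true concentration is large, because the von Mises shape becomes
insensitive to $\kappa$ there.

## Simulation, fixtures, and what they do and do not show

`simulate_trajectory()` runs any heading/speed pair forward; asymmetric noise
is realised constructively (von Mises draw pushed through the generating
transformation), which is also how the sampler is tested against the closed
form. Rejection sampling from a circular-uniform proposal accepts with
probability $f(x)/f_{\max}$ — normalising by the density maximum keeps the
method exact for concentrated densities whose maximum exceeds 1.

Five fixture scenarios (`make_fixture()`) emulate oriented, wind-skewed,
zigzag, tortuous and homing flights with documented true parameters; the
oriented/zigzag/wind-skew parameter values follow the simulated regimes used
to illustrate the model family (e.g. $\alpha = -\pi/8$, $w = 0.7$,
$\kappa = 6$, $r = 0.3$, $\lambda = 5\pi/8$ for the skewed flight), the
others are chosen to be realistic for a cruising seabird (10 m/s mean speed,
1-s control scale, speed noise SD 1 m/s). The generator reproduces what the
models assume: homogeneous behaviour within a section, regular sampling,
planar coordinates, stationary forcing. Passing recovery, selection and
calibration tests on these fixtures shows the estimators and tests are
correct under the model; it does not show that real trajectories satisfy the
assumptions — real data bring segmentation, stops, spatially varying wind
and projection error, which are out of scope here.

## Numerical choices

Angles live on the half-open interval $[-\pi,\pi)$ everywhere, so histogram
seams are never double-counted. The antipode of the attraction map is
evaluated by its analytic limit ($\alpha + \pi\,\mathrm{sign}(w)$), never by
`tan(pi/2)`. The scaled Bessel function $e^{-\kappa}I_0(\kappa)$ switches to
its asymptotic expansion above $\kappa = 10^5$, where the library routine
underflows. Normalisation checks integrate adaptively to $10^{-10}$; the KJ
mode is located on a 4096-point grid and refined by golden-section search;
KJ medians and quartiles are the generating-transform images of the von
Mises quantiles (the transform is monotone on the circle). Zero-length steps
have no defined heading; they are flagged `NA` and refused by the fitting
functions rather than silently assigned a direction. All stochastic
operations are reproducible from a single integer seed.

Default problem sizes in the shipped tests (2000-step recovery series, 50
replicates for selection and recovery studies, 200 replicates for
calibration at 200 simulations each, 100–200 bootstrap refits) were chosen
so the full suite exercises every claim at realistic study scale while
remaining comfortable to run routinely.

## A worked example

```{r example, eval = FALSE}
scn <- make_fixture("wind_skewed", n_steps = 2000)
traj <- simulate_trajectory(scn, seed = 6)
series <- derive_steps(traj, 1)

fits <- select_heading(series, list(heading_spec("CAR", "VM"),
                                    heading_spec("CAR", "KJ")),
                       n_starts = 8, seed = 1)
fits$table
best <- fits$fits[[1]]

speed <- select_speed(series)$best
heading_gof(series, best, n_sim = 1000, seed = 2)
final_location_gof(series, best, speed, n_sim = 1000, seed = 3)
bootstrap_mles(series, best, n_boot = 200, seed = 4)
```

## Known limitations

* No segmentation: a series is assumed to follow one model throughout.
* No continuous-time or state-switching formulation; no covariate-dependent
  concentration.
* The speed model has no stop/float phase; it describes sustained movement.
* The equirectangular lon/lat projection in `read_fixes()` is a convenience
  for kilometre-scale tracks only.
* There is no formal theory for the *exact* control time unit; the screen
  yields the smallest acceptable unit, a lower bound on the true pace.
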