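---
title: "Merging contact-pressure-biased wall-thickness studies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging contact-pressure-biased wall-thickness studies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Published measurements of abdominal-aortic-aneurysm (AAA) wall thickness
disagree systematically between groups.  A major cause is instrumentation:
contact devices (micrometers, thickness gauges) press on a radially very
compliant tissue, so a study measuring under 25 kPa of contact pressure
reports walls that are tens of percent thinner than a study using a
non-contact laser micrometer.  On top of the systematic shift, wall
thickness varies strongly both between patients and between samples from
the same patient, and some large studies publish only a mean and standard
deviation rather than raw values.  Stochastic rupture-risk analyses need
the distribution of the *undeformed* thickness -- including its thin tail
-- which no single study is large enough to estimate.

`aawt` merges such heterogeneous studies into one posterior distribution
of undeformed wall thickness.  Three ingredients do the work: a
finite-strain model of radial tissue compression, a hierarchical
lognormal population model, and an exact sampling density for studies
known only through summary statistics.

## Radial compression model

The wall is modelled as an incompressible fiber-reinforced solid of the
Holzapfel--Gasser--Ogden (HGO) family.  With principal stretches
$(\lambda_c, \lambda_a, \lambda_r)$ (circumferential, axial, radial),
$\lambda_c \lambda_a \lambda_r = 1$, the strain-energy density is

$$
\Psi = \frac{c}{2}\,(I_1 - 3) + \frac{k}{2 k_2}
\sum_{i = 4, 6}\Big(e^{k_2 (I_i - 1)^2} - 1\Big),
$$

where $I_1 = \lambda_c^2 + \lambda_a^2 + \lambda_r^2$ and
$I_4 = I_6 = \lambda_c^2 \cos^2\varphi + \lambda_a^2 \sin^2\varphi$ are
the pseudo-invariants of two symmetric fiber families inclined at
$\pm\varphi$ to the circumferential direction.  The fiber constants are
held at $\varphi = 0.546$ rad and $k_2 = 15$ for all patients; the two
stiffness parameters $c$ (ground matrix) and $k$ (fiber initial
stiffness), both in kPa, are inferred from the data because they control
compliance in the low-pressure regime where thickness measurements
operate.  The anisotropic terms carry load only when the fibers are
extended ($I_i > 1$); under radial compression the in-plane directions
expand, so the switch is a guard rather than an active regime.

A measurement at contact pressure $p$ prescribes the radial
first-Piola--Kirchhoff stress.  For a given $\lambda_r$ the in-plane
equilibrium (zero in-plane stress, traction-free lateral faces) is a
one-dimensional root-find once the hydrostatic pressure is eliminated:
$P_c = 0$ gives $p_h = \lambda_c\, \partial\Psi / \partial\lambda_c$,
and $P_a = 0$ then determines $\lambda_c$ (the two in-plane stretches
are *not* assumed equal; the fiber families make them differ).
`radial_stress()` evaluates the resulting contact pressure,
`invert_pressure()` inverts it by bracketed root-finding over
$\lambda_r \in [0.61, 1]$, the deformation range for which the model is
intended.

Because the likelihood needs $\lambda_r(c, k, p)$ at every Markov chain
Monte Carlo (MCMC) proposal, `build_response_surface()` precomputes the
inversion on a stiffness grid (defaults: $c \in [0, 10]$ kPa,
$k \in [0, 40]$ kPa, one layer per distinct pressure in the data) and
interpolates with tensor-product cubic splines.  Choices that matter:

* **Grid refinement.**  The stretch varies fastest where the fibers
  first engage (small $k$) and near the feasibility boundary, so the
  grid is power-law refined toward low stiffness (defaults: 41 nodes in
  $c$ with exponent 2.5, 81 nodes in $k$ with exponent 3).  The build
  measures its own error against exact inversion at random off-grid
  points and aborts if the maximum stretch error exceeds $10^{-3}$; the
  achieved error (a few $10^{-5}$ internally, $\sim 3\times 10^{-4}$
  worst-case near the feasibility boundary) is stored in the object.
* **Spline degree.**  Smoothness of the emulator, not a particular
  polynomial degree, is what the inference needs; C$^2$ cubic splines
  meet the fidelity contract, so no higher-order construction is used.
* **Feasibility.**  A near-zero-stiffness material cannot support 16 or
  25 kPa within the admissible deformation range.  Node inversion is
  performed on an internally wider range ($\lambda_r \ge 0.35$) so the
  stored surface stays smooth across the reporting boundary; during
  inference any parameter proposal whose implied stretch falls below
  0.61 (or hits an infeasible node, which occurs only on the $k = 0$
  grid line) is rejected with log-likelihood $-\infty$.

`equibiaxial_initial_stiffness()` converts posterior $(c, k)$ draws into
small-strain equibiaxial tangent moduli,
$E_0^{circ} = 6c + 8k\cos^2\varphi$ and
$E_0^{axial} = 6c + 8k\sin^2\varphi$, for comparison with
planar-biaxial literature values.

## Hierarchical population model

Undeformed thicknesses are modelled as
$T_{ij} \sim LN(\mu_i, \sigma_{pat})$ with patient effects
$\mu_i \sim N(\mu_{pop}, \sigma_{pop})$, so $\sigma_{pop}$ captures
inter-patient and $\sigma_{pat}$ intra-patient variability; a random
sample from the population is
$LN\!\big(\mu_{pop}, \sqrt{\sigma_{pop}^2 + \sigma_{pat}^2}\big)$.
Deformation is deterministic given the parameters:
$t_{ij} = \lambda_r(c, k, p_{ij})\, T_{ij}$.  Non-contact (laser)
studies enter with $p = 0$, i.e. $\lambda_r \equiv 1$ exactly.  The five
free parameters are $(c, k, \mu_{pop}, \sigma_{pop}, \sigma_{pat})$.

Two design choices deserve emphasis:

* **Analytic marginalization of the patient effects.**  On the log
  scale the raw-data model is linear-Gaussian given $(c, k)$: the
  adjusted values
  $y_{ij} = \log t_{ij} - \log \lambda_r(c, k, p_{ij})$ of patient $i$
  are jointly normal with mean $\mu_{pop}$ and covariance
  $\sigma_{pat}^2 I + \sigma_{pop}^2 \mathbf{1}\mathbf{1}^T$.  The
  sampler therefore targets the exact five-dimensional marginal
  posterior instead of a $(5 + n_{patients})$-dimensional joint one, and
  `patient_effects()` reconstructs exact conjugate draws of every
  $\mu_i$ afterwards.  This is a reparameterization of the same
  posterior, not an approximation, and it is what makes a random-walk
  sampler adequate here.
* **Sampler.**  `sample_posterior()` runs independent adaptive
  random-walk Metropolis chains: a scale-only warmup phase, then
  Haario-style covariance adaptation accumulated from post-burn-in
  states only, with the kernel frozen for the sampling phase.  Chains
  start at small jitters around a Nelder--Mead sharpening of the best
  of 64 prior draws.  A gradient-based sampler is unnecessary at this
  dimension, and the marginalized posterior has no funnel geometry.
  Convergence is monitored with rank-normalized split R-hat and bulk
  effective sample size; any R-hat above 1.01 flags the result (the
  draws are returned regardless -- diagnostics belong to the user).
  Random-walk kernels have no divergent-transition concept; the
  metadata reports acceptance rates and out-of-support proposal counts
  instead.

Priors default to independent uniforms on wide intervals --
$c \sim U(0, 10)$, $k \sim U(0, 40)$ kPa (the response-surface ranges),
$\mu_{pop} \sim U(0, 2)$, $\sigma_{pop}, \sigma_{pat} \sim U(0, 1)$ --
and are configurable through `prior_dist()` (normal, half-normal,
exponential families) for prior-robustness checks.

With at least two samples per patient for part of the cohort the two
variance components are separately identified; with strictly one sample
per patient only $\sqrt{\sigma_{pop}^2 + \sigma_{pat}^2}$ is, and the
posterior of the pair degenerates to a ridge.  The test suite asserts
both behaviours.

## Studies reported as summary statistics

A study reporting only $(M, S, N)$ -- sample mean, sample SD, count --
of non-contact measurements still carries information about
$\mu_{pop}$ and $\sigma = \sqrt{\sigma_{pop}^2 + \sigma_{pat}^2}$ (each
sample is treated as its own patient; for the study where 34 samples
came from 27 patients this approximation is part of the model).  There
is no closed form for the joint sampling density of $(M, S)$ of
lognormal samples, so `joint_mean_sd_density()` computes it exactly up
to quadrature:

1. the characteristic function $\phi(u, v) = E\,e^{i(uT + vT^2)}$ of
   $(T, T^2)$ by trapezoid quadrature on a lognormal support truncated
   at tail probability $10^{-8}$ and renormalized;
2. $\phi^N$, by the convolution theorem the characteristic function of
   $V = (\sum T_i, \sum T_i^2)$;
3. inversion as a two-dimensional Fourier series on a window covering
   the mean of $V$ plus 9 standard deviations below and 13 above
   (asymmetric because the $T^2$ sum is right-skewed);
4. the change of variables $V_1 = NM$, $V_2 = (N-1)S^2 + NM^2$ with
   Jacobian $2N(N-1)S$.  $S$ uses the $n-1$ convention throughout.

The frequency grid is $192^2$; the quadrature grid adapts so the fastest
oscillation $u_{max} + 2 v_{max} t_{max}$ is resolved by at least four
points per half-period.  The captured probability mass is checked
against 1 (tolerance 0.01) and the density matches a $10^6$-replicate
Monte-Carlo histogram to a few percent in the bulk.  Accuracy degrades
for $\sigma \gtrsim 0.9$, where the $T^2$ sum becomes too heavy-tailed
for a Gaussian-width window; combined scales that large are treated as
having zero summary-study likelihood, which is immaterial for data whose
coefficient of variation is far smaller.

Inside MCMC the summary-study term is a precomputed interpolant:
`loglik_surface()` evaluates $\log f(M_k, S_k; \mu_{pop}, \sigma)$ on a
$100 \times 100$ grid (one characteristic-function build per $\sigma$
value -- the lognormal scale family makes $\mu$ a pure rescaling) and
interpolates.  Because the log-density spans hundreds of nats between
peak and underflow floor, splining it directly overshoots
catastrophically at the cliff; the interpolant instead splines
$q = -\sqrt{2(\max \log f - \log f)}$, which is conical rather than
cliff-like, and maps back as $\log f = \max - q^2/2$.  This bounds the
interpolant above by the true grid maximum, so it cannot invent
spurious likelihood peaks; near the mode it is accurate to well under
1%, while on the super-quadratic flank several nats below the peak it
is only qualitatively accurate -- acceptable, because those regions are
dominated by the raw-data likelihood.

`pool_subset_stats()` merges the published male/female or thin/thick
subset statistics into exact whole-study statistics before any of this.

## Predictive distribution and corrections

`posterior_predictive()` propagates the full posterior: per retained
draw, a new patient and a new sample are simulated.
`fit_lognormal_approx()` moment-matches a lognormal on the log scale --
the simplest estimator consistent with reporting the predictive as
$LN(\mu, \sigma)$ for downstream rupture-risk analyses -- and
`tail_probability()` evaluates $100\,\Phi((\ln t_1 - \mu)/\sigma)$, the
percent probability of a wall thinner than $t_1$.

`undeform_study()` divides measured thicknesses by
$\lambda_r(c, k, p)$.  Both a point mode (posterior medians of $(c, k)$;
the default) and a draw-averaged mode (mean of $t/\lambda_r$ over a
posterior subsample) are provided, because either convention is
defensible for a table of corrected study means; on synthetic data they
agree to well under the sampling noise.  `shift_metrics()` reports the
max--min range of study means and medians before and after correction.
`theoretical_quantile_boxplot()` builds boxplot statistics from
$n$ theoretical quantiles at plotting positions $i/(n+1)$ (default
$n = 98$, a typical study size), the device that makes raw-data studies
and distribution-only studies comparable in one figure; the residual
$\sim 0.5\%$ quartile offset against a dense quantile grid is the
plotting-position convention, not an error.

## Synthetic cohorts

`six_study_design()` encodes the multi-study structure the model is
built for: six studies at contact pressures (0, 0, 25, 0, 16, 1) kPa
with raw-sample counts 39, 251, 90, 92 (472 raw measurements), two
studies reduced to summary statistics ($N = 34$ and $N = 90$), and a
shared pool of 34 patients between the 16 kPa and 1 kPa studies -- the
same-patient, different-pressure pairs are what identify the radial
stiffness.  Generating truth defaults to $\mu_{pop} = 0.85$,
$\sigma_{pop} = 0.26$, $\sigma_{pat} = 0.18$ (log-mm) and mid-range
stiffness $c = 5$, $k = 20$ kPa.  `generate_cohort()` simulates the
generative model exactly -- there is no residual measurement-error term
on $t_{ij}$, matching the model's own idealization -- with every patient
receiving at least one sample and remaining samples assigned uniformly
at random.

What passing on such cohorts does and does not show: the generator
reproduces the model's statistical structure (hierarchy, pressure
shifts, summary-only reporting, patient sharing) but none of the ways
real tissue departs from it -- calcifications stiffening individual
samples, fixture friction, patient-level covariates, or laser
surface-definition bias.  Recovery on synthetic data validates the
inference machinery, not the constitutive idealizations.

## Problem sizes and numerical defaults

Desk-scale inference (the package default and what the test suite and
acceptance script run) uses 4 chains of 2,000 retained draws after
1,500--2,000 adaptation iterations; a `paper_scale` flag switches to 20
chains of 10,000 draws.  The calibration checks fit 10 replicate
six-study cohorts at desk scale and require the generating parameters
inside their 95% credible intervals in at least 9; the joint five-
parameter coverage of equal-tailed 95% intervals is, as expected,
slightly below $0.95$ per run, and desk-scale quantile noise (bulk ESS
of a few hundred) contributes a small additional miss rate.  The
Monte-Carlo oracle for the summary-statistics density uses $10^6$
replicates compared on a $16 \times 16$ bulk histogram with
bin-averaged theoretical values, so that Monte-Carlo noise
($\sim 1.5\%$ per bin) stays well inside the 5% comparison band.
Root-finds use Brent's method with tolerance $10^{-8}$ on stretches;
degenerate inputs (zero-stiffness material, $\sigma_{pat} = 0$ with
disagreeing replicates, pressures outside the calibrated range) are
rejected with explicit errors rather than extrapolated.

## Known limitations

* The constitutive constants $\varphi$ and $k_2$ are fixed population
  values; $(c, k)$ are shared by all patients.  With only a few distinct
  pressures the $(c, k)$ posterior is a pronounced ridge -- many
  stiffness pairs produce nearly the same stretches at the observed
  pressures -- so stiffness intervals are wide even when the thickness
  parameters are sharp.
* The summary-statistics density is unreliable for log-scale
  $\sigma \gtrsim 0.9$ (treated as zero likelihood there).
* Corrections assume the calibrated deformation range
  $\lambda_r \in [0.61, 1]$; pressures that would compress a proposed
  material further are rejected rather than extrapolated.
* The sampler is a random-walk kernel: adequate for the marginalized
  five-parameter posterior, but the effective sample size per draw is
  far below a gradient-based sampler's, which is why defaults retain
  8,000 draws.
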