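---
title: "Choosing experimental designs for Bayesian model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing experimental designs for Bayesian model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmsdesign)
```

## The problem

Bayesian model selection picks, among a set of candidate generative models
$\mathcal{M} = \{m_1, \dots, m_M\}$ with priors $p(m)$, the model with the
highest posterior probability given data $y$ acquired under an experimental
design $u$. Because $y$ is a random sample, the selection can be wrong, and
the probability of selecting wrongly depends on the design: a design under
which the candidate models predict very different data makes errors rare.
`bmsdesign` scores candidate designs *before* any data are collected by an
information-theoretic proxy of the selection error rate, and provides the
simulation and inversion machinery needed to validate that score for small
network models of neuroimaging time series.

## The risk and its bounds

For each model, the *prior predictive density* $p(y \mid m, u)$ is the
distribution of datasets the model expects under design $u$, obtained by
integrating the likelihood over the parameter prior. The dissimilarity of
the set of predictive densities is measured by the Jensen–Shannon
divergence
$$
D_{JS}(u) \;=\; H\!\Big[\textstyle\sum_m p(m)\, p(y \mid m, u)\Big]
\;-\; \sum_m p(m)\, H\big[p(y \mid m, u)\big],
$$
the entropy of the prior-weighted mixture minus the average entropy. It is
symmetric, non-negative, zero iff all densities coincide, and (in base-2
logarithms, used throughout) bounded by the entropy $H(m)$ of the model
priors — 1 bit for two equiprobable models. The selection error rate
$p(e \mid u)$ is sandwiched by Lin-type (Chernoff) bounds,
$$
\frac{\big(H(m) - D_{JS}\big)^2}{4\,(M-1)} \;\le\; p(e \mid u) \;\le\;
\frac{H(m) - D_{JS}}{2},
$$
so maximizing $D_{JS}$ with respect to $u$ minimizes both bounds.

For nonlinear Gaussian models $y = g_m(\theta, u) + \varepsilon$, with
$\theta \sim N(\eta_m, \Sigma_\theta)$ and
$\varepsilon \sim N(0, \Sigma_\varepsilon)$, the predictive moments follow
from a first-order Taylor expansion around the prior mean:
$$
\mu_m = g_m(\eta_m, u), \qquad
Q_m = J_m \Sigma_\theta J_m^{\top} + \Sigma_\varepsilon ,
$$
with $J_m$ the Jacobian at $\eta_m$. Approximating the mixture entropy by
the entropy of the moment-matched Gaussian gives a closed-form divergence
$D_{JS}^{L}$ computed purely from $\{\mu_m, Q_m\}$, and the
**Laplace–Chernoff risk**
$$
b_{LC}(u) \;=\; H(m) - D_{JS}^{L}(u) .
$$
Low risk means a discriminative design. For two equiprobable models with
equal predictive covariance $Q$ the risk reduces to a contrast-resolution
measure, $b_{LC} = 1 - \tfrac{1}{2}\log_2\!\big(1 + \Delta g^2 / 4Q\big)$,
which tends to its maximum of 1 bit as the mean contrast $\Delta g$
vanishes or $Q$ diverges.

**Reporting convention.** $D_{JS}^{L}$ is an approximation and can exceed
$H(m)$ when the models are highly discriminable; $b_{LC}$ is then negative
and the upper error bound is no longer valid. We deliberately report the
risk *unclipped* — negative values are meaningful for ranking designs —
and set `valid = FALSE` in the `risk_report` (with a warning) rather than
silently truncating. The quadrature oracle `exact_error_rate_1d()` shows
(and the test suite asserts) that the risk remains strictly co-monotone
with the exact error rate even where the bound itself has broken down, so
ranking designs by $b_{LC}$ stays safe.

## The general linear model special case

For a GLM $y = X\theta + \varepsilon$ with i.i.d. $N(0, v)$ priors, testing
the contribution of one column reduces to comparing the full design against
the design with that column removed. The risk has the closed form
`glm_risk()`; `classical_efficiency()` implements the classical
C-optimality efficiency (the inverse variance of the maximum-likelihood
contrast estimate). As $v \to \infty$ the risk becomes a decreasing
function of the classical efficiency, so at the non-informative limit the
two criteria select the same design — realized numerically at
$v = 10^6 \sigma^2$ in `frequentist_limit_ranking()`. General contrast
vectors are handled by an orthonormal rotation of $X$ that maps the
contrast onto a single column; an orthonormal rotation leaves the isotropic
prior invariant, which is why the single-column machinery applies
unchanged.

## The network forward model

`dcm_spec()` defines a deterministic bilinear network model: neural states
$x$ evolve as
$$
\dot x = \Big(A + \sum_j u_j B^{(j)} + \sum_k x_k D^{(k)}\Big) x + C u ,
$$
with between-region coupling $A$ (Hz), input-dependent modulations
$B^{(j)}$, driving gains $C$ and optional gating matrices $D^{(k)}$ (off by
default — every built-in scenario is purely bilinear). Each region adds a
four-state balloon cascade (vasodilatory signal, inflow, venous volume,
deoxyhemoglobin) and a static BOLD observation in percent signal change —
five states per region in total. Balloon constants follow the standard
published conventions (signal decay 0.64 s⁻¹, autoregulation 0.32 s⁻¹,
transit time 2 s, stiffness exponent 0.32, resting extraction 0.32,
resting volume fraction 0.04), all overridable; they are a community
convention here, not estimated quantities.

Self-connections are fixed at $-1$ Hz unless explicitly freed, which
guarantees prior-mean stability. Free parameters are the masked neural
entries (prior mean = their specification values), per-region log-scale
multipliers of hemodynamic decay and transit time, and per-region
log-scale BOLD gains (prior mean 0); all carry i.i.d. Gaussian shrinkage
priors with variance 1 by default. Integration is fixed-step fourth-order
Runge–Kutta at `dt = 0.1` s (compiled code), with inputs held constant over
each microtime step and scans sampled every `TR = 1.3` s. The test suite
asserts self-convergence: halving `dt` changes the sampled BOLD by well
under 0.1% RMS.

## Variational-Laplace inversion

`invert_vl()` fits a fixed-form Gaussian posterior over the parameters and
a Gamma posterior over the residual precision by coordinate ascent on the
free energy, a lower bound on the log evidence (reported in nats). The
Gauss–Newton step is Levenberg-regularized; steps that would decrease the
free energy are rejected and retried with a stronger regularizer, so the
accepted-iteration trace is non-decreasing by construction. Convergence is
declared at $|\Delta F| < 10^{-2}$ nats (configurable), capped at 64
iterations. For a linear mapping with known precision the converged free
energy equals the exact log marginal likelihood (asserted to $10^{-3}$
nats), and posterior covariances never exceed the prior in Löwner order.
Model posteriors are a max-stabilized softmax of free energy plus log
prior, with ties broken by the lowest index so that selections are
deterministic.

Jacobians are computed by finite differences with per-parameter step
$\max(10^{-4}, 10^{-4} |\eta_i|)$: central differences for design-risk
predictives, forward differences inside the Gauss–Newton loop (half the
integration cost; the slight loss of Jacobian accuracy only perturbs the
ascent direction, not the fixed point). A sensitivity-equation variant was
considered and not implemented; finite differences are mapping-agnostic,
which keeps user-supplied observation mappings first-class.

## What the synthetic data emulate — and what they do not

`simulate_dataset()` produces two-region BOLD-like series: deterministic
forward dynamics driven by on/off inputs plus i.i.d. Gaussian noise of a
stated precision. The built-in study conditions are: 5-minute sessions,
TR 1.3 s, onset jitter SD 2 s, balanced factorial input conditions, and
two residual-precision levels $\{0.1, 0.3\}$ — chosen once so that the
lower level sits near the realistic ~1 dB signal-to-noise ratio for this
simulator's signal variance, the higher near 6 dB. Where a quantity needed
by a scenario is not available in printed form (the coupling-prior grid
$\{0.2, 0.6\}$, input-correlation levels $\{0, 0.5, 0.9\}$, the fixed 40-s
inter-block interval of the epoch-duration sweeps, the PPI model
structures), the values are reconstructed, documented here, and held
fixed.

Real fMRI differs in ways the generator does not emulate: serially
correlated and low-frequency drifting noise (we use white noise),
scanner/physiological confounds, regional hemodynamic variability beyond
the two freed parameters, and between-subject variability (everything here
is within-"subject"). Passing tests therefore show internal consistency of
the method and reproduction of the qualitative design prescriptions under
idealized noise — not performance guarantees on empirical data.

## Numerical choices

- **Positive-definiteness repair:** predictive covariances are
  symmetrized and, if a Cholesky factorization fails, ridged by
  $10^{-10}\,\mathrm{tr}(Q)/n$ (escalating, with a warning). Long sessions
  make $Q$ ill-conditioned; the ridge is far below the noise floor.
- **Family comparisons:** a family's predictive is the prior-weighted
  mixture of its members' predictives, collapsed to its moment-matched
  Gaussian before the risk formula; the report's `method` field records
  the collapse, and a stratified Monte-Carlo mixture divergence is
  available as a cross-check (the tests assert both rank designs
  identically).
- **Monte-Carlo divergence:** stratified sampling from the mixture,
  default $10^5$ samples, mandatory seed, standard error attached.
- **Quadrature oracles:** 1-D only; error-rate integration is done per
  model over ±12 SD windows so widely separated components are not missed.
- **Tie-breaking:** model selection uses the lowest index on ties,
  everywhere.
- **Degenerate inputs:** zero prior covariance reduces the predictive to
  the noise covariance; zero free parameters reduce the free energy to
  the expected log likelihood; exactly collinear GLM contrasts return
  efficiency 0 with a warning rather than an error.

## Problem sizes

The packaged experiments are sized for a single CPU: the Monte-Carlo
validation uses the matched-input scenario at one coupling level, three
input-correlation levels, two noise precisions and 8 residual realisations
(96 simulated datasets, each inverted under both models); epoch-duration
sweeps use 4 jittered designs per grid point on a 5-epoch grid; the
parameter-recovery study uses 20 high-SNR repetitions. Each piece scales
up by its explicit arguments (`n_noise_reps`, `n_jitter_draws`, grids).

## Known limitations

- The Laplace predictive linearizes the forward model at the prior mean;
  strongly nonlinear regimes (large couplings, long epochs) inflate
  $D_{JS}^{L}$ and break the upper bound early. Rankings remain reliable;
  absolute error-rate estimates do not, except for weakly discriminable
  comparisons.
- Precision hyperparameter uncertainty is not propagated into the
  predictive covariance (the expected precision is used), and
  unscented-transform predictives are out of scope.
- Designs are ranked within a fixed model set; hierarchical group-level
  variability and adaptive/online design optimization are out of scope.
- Session segments in `split_analysis()` are re-integrated from rest,
  which slightly mis-states the first few scans of interior segments.
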