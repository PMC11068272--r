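---
title: "Coalescent skyline plot models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent skyline plot models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalsky)
```

## The coalescent density

`coalsky` treats a time-calibrated genealogy — tip sampling ages plus
internal coalescent times, time running backward from the present — as
data, and the effective population size trajectory $N_e(t)$ as the unknown.
With $k(t)$ active lineages the total coalescent rate is
$c(t) = k(t)(k(t)-1) / (2 N_e(t))$: each of the $\binom{k}{2}$ lineage
pairs coalesces at rate $1/N_e(t)$.  Sampling events increase $k$ by one
(coincident samples are merged into one event), coalescences decrease it by
one, and trajectory change-points leave it unchanged.

The log density of the genealogy sums, over consecutive events of the
merged timeline, the log probability of no coalescence
$-\int c(t)\,dt$, plus $-\log N_e(u_j)$ at each coalescent event (the
point-mass factor $\tfrac{2}{k(k-1)} c(u_j)$ simplified algebraically).
Both per-interval demographic functions make the integral analytic:

* constant: $\int_a^b c = k(k-1)(b-a)/(2\rho_i)$;
* linear with slope $\alpha_i$: $k(k-1)/(2\alpha_i)\,
  \log\!\big(1 + \alpha_i (b-a)/N_e(a)\big)$, implemented with `log1p` so
  the $\alpha_i \to 0$ limit degrades gracefully to the constant formula
  (a naive `log` ratio loses all precision below $|\alpha| \approx
  10^{-8}$).

Intervals are left-closed/right-open, $[x_i, x_{i+1})$, so $N_e(0)$ is
always defined and a coalescent event lying exactly on a change-point uses
the older interval's size; beyond the last change-point the trajectory is
constant at $\rho_L$.  Ties in the timeline are ordered sampling <
coalescent < change-point, which keeps $k \ge 2$ at coalescent events in
degenerate ties.  The event-product bounds are read as covering *all*
consecutive event pairs and all coalescent events — the only reading under
which the two-tip density integrates to one, which the suite verifies by
quadrature to $10^{-6}$.

Population sizes are in the genealogy's own time units (the density
estimates $N_e$ directly, not $\theta = 2 N_e \mu$) and no ploidy factor is
applied; users rescale externally if needed.

## Change-point schemes

Two schemes cover the published model families. In the `events` scheme,
change-points co-occur with coalescent events: the $n-1$ events are grouped
most-recent-first with a fixed group size (five for the skyline/BSP layout,
$\lceil (n-1)/5 \rceil$ intervals with the final group absorbing the
remainder; one per event for the Skyride/EBSP layout).  The grouping is
deterministic — the historically implicit multinomial distribution on
events per interval is not modeled, matching how these analyses are run in
practice and keeping the probabilistic graph acyclic.  In the `specified`
scheme, change-points are fixed independently of the genealogy, most
commonly as an equal grid on $[0, t_{\max}]$.

Event-based schemes are intrinsically single-genealogy: gene trees from
different loci have different coalescent times and hence would induce
different demographic histories.  `multilocus_log_density()` and
sequential inference therefore refuse the `events` scheme.

## The nine prior models

All priors are densities with respect to the natural $\rho$ scale (models
stated on the log scale enter as lognormals).  Default hyperparameters are
deliberately broad: $\mathrm{Uniform}(0, 10^8)$ for uncorrelated sizes,
$\mathrm{Loguniform}(10^{-2}, 10^8)$ for the first interval of the
autocorrelated chains, $\mathrm{Gamma}(0.001, 0.001)$ on the precision
$\tau$ (mean 1, variance 1000), standard half-Cauchys on the global and
local scales of the Markov-random-field models, and the smoothing
constants $\zeta = 0.0195$ (GMRF) and $\zeta = 0.0051$ (HSMRF), which
calibrate the a-priori expected variation for 50 intervals; `coalsky`
treats $\zeta$ as a configuration constant and does not re-derive it for
other interval counts.

Interpretation choices that the model statements leave open, and how they
were resolved:

* **Skyride/Skygrid** `Lognormal(rho_i, 1/tau)` is read with location
  $\ln \rho_i$ and *variance* $1/\tau$: the Gamma(0.001, 0.001) hyperprior
  is the classic precision prior of these models.
* **BSP** `Exponential(1/rho_i)` is rate $1/\rho_i$ (mean $\rho_i$) —
  forced by the autocorrelation intent.
* **Skyfish** $\sigma \sim \mathrm{Exponential}(t_{\max}/8)$ is read as
  *rate* $t_{\max}/8$ (mean $8/t_{\max}$): with increment standard
  deviation $\sigma\,(\xi_{i+1}-\xi_i)$, this produces order-one log-size
  jumps across $t_{\max}$-scale gaps, whereas the mean-$t_{\max}/8$ reading
  would produce $e^{10^{10}}$-scale jumps.  The increment sd is the
  literal product $\sigma \Delta\xi$ (not Brownian $\sqrt{\Delta\xi}$
  scaling), and $\rho_1 \sim \mathrm{Lognormal}(\ln(t_{\max}/4), 2H)$ with
  $H = 0.587405$, the half-spread for which a lognormal's central 95%
  spans two orders of magnitude (`skyfish_h()` computes
  $H = \log(10^2) / (2\,z_{0.975}) / 2$ from first principles).
* **Skyfish change-points** are stored sorted, with the order-statistics
  factor $\kappa!/t_{\max}^\kappa$ in the prior, consistent with iid
  $\mathrm{Uniform}(0, t_{\max})$ draws.
* **EBSP** follows the binomial reversible-jump formulation: each
  candidate change-point (one per coalescent event) is independently free
  with probability $\alpha_{\mathrm{eq}}$, so the number of distinct
  intervals is $1 + \mathrm{Binomial}(n-2, \alpha_{\mathrm{eq}})$.  Two
  constants are not fixed by the published formulations and are package
  choices, both exposed in configuration: $\alpha_{\mathrm{eq}} = 0.5$
  (indifference) and a $\mathrm{Loguniform}(10^{-2}, 10^8)$ hyperprior on
  the mean $1/\lambda$, consistent with the size ranges of the other
  models.
* **GMRF/HSMRF** keep the printed $\mathrm{Uniform}(0, 10^8)$ on
  $\rho_1$ (contrasting the Loguniform used by BSP/Skyride) and the
  literal sd products $\gamma\zeta$ and $\sigma_i\gamma\zeta$.

## MCMC design

One sweep applies a multiplier (scale) proposal to every free population
size and every positive hyperparameter, a reflected sliding move to each
Skyfish change-point, and one reversible-jump move (Skyfish birth/death or
EBSP tie toggle).  Scale proposals are
$\rho' = \rho\, e^{\delta (u - 1/2)}$ with Hastings ratio $\rho'/\rho$;
proposal widths adapt toward 0.44 acceptance during burn-in only and are
frozen afterwards, preserving detailed balance for the retained samples.
Chains initialize from the prior; up to 1000 redraws are attempted before
declaring the posterior degenerate.

The Skyfish birth move draws $\xi^* \sim \mathrm{Uniform}(0, t_{\max})$
and the new interval's log size from a normal centered on the current
$\log N_e(\xi^*)$; death removes a uniformly chosen change-point.  The
acceptance ratio combines the exact prior ratio (obtained from log-prior
differences, which automatically accounts for the Poisson, order-statistics
and increment terms), the proposal densities, and a unit Jacobian (the new
coordinates are drawn directly).  These proposal choices are validated by
prior recovery — a likelihood-free run reproduces the $\mathrm{Poisson}(10)$
change-point distribution (chi-square on the pmf) — rather than by matching
any external sampler's internals.  The EBSP toggle draws activations from
the exponential prior itself, so prior and proposal densities cancel and
the acceptance reduces to the $\alpha_{\mathrm{eq}}$ odds times the
likelihood ratio.

For fixed change-points in constant mode the likelihood collapses to a
sufficient structure — per-interval hazard weights
$W_i = \sum k(k-1)/2 \cdot \mathrm{width}$ and coalescent counts $m_i$,
giving $\ell(\rho) = -\sum_i W_i/\rho_i - \sum_i m_i \log \rho_i$ — and for
Skyfish the genealogy is summarized once by its piecewise-linear cumulative
pair-hazard profile $F(t)$, so that arbitrary change-point configurations
cost $O(L + n)$ per evaluation.  Both fast paths are tested for exact
agreement with the generic segment-by-segment density.

Replicates run with seeds `seed + r - 1`; each records every
`thinning`-th iteration and discards its leading burn-in fraction before
pooling, so 100,000 iterations, thinning 10, 10% burn-in and two
replicates retain 18,000 samples.  Convergence is checked by the
Kolmogorov–Smirnov distance between replicate samples of $\log N_e$ at
each grid time; the published diagnostic's threshold is not specified, so
0.05 is the exposed default.  The deep, prior-dominated past mixes slowly
and at scaled-down chain lengths routinely fails this strict check — that
is a true positive, not a defect.

## Marginal likelihoods

Stepping-stone estimation runs a ladder of power posteriors
$L^{\beta}\pi$ with $\beta_i = (i/(K-1))^{1/0.3}$ — quantiles of
$\mathrm{Beta}(0.3, 1)$, the customary spacing that concentrates stones
near the prior — warm-starting each stone from the previous one, and
assembles $\log \hat{Z} = \sum_k \log \frac{1}{N}\sum_j
e^{(\beta_{k+1}-\beta_k)\,\ell_{jk}}$ (max-shifted).  The default ladder is
128 powers (127 power posteriors plus the prior stone) at 5,000 iterations
each.  Only proper priors are accepted: unbounded uniform or log-uniform
limits raise an error before any sampling.  On a two-tip genealogy with a
bounded uniform prior the estimate agrees with direct one-dimensional
quadrature to well under 0.1 log units at 64 stones.

## Simulator

Genealogies are simulated by exact inversion: a standard exponential
deviate is matched against the cumulative hazard, accumulated through
sampling events and change-points with the realized $k(t)$ (valid by
memorylessness), and inverted analytically inside each segment (constant:
$w = 2\rho E/(k(k-1))$; linear: $w = N_e(a)(e^{2\alpha E/(k(k-1))} -
1)/\alpha$ via `expm1`).  A thinning (rejection) sampler exists in the test
suite purely as an independent oracle.  The central cross-validation of the
package simulates $10^4$ three-tip genealogies under a two-interval
trajectory and compares their binned $(t_2, t_1)$ distribution against
bin masses integrated from $\exp(\log\text{density})$ (the factorized
integrand is itself verified pointwise against the density to $10^{-12}$),
by chi-square.

Sequence fixtures evolve sites independently under Jukes–Cantor.  The
fixture scenarios emulate two study designs: 36 isochronous tips, and 173
tips of which 137 have ages drawn uniformly on (0, 50,000) — the real
serially sampled ages they stand in for are not reproduced, so these ages
are synthetic by construction.  Fixture sequences use length 16,000 and a
clock of $10^{-7}$ per site per generation, giving roughly 2% pairwise
diversity at the default $N_e = 10^5$ — a mitochondrial-genome-like
configuration.  The two truth trajectories are a constant $N_e = 10^5$ and
a "recent peak" shape (80,000 rising to 250,000 around 5,000–25,000 time
units ago, then 120,000 in the deep past), representing the two
qualitative regimes the model comparison distinguishes.  What the
simulator deliberately omits: recombination, migration and population
structure, ancient-DNA damage, and any direct tie between simulated
sequences and inference (inference here is from genealogies; joint
tree-and-demography estimation from alignments is out of scope).  Passing
tests therefore demonstrate correctness of the coalescent machinery, not
robustness to real-data violations of panmixia or clock assumptions.

## Numerical choices and degenerate inputs

* All probability computations are in log space; the sequential
  (importance-averaged) likelihood over genealogy samples uses a
  max-shifted log-mean-exp.
* Heavy-tailed hyperpriors ($\mathrm{Gamma}(0.001, 0.001)$ precision,
  half-Cauchy scales) place most of their mass at precisions so small that
  ancestrally sampled trajectories overflow double precision; such draws
  have zero posterior density and are simply redrawn at initialization.
  Prior-recovery tests for those models condition on the global scale;
  free-hyperparameter recovery is tested where doubles can represent the
  prior (constant, skyline, BSP, EBSP, GMRF increments, Skyfish).
* Summaries evaluate $N_e$ sample-wise on the grid and then take type-7
  quantiles (linear interpolation of order statistics) — quantiles of the
  curve, not curves of parameter quantiles — which is how skyline
  envelopes are conventionally drawn.
* The reporting grid is "exponentially spaced between 0 and
  $t_{\max}$"; literal log spacing is undefined at 0, so the grid is
  equally spaced in $\log(1+t)$, including both endpoints.  This affects
  plotting resolution only, never inference.
* Tip ages are authoritative when reading genealogies; branch lengths are
  validated against them with a $10^{-6}$ relative tolerance and
  zero-length or negative branches are rejected.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen once as the smallest sizes
at which each statistical property is decisive: prior recovery of the
Skyfish change-point count from 150,000 prior-only iterations (acceptance
script) or 60,000 (test suite); $10^4$ replicate simulations for the
simulator/density chi-square; 50,000-iteration chains for the grid-posterior
total-variation check; 50 seeded 36-tip data sets for coverage; 64 stones
for the stepping-stone benchmark; and ten 36-tip data sets at
8,000–10,000 iterations for the BSP-versus-Skyfish near-present contrast.

## Known limitations

Joint inference of the genealogy from sequence alignments is out of scope
(the sequence simulator exists for validation and fixture generation
only).  Event-based models cannot pool loci, by construction.  The
$\zeta$ constants are valid for 50 intervals only.  RJ proposals are
validated against the prior, not against any external implementation's
proposal internals.  The EBSP free constants and the heterochronous
fixture ages are package choices, documented above.
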