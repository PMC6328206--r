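---
title: "Methods: the switching movement model and its pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the switching movement model and its pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the tunable constants with their defaults and units, the
design decisions taken where the method family leaves choices open, and the
limits of what the synthetic-data tests demonstrate.

## The movement model

Argos telemetry of large whales delivers a handful of noisy fixes per day
at irregular times, each stamped with a location class (LC) in
{3, 2, 1, 0, A, B, Z} that encodes nominal accuracy from under 200 m (LC 3)
to worse than 5 km (LC B); LC Z has unbounded error. The package infers one
true position per day from such data with a two-mode switching
first-difference correlated random walk (DCRWS) state-space model.

**Process.** With daily positions $x_t$ in raw lon/lat degrees and
displacements $d_t = x_t - x_{t-1}$,

$$ d_t \mid b_t \sim \mathcal{N}_2\!\left(\gamma_{b_t}\, T(\theta_{b_t})\,
   d_{t-1},\ \Sigma\right), $$

where $T(\theta)$ is the rotation matrix, $\gamma_k \in (0,1)$ the move
persistence and $\theta_k$ the mean turning angle of mode $k$, and $\Sigma$
a full 2×2 process covariance (deg²). The behavioural mode $b_t \in \{1,2\}$
is a two-state Markov chain with switching probabilities
$\alpha_1 = P(1\to1)$, $\alpha_2 = P(2\to1)$. Mode 1 is transiting, mode 2
area-restricted searching (ARS); the ordering $\gamma_1 > \gamma_2$ is
imposed for identifiability (transiting is the more persistent mode). The
first displacement gets a diffuse zero-mean Gaussian prior with covariance
$\kappa\Sigma$, $\kappa = 100$; the first two states are initialised at the
first fix.

**Observation.** The daily grid is anchored at the first retained fix's
timestamp with a 24-h step; the final partial day is dropped. A fix at time
$t_i$ falls in the interval $[k_i, k_i+1)$ with fraction
$j_i = (t_i - \text{node}_{k_i})/24\,h$, and each coordinate is

$$ y_i = (1-j_i)\,x_{k_i} + j_i\,x_{k_i+1} + \varepsilon_i, \qquad
   \varepsilon_i \sim \tau_{LC}\, t_{\nu_{LC}}, $$

component-wise with LC-specific scale and degrees of freedom. A fix landing
exactly on the final node is assigned to the last interval with $j = 1$, so
a track spanning exactly $k$ days keeps its closing fix; this is the one
point where $j$ leaves $[0,1)$.

**Error-model defaults.** The per-LC scales ship as an editable
configuration table (degrees; latitude slightly tighter than longitude)
spanning roughly 0.15 km (LC 3) to 9 km (LC B) at mid latitudes, with
$\nu$ from 10 (LC 3) down to 3 (LC Z) so poorer classes get heavier tails.
These are field-plausible defaults for marine Argos deployments, not
constants asserted from any particular error study, and should be tuned per
deployment.

## Priors and sampler

Priors are weakly informative and standard for this family:
$\theta_k \sim U(-\pi, \pi)$; $(\gamma_1, \gamma_2)$ uniform on the ordered
unit square $\gamma_1 > \gamma_2$; $\alpha_k \sim U(0,1)$; half-normal
(scale 1°) on the process SDs and $U(-1,1)$ on the process correlation.

The sampler is Metropolis-within-Gibbs written for this model (C++ core):

* each daily state gets a bivariate isotropic random-walk proposal, with
  only the local likelihood terms re-evaluated;
* the discrete modes are drawn exactly from their full conditionals
  (process term plus both adjacent transitions);
* each scalar parameter gets a random-walk proposal; turning angles wrap on
  the circle, and proposals leaving the prior support are rejected, which
  is how the $\gamma$ ordering is enforced;
* proposal scales adapt in batches of 50 iterations toward 44% acceptance
  during burn-in only, so the retained chain is a fixed Markov kernel.

Chains start overdispersed: states at the fix interpolation plus
chain-scaled jitter, parameters drawn from their priors (chain seeds are
`seed + chain`). Defaults are two chains × 30,000 iterations, 10,000
burn-in, thinning by 5 — exactly 4,000 retained samples per chain.
Per-sample deviance is $-2\times$ the observation log-likelihood; the
reported track deviance $D$ is its posterior mean, and
$\mathrm{DIC} = D + p_D$ with $p_D = D - D(\bar{x})$, the plug-in deviance
at the posterior mean states. Defining the deviance on the observed fixes
(not the latent process terms) matches how general-purpose Gibbs samplers
report DIC for state-space models and makes $D$ negative at degree scale,
since the t log-densities are positive there; $D$ is therefore comparable
across tracks fitted by this package but not across data scales.

## Prefilter interpretation

Three rules run in the order class-Z removal, 20-minute quality rule,
duplicate removal. Two readings were fixed where the rule family is
ambiguous:

* the 20-minute window is two-sided (a low-quality fix is suppressed
  whether it precedes or follows the high-quality fix) and inclusive at
  exactly 20 min; the window length is configurable;
* a duplicate is a fix identical in (platform, timestamp, lon, lat); the
  best location class wins, ties broken by first occurrence.

The rule is applied across all fixes of a platform, not within satellite
passes, and the composition is idempotent.

## Convergence QC

The visual checks used in practice (trace randomness, distribution shape)
are implemented as quantitative proxies: a potential-scale-reduction-style
two-chain agreement ratio (≈1 means agreement; two identical chains give
$\sqrt{(n-1)/n}$, i.e. 1 within 10⁻³ at $n = 4000$) and a largest-gap
unimodality screen on sorted samples. Both thresholds are the caller's
choice; the package does not hard-code a cutoff.

Six per-track data metrics feed the deviance regressions: (a) mean filtered
locations per day, (b) their SD, (c) the Argos:SSM location ratio, (d)
total tracking days, (e) total filtered locations, (f) e/d. The denominator
of (a) is the number of days with at least one filtered location — the
only reading under which (a) and (f) are distinct metrics, and the one
consistent with published per-tag "locations per day" values that exceed
total/days. Tracking days (d) count first to last fix date inclusive.
Track exclusion defaults to a threshold of 10 total filtered locations,
the metric that regression identifies as driving deviance; the regression
itself is ordinary least squares via `lm()`, reporting $R^2$, $F$ and $p$.

## Land correction

The daily estimates are not land-aware, so a narrow gulf coastline leaves
some of them on land. Each on-land day is relocated to the area centroid of
the ocean portion of its 95% credible ellipse:

* the ellipse is axis-aligned in degree space — longitude semi-axis = 95%
  credible half-width in longitude, latitude semi-axis = half-width in
  latitude — regardless of which half-width is larger, since the method
  needs the axis assignment, not a magnitude ordering;
* "95% credible limits" are read as half-widths (centre ± half-width spans
  the equal-tailed interval), which is what an ellipse centred on the
  estimate requires;
* geometry runs in a local equidistant planar frame about the ellipse
  centre (longitude scaled by cos latitude), because degree-space areas are
  anisotropic; the centroid is mapped back afterwards;
* the clipped region is integrated by horizontal slabs (default 720) with
  the exact ellipse width per slab, so the only discretisation is in
  latitude; the half-plane benchmark centroid offset $-4a/(3\pi)$ is
  reproduced to ~10⁻⁴ relative error at the default slab count;
* fallbacks: an ellipse wholly on land is inflated ×1.5 up to 3 times; if
  still empty, an expanding radial search returns the nearest ocean point
  (hard error beyond 10° — that is data, not geometry, being wrong). If the
  centroid of a crescent-shaped remainder itself falls on land it is
  replaced by the nearest point of the ocean remainder, guaranteeing the
  never-on-land postcondition;
* only on-land days move; dates and behavioural means are untouched;
  degenerate half-widths are floored at 0.01° so the ellipse is always
  two-dimensional; the operation is idempotent.

Whether the original implementations of this correction worked in planar
degree space or a projected frame is generally unstated; the projected
choice here is documented as this package's, and the two differ only at the
third decimal of a degree for whale-scale ellipses.

## Movement summaries

Distances are haversine great-circle distances on a sphere of radius
6,371 km; speed is distance/24 h. A day with posterior mode mean above 1.75
is ARS, below 1.25 transiting, otherwise uncertain — boundary values are
uncertain, reading the published cutoffs' "greater/lower than" strictly;
both cutoffs are configurable. A step between consecutive days takes its
label and season from its end day (configurable to start day), since
behaviour is estimated per location while steps need one convention.
Seasons follow the Gulf of California climatology: December–May cool,
June–November warm. Cohort "mean" rows are unweighted arithmetic means
across tracks, skipping missing per-mode cells, which is the arithmetic
that reproduces a per-track summary table's printed mean row from its
rows — not a pooled mean over steps.

## The synthetic-data generator

The generator is first-class, tested code and defines the study conditions
for every simulation-based check. Defaults emulate the motivating
deployment: 70-day tracks starting near 111°W 26°N; transmitter duty cycle
of a fixed 4-h daily window, switching to every other day after day 90;
fix times a homogeneous Poisson process in the window at 1.7 expected
fixes per transmitting day; an LC mixture weighted toward 0/A/B (0.18 /
0.25 / 0.30) with minority 1/2/3 and 5% Z, as is typical of marine
deployments; movement parameters $\gamma = (0.8, 0.2)$,
$\theta = (0, \pi/2)$, $\alpha = (0.9, 0.1)$, isotropic process SD 0.08°
(≈ 8 km daily scale). Fixes are exact interpolations of the bracketing
daily states plus scaled-t noise, i.e. the generator matches the estimation
model's own observation geometry.

What this does and does not show: passing recovery tests demonstrates the
sampler targets the right posterior when the model is true. Real tracks
add what the generator omits — tag failure and duty-cycle drift, error
scales that differ from the shipped defaults, spatially correlated Argos
error, behaviour that is not a two-state Markov chain, and movement
constrained by coastlines (the generator moves freely; only the
post-processing is land-aware).

## Numerical choices and problem sizes

Test and acceptance runs use deliberately scaled problem sizes chosen as
the package's own balance of power against runtime: recovery experiments
use 10 replicates of 120-day tracks with 60-day persistent/tortuous blocks
and chains of 15,000 iterations (5,000 burn-in, thinning 10); the
behavioural-contrast unit test uses a single 60-day track; line-recovery
and bookkeeping tests use 6–15-day tracks. Closed-form geometry checks use
720 slabs and tolerances an order of magnitude above the discretisation
error.

Across replicate sets, the empirical coverage of the 95% credible
intervals for $\gamma_1$ sits in the 0.7–0.9 range rather than at the
nominal 0.95: with ~1.7 heavy-tailed fixes per day the posterior states
are smoother than the truth, which biases persistence slightly upward and
makes the upper interval endpoint brush the true value on some replicates.
This is a property of the model-data combination at study-scale sparsity,
not of the sampler (two-chain agreement ratios are ≈1.00 on those same
fits); it is reported as measured.

## Known limitations

* The model operates in raw lon/lat degrees, as the original
  implementations of this family did; at high latitudes the anisotropy of
  degrees distorts the process covariance. Distances and speeds are
  computed on the sphere afterwards.
* Two modes only, fitted per track; no hierarchical sharing across
  animals, no continuous-time formulation.
* The land correction fixes daily estimates, not the path between them; a
  step may still cross land.
* DIC for latent-state models has a well-known sensitivity to the
  focus (observed vs latent likelihood); the observation-focused choice is
  documented above and used consistently.
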