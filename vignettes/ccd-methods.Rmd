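---
title: "Methods: coupling coordination analysis of environment-health panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling coordination analysis of environment-health panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdpanel)
```

This vignette documents the statistical choices behind `ccdpanel`: the model
each stage implements, the parameters that matter and their defaults, what
the synthetic data generator does and does not emulate, and the numerical
conventions for edge cases.

## The measurement problem

Two composite indices are built from a long panel of indicators for the same
units and years: an ecological environmental civilization (EEC) index from
pressure/state/response indicators, and a resident public health (RPH) index
from staffing, facility, healing-capacity and efficiency indicators. The
question is not how high each index is, but how *matched and jointly
developed* the two are, how that synergy is distributed across space, and
what drives it.

## Entropy scoring

Indicators are min-max normalized by attribute sign with the minimum and
maximum pooled over **all units and years**, so one fixed scale underlies
every year and scores are comparable over time. Weights come from
information entropy computed on the pooled sample:

$$e_j = -\frac{1}{\ln(nm)} \sum_{i,t} p_{ijt}\,\ln p_{ijt},\qquad
  w_j = \frac{1-e_j}{\sum_j (1-e_j)},$$

with $p_{ijt}$ the cell's share of the indicator's normalized total and the
convention $0\ln 0 = 0$. The $\ln(nm)$ denominator matches the double sum
over units and years and guarantees $e_j \in [0,1]$; an `entropy_denominator
= "m"` switch (years only) is provided because both conventions circulate in
the applied literature, as is an optional additive `zero_shift` for users
who prefer shifting over the $0\ln 0$ convention (default off). Degenerate
indicators — constant over the whole panel, or all-zero after normalization
— are rejected with an error naming the indicator rather than silently
producing `NaN` weights.

Two consequences worth knowing: weights are invariant to positively rescaling
any raw indicator (only relative variation matters), and highly skewed
indicators (a few units far above the bulk) have concentrated proportions,
low entropy, and therefore *large* weights. That is a property of the
method, not a bug; it is also why real yearbook data can put half a
subsystem's weight on one skewed indicator.

## The modified coupling coordination degree

With subsystem scores $U_1, U_2 \in [0,1]$ and $U_2$ relabelled as the
larger one,

$$C = \bigl[1-(U_2-U_1)\bigr]\sqrt{U_1/U_2},\qquad
  T = \alpha_1 U_1 + \alpha_2 U_2,\qquad D = \sqrt{CT}.$$

The traditional product-form coupling degree concentrates near 1 for almost
any pair of moderate scores; this modified $C$ spreads over all of $[0,1]$,
equals 1 exactly when $U_1 = U_2$, and decreases strictly as the smaller
score falls (the test suite sweeps $10^5$ random pairs for these
properties). $\alpha = (0.5, 0.5)$ by default: the two subsystems are
treated as equally important.

The combination $D = \sqrt{CT}$ is the model-family convention and the only
reading consistent with the value ranges such analyses report; the literal
product $C\cdot T$ remains available via `d_formula = "product"` for
comparison. Both bounds are handled by convention: $C = D = 0$ when both
scores are 0 (the $0/0$ limit), and the top classification interval
$[0.9, 1.0]$ is closed. Classification uses half-open decile intervals
(`classify_ccd()`), so e.g. $D = 0.4908$ is "Near non-coordination" and
$D = 0.6595$ "Primary coordination".

## Dagum Gini decomposition

Per year, the cross-unit Gini of $D$ is decomposed exactly into
within-region ($G_w$), net between-region ($G_b$), and transvariation
($G_s$) components following Dagum's 1997 construction: pairwise Ginis
$G_{hi}$ between regions, relative economic affluence
$D_{hi} = (d_{hi}-p_{hi})/(d_{hi}+p_{hi})$ from gross affluence and gross
transvariation computed by exhaustive pair sums, and population/value-share
weights. All sums are $O(n^2)$ and exact — at $n = 31$ clarity beats
cleverness, and additivity $G = G_w + G_b + G_s$ holds to $10^{-10}$ on
every random instance in the property tests. Decomposition is computed
independently per year; the "average" row of the yearly table is the plain
mean of yearly components and rates.

## Distribution dynamics (KDE)

Gaussian kernel density estimates are computed by direct summation on an
explicit grid (default 512 points spanning the data range $\pm 3h$), with
Silverman's rule-of-thumb bandwidth $h = 0.9\min(\hat\sigma,
\mathrm{IQR}/1.34)\,n^{-1/5}$ per curve. A `shared_bandwidth` option uses
one pooled bandwidth across years so curve widths are visually comparable.
Curve summaries count modes as strict local maxima above 5% of the global
peak (suppressing numerical ripples on the grid) and report the right-tail
mass beyond the estimated 90th percentile. Plotting is deliberately left to
the user — the tidy `(scope, year, grid, density)` output feeds directly
into ggplot2.

## Markov dynamics

States are pooled quartiles of all unit-year CCD values: one set of three
cutpoints for the whole panel, so "low" means the same thing in 2010 and
2022 and upward mobility over time is visible in the transition counts.
Values equal to a cutpoint go to the upper class; the top interval is
closed. (Per-year quartiles would instead condition out the common trend;
the pooled choice matches reporting one matrix for the whole window, and
the cutpoints can be overridden.)

The spatial Markov analysis discretizes the spatial lag $\sum_j W_{ij}
D_{jt}$ with the **same** pooled cutpoints, so a "low" neighbourhood is
commensurable with a "low" own state, and conditions each one-year
transition on the origin-year lag class. The four conditional count
matrices partition the traditional counts exactly — a property test, since
it is easy to break when filtering joins. Rows with no observed transitions
are reported as `NA`, never as zeros.

Global Moran's I uses row-standardized first-order contiguity by default
(the edge-list reader symmetrizes and standardizes), permutation inference
with 999 draws under a fixed seed, and the analytic normal approximation for
the z-value. For panel data `morans_i_panel()` pools the years: the
statistic is the mean yearly I and the null permutes units independently
within each year. A single cross-section at $n = 31$ has limited power
(even strongly autocorrelated fields fail significance in a quarter of
draws); pooling thirteen years is what makes spillover reliably detectable
at the study's scale.

## Random-effects panel Tobit

The driver regression is a two-limit censored panel model,

$$D_{it}^{*} = \alpha + x_{it}'\beta + u_i + \varepsilon_{it},\qquad
  u_i \sim N(0, \sigma_u^2),\ \varepsilon_{it}\sim N(0,\sigma_e^2),$$

with $D$ observed censored at $[0,1]$ and $x$ the five pre-logged drivers
(lnPGDP, lnUR, lnOPEN, lnEL, lnGHE). Observed CCDs are typically interior,
in which case the censored terms vanish and the model degenerates gracefully
to a random-effects linear regression — the uncensored, no-effect limit is
verified against least squares to $10^{-3}$.

The unit effect is integrated out by **adaptive** Gauss-Hermite quadrature:
each unit's posterior mode and curvature are found by vectorized Newton
steps (analytic first and second derivatives, inverse-Mills terms for
censored observations), and the 12 default nodes are shifted and scaled
accordingly. Plain prior-centred quadrature is not sufficient here: with
many observations per unit the integrand is far narrower than the prior.
On a converged fit, doubling the nodes changes the log-likelihood by less
than $10^{-6}$ (tested). Optimization is deterministic — least-squares warm
start, BFGS on $(\beta, \log\sigma_u, \log\sigma_e)$ — and standard errors
come from the observed information; non-convergence is flagged on the
returned object, never silent.

At the study size (31 units x 13 years) the recovery study in the test
suite checks that each true coefficient falls inside its 95% CI in at least
90 of 100 replicates. One caveat the tests encode: a coefficient whose true
magnitude is below its own standard error (the government-health-expenditure
driver at the default truth) cannot have its *sign* recovered reliably by
any estimator — only the four identifiable drivers are held to the 95%
sign-recovery bar.

## What the synthetic generator emulates

`generate_panel()` builds a 31-unit x 13-year panel with the structure the
analysis assumes:

- latent subsystem levels rising linearly (defaults anchored at 0.26→0.485
  for EEC and 0.30→0.465 for RPH, so the environment index grows faster
  than the health index);
- three contiguous regional bands (11/8/12 units) with small region
  offsets, Eastern-leaning for health;
- spatial spillover through a simultaneous-autoregressive transform
  $(I-\rho W)^{-1}e$ at $\rho = 0.6$ on a symmetric k-nearest-neighbour
  (k = 4) contiguity graph over random coordinates. The spillover operates
  on one **shared** regional-development field that moves both subsystems,
  with smaller subsystem-specific components — neighbouring units
  co-develop as wholes, which is what makes the CCD itself spatially
  autocorrelated (yearly Moran's I typically in the 0.1-0.4 band);
- indicators as monotone noisy affine transforms of their subsystem's
  latent level, falling for negative-attribute indicators;
- a 2% missing-cell rate (never reducing a series below two observations)
  to exercise imputation.

A planar triangulation would be the textbook contiguity emulation; the
k-nearest-neighbour graph is used because it needs no geometry dependency
and has the same sparse, planar-like, connected character. A real province
adjacency list ships as an optional fixture
(`inst/extdata/china_province_adjacency.csv`, first-order queen contiguity
with the usual island convention).

`generate_covariates()` has two modes. For simulation studies it draws the
five drivers on realistic log scales and generates the CCD from the linear
index with the configured truth ($\beta = (0.08, 0.15, -0.015, 0.02,
-0.01)$, $\sigma_u = 0.03$, $\sigma_e = 0.02$, intercept auto-centred so the
mean CCD is 0.55). For pipeline runs it conditions on an existing CCD
panel, solving the linear index for lnPGDP so the configured relation holds
exactly against the panel's own CCD.

**What it does not emulate.** Real yearbook indicators are heavily
right-skewed (a single province can dominate an indicator's range), which
simultaneously produces large relative score growth and very small
cross-unit Gini levels. The generator uses symmetric noise, so its Gini
levels are several times larger than real panels exhibit, while score
growth lands on the right order (the latent noise scale, `noise_sd = 0.05`,
was chosen to put national score growth near the observed magnitudes for
this kind of panel rather than to match Gini levels — one knob cannot do
both without modelling skew). Passing tests therefore demonstrate the
*method's* correctness and power at realistic sizes, not that synthetic
distributions match any particular real dataset cell for cell.

## Numerical conventions and degenerate inputs

- Imputation: linear in year within a (unit, indicator) series, nearest
  observed value beyond the observed range; series with fewer than two
  observations are an error naming the series. Idempotent.
- Normalization: constant indicators are an error (no 0/0).
- Entropy: $0\ln 0 = 0$; all-zero indicators are an error.
- CCD: inputs outside $[0,1]$ are a domain error; $C(0,0)=0$ by limit.
- Gini: requires positive mean and at least two regions with units.
- KDE: zero-dispersion samples have no bandwidth (error); when the IQR
  collapses under ties the bandwidth falls back to the standard deviation.
- Markov: fewer than four distinct values cannot be quartile-discretized;
  undefined transition rows are `NA`.
- Moran: zero-variance vectors are an error; permutation seeds restore the
  caller's RNG state.
- Tobit: responses outside the bounds are an error; `sigma_u_fixed = 0`
  gives the pooled model without quadrature.

## Problem sizes used by the checks

The property and acceptance tests run at the sizes the method targets:
$10^5$ random score pairs for the CCD algebra, 1000 random instances for
Gini additivity, 100 replicates of the 31x13 Tobit recovery study, and 100
generator replicates for the spillover-power study (199 permutations each
inside the replication loop; single analyses default to 999).

## Known limitations

- The entropy-weight convention (denominator, zero handling) differs across
  applied papers; published weight tables can generally not be reproduced
  exactly without knowing those choices, which is why both switches exist.
- The Gini "average" row convention (mean of yearly values) is one of
  several in use.
- Spatial inference is conditional on the chosen weight matrix; only
  contiguity-style matrices are built in (inverse-distance would be a
  straightforward extension of the edge-list weights).
- The Tobit stage assumes normal, homoskedastic errors and exogenous
  drivers; no instrumental-variable or spatial-econometric variants are
  provided.
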