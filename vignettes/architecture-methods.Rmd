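---
title: "Quantitative-trait architecture under pleiotropic stabilizing selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative-trait architecture under pleiotropic stabilizing selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(stabarch)
```

## The model

An individual's phenotype is a vector in an n-dimensional trait space; we
study the architecture of one focal trait (the first coordinate), with the
dimension n parameterizing pleiotropy. Fitness declines with the Euclidean
distance r of the phenotype from an optimum at the origin,
W(r) = exp(-r^2 / 2w^2); only the curvature at the optimum matters, so the
Gaussian form is a convention, and the additive environmental variance is
absorbed into w. The phenotype is the sum of allelic effect vectors over a
large mutational target of L sites with per-site mutation rate u, in a
diploid Wright–Fisher population of size N with free recombination and
infinite-sites bookkeeping (theta = 4Nu << 1, 1 >> U = Lu >> 1/2N).

At equilibrium the phenotypic distribution is a tight multivariate normal
centered at the optimum, and the marginal dynamic at a segregating site is
underdominant:

* drift:     E(dq) = (a^2/w^2) pq (q - 1/2)
* diffusion: V(dq) = pq/2N

where a is the Euclidean size of the site's effect vector. Comparison with
the standard viability model identifies the selection coefficient
s = a^2/w^2 (scaled: S = 2Ns). Selection on a variant is therefore set by its
*total* effect size, while its contribution to the focal trait involves only
the first component a1. Isotropic mutation makes the conditional law of a1
given s geometric: a1 = a x where x is the first coordinate of a uniform
point on the (n-1)-sphere, with density proportional to
(1 - x^2)^((n-3)/2), E(a1^2 | s) = (w^2/n) s, and, as n grows,
a1 ~ N(0, (w^2/n) s). The package exposes the exact finite-n law
(`effect_density()`, `sample_effect(mode = "exact")`), which accepts any real
n >= 1 so an effective number of traits n_e can stand in for anisotropic
mutation, and uses the pleiotropic limit by default (internally the
chi-square representation a1^2 = (w^2/n) s eps, eps ~ chi^2_1). n = 1 is a
two-point distribution (+/- a) and is handled as a separate discrete code
path rather than a degenerate density.

The closed-form normalization of the finite-n density is taken from the
Gamma-function expression and verified numerically (integral to 1e-8, second
moment to 1e-6) rather than trusted from print. For n = 2 the density has
integrable endpoint singularities; QAGS endpoint extrapolation or the
substitution a1 = a sin(t) both integrate it accurately.

## Sojourn densities and per-site variance

All equilibrium statistics derive from the diffusion sojourn-time density of
a new mutation entering at q0 = 1/2N. With psi(y) = exp(S y (1-y)),

t(q) = 2 [int_0^q0 psi][int_q^1 psi] / (V(q) psi(q) int_0^1 psi),  q >= q0,

and the mirrored form below q0. Writing psi(y) = e^(S/4) e^(-S(y-1/2)^2),
the e^(S/4) factors cancel, leaving error-function integrals that are
evaluated stably in log space; integrands are integrated by trapezoid on a
log-spaced frequency grid mirrored around 1/2 (default 3000 points per
side), which resolves both the 1/q neutral spectrum and the e^(-Sq) boundary
layer of strong selection. Degenerate inputs are refused early (S < 0,
frequencies outside (0,1), N < 100 where the diffusion scaling is
meaningless).

The expected per-site contribution to focal-trait variance, in units of
v_s = 2w^2/(nN) (the strong-selection asymptote and the package's variance
unit), is (S/4) int 2pq t(q) dq. It equals S/2 for effectively neutral
sites, crosses 1 near S = 3.4, peaks about 28% above 1 near S = 9, and
relaxes back to 1 — the numbers the acceptance script recomputes:

```{r ratio-curve}
vc <- variance_ratio_curve(c(0.5, 1, 3, 10, 30, 100))
vc
c(crossing = attr(vc, "crossing"), argmax = attr(vc, "argmax"),
  peak = attr(vc, "peak"))
```

MAF decompositions fold the integration domain (`maf_variance_fraction()`),
not the integrand, since folding is a property of the statistic:

```{r maf}
c(S3 = maf_variance_fraction(3, 0.1), S10 = maf_variance_fraction(10, 0.1))
```

Two regime caveats surfaced during validation and are worth recording. The
strong-selection asymptote carries an entry-frequency correction of order
e^(-S/2N): at N = 1e4 and S = 1000 the true ratio is 0.977, so checks of the
S -> infinity limit are run at N = 1e5. Likewise the closed forms below are
S -> infinity (or S -> 0) limits whose own truncation error at S = 100 is
about 0.01 at N = 1e4; corner comparisons therefore also use N = 1e5.

## The distribution of variances among sites, G(v)

G(v) is the fraction of additive variance from segregating sites whose
contribution v = 2 a1^2 p q (in units of v_s) exceeds v. In v_s units,
v = (S/2) eps q(1-q) with eps the effect factor above, so the
variance-weighted survival reduces to a single quadrature over q using the
closed tail identities E[eps 1(eps > c)] (chi^2_3 survival in the limit,
Beta(3/2, (n-1)/2) survival at finite n). This deterministic quadrature is
the package's oracle (`G_numeric()`); a Monte Carlo mode cross-checks it.
Four closed forms hold in the regime corners (`G_closed()`):

| regime          | G(v)                          | int_0^inf G dv |
|-----------------|-------------------------------|----------------|
| strong, n = 1   | exp(-2v)                      | 1/2            |
| neutral, n = 1  | sqrt(1 - v/v_max), v_max = S/8| S/12           |
| strong, limit   | (1 + 2 sqrt v) exp(-2 sqrt v) | 3/2            |
| neutral, limit  | exp(-4v/S)                    | S/4            |

The mean–survival integrals pin down the algebra independently of the
oracle; both agree with the radical-bearing forms above. Pleiotropy raises
G(v) at every threshold (more variance behind any given cutoff), which the
suite verifies on an (n, v) grid. At intermediate S (~5) the numeric curve
is bracketed by the two limit forms only at small v; in the tail the finite
maximum per-site contribution pulls it below both — the closed forms there
are upper envelopes, not brackets.

The site-count analogue (`expected_sites_above()`) drops the variance weight
and multiplies by the influx 2Nu: the expected number of segregating sites
per target site contributing more than v. Per-site expectations throughout
are per new mutation; multiplying by 2Nu converts to stationary per-site
moments, and all ratios and G curves are normalization-free.

## Forward simulation and demography

`simulate_site()` runs the discrete Wright–Fisher counterpart of the
diffusion: q <- Binomial(2N(t), q + s pq(q - 1/2))/2N(t), one replicate per
new mutation, under piecewise demographies (constant or per-generation
discretized exponential epochs; sizes floored at 2). The inner loop is
compiled (Rcpp) and draws through R's RNG, so runs are bit-reproducible
under a seed, and a multi-epoch demography with equal sizes is bit-identical
to the constant-N path. Mutations enter either at a fixed generation or at
origins sampled proportional to the influx 2 N(t) u.

For the constant-N agreement check (`integrated_variance_sim()`) the
quantity compared is the per-mutation time-integrated variance
(S/2) E[sum_t p_t q_t], with the chi-square effect factor marginalized
analytically. Its per-replicate coefficient of variation at N = 1000 is
large (~25–90, rising toward intermediate S) because rare excursions through
the underdominance barrier to near-fixation dominate the second moment;
replicate counts in the tests (2e6–6e6 per S) were sized from that measured
CV so the Monte Carlo standard error sits near 1.2–1.5%, well inside the 5%
comparison band.

The demographic illustration uses a clearly synthetic bottleneck-plus-growth
history (40000 generations at N = 10000, 1500 at 2000, then exponential
growth to 100000 over 200; `inst/extdata/synthetic_bottleneck.yaml`) — a
generic severe-bottleneck shape, not an inferred human history. Under it the
*total* per-site variance above a high threshold is maximal at intermediate
s: strongly selected mutations are young (they arose after growth began,
at high N, hence low frequency), effectively neutral ones have small
effects, and mutations with s around 1e-3 that predate or span the
bottleneck drifted to relatively high frequencies and dominate the upper
tail. The summary statistic (`variance_by_s_under_demography()`) thresholds
the effect-marginalized contribution 2 s p q (units w^2/n); drawing eps per
site is available in the ensemble but would only add heavy-tailed noise to
this comparison.

`simulate_multilocus()` is the full individual-based model (Gaussian
fitness on the summed effect vectors, viability sampling, Poisson(U)
mutations per gamete with isotropic fixed-size effects, free recombination)
and exists to validate the per-site reduction. Two of its diagnostics
deserve comment. First, the regression of per-generation frequency changes
on pq(q - 1/2) estimates s = a^2/w^2 only up to two finite-size corrections
that pull in opposite directions: averaging fitness over the phenotypic
distribution replaces w^2 by roughly w^2 + sigma^2 per trait (a downward
bias of order sigma^2/w^2), while weak background compensation at low
polygenicity leaves part of the self-displacement term in the marginal
drift (an upward bias). Validation runs therefore sit in a regime where
both are small — sigma^2 near 3% of w^2 with several hundred segregating
sites (N = 800, U = 0.03, s = 0.02) — measured to give a slope within ~3%
of s on average, with between-run wander noise the remaining error.
Second, the instantaneous displacement of the population mean
from the optimum adds a directional term -pq (a . rbar)/w^2 that the
*marginal* Eq-5 dynamic absorbs through background compensation; it is
recorded as a diagnostic covariate but deliberately not partialled out of
the regression — regressing it away removes the compensation itself and
biases the slope downward. Fixed sites are folded into a constant
phenotypic offset so the optimum is never silently re-centered.

## GWAS inference

Detection is modelled as a step function: a study of size m on a trait with
phenotypic variance V_P detects loci explaining v >= v* = c V_P/m. The
calibration c is the noncentrality at which a 1-df chi-square association
test has 50% power at genome-wide significance alpha = 5e-8
(`power_constant()` ~ 29.7); both alpha and the power point are arguments.

Among detected loci in the strong-selection pleiotropic regime, each
genome-wide-significant locus is one segregating site, so the likelihood of
its variance is the *per-site* truncated density

f(v) = exp(-2 sqrt(v/v_s)) / v / (2 E1(2 sqrt(v*/v_s))),  v >= v*,

where E1 is the exponential integral: the variance-weighted survival of
this family is exactly the strong-limit G above, and its count survival
2 E1(2 sqrt(v/v_s)) is what target-size estimation uses. The distinction
between per-site and variance-weighted forms matters: the variance-weighted
density proportional to exp(-2 sqrt(v/v_s)) (no 1/v) describes where the
*variance* sits, not where the *loci* sit, and fitting it to per-locus
records is misspecified. `fit_vs()` defaults to the per-site weighting and
retains the variance weighting (`weighting = "variance"`) — the latter is
also the form that remains normalizable at v* = 0 and has the textbook
unimodal likelihood there; the per-site count diverges logarithmically as
v* -> 0, so site-weighted fitting requires a positive threshold. A
single-trait strong-selection mode (`mode = "strong-n1"`, kernel
exp(-2v/v_s)) supports the model comparison that favors high pleiotropy.

The MLE is a 1-D optimization in log v_s. Uncertainty comes from a
nonparametric bootstrap over loci (percentile intervals; 400–500 resamples
in the tests). Goodness of fit is a Kolmogorov–Smirnov test against the
fitted truncated CDF, with the classic asymptotic p-value for comparability
and a parametric bootstrap (refitting v_s on each resample) as the
recommended, calibrated option — under the null the bootstrap p-values are
uniform, which the suite checks.

Target size: the observed count equals L 2Nu C(v*/v_s) in expectation, with
C the count survival, so L follows by division; its interval propagates
both the bootstrap draws of v_s and the Poisson variation of the count.
The detectable fraction of heritable variance is L 2Nu v_s / (h^2 V_P),
using the strong-selection per-site expectation v_s. Projections to larger
studies combine v*(m) with the variance-weighted survival:
explained(m) = detectable_fraction x G(v*(m)/v_s), and hit counts scale with
the count survival. Both rise monotonically to their ceilings as m grows.

Validation of this pathway is generative: `synth_spec()` +
`generate_gwas_table()` draw segregating sites from the exact sojourn law
(frequencies by inverse-CDF on the quadrature grid, effects from the
geometry), threshold them at v*(m), and the fit must recover the known v_s
and L. The round-trip conditions mimic a height-like trait: n = 10, w = 4.5
(so v_s ~ 4e-4 V_P), N = 1e4, u = 1e-8, L = 5.5e6 sites (~5.5 Mb),
m = 1.5e5 — about 500 detected loci and a detectable fraction near 0.5. The
generating selection coefficient is a point mass at S = 1000: the fitted
family is an S -> infinity form, and at S = 100 its residual curvature error
(~2% bias on v_s-hat) is comparable to the sampling error of 500 loci, so
the strong limit is only genuinely realized deeper in the regime. Coverage
is assessed per parameter over 150 replicates; note that even two exact 95%
intervals jointly cover two parameters as rarely as ~90% of the time, which
is why coverage is evaluated marginally per parameter.

What the synthetic surface does *not* exercise: linkage disequilibrium and
clumping of real hit tables, winner's-curse inflation of reported effects,
uncertainty in V_P and h^2, per-locus power that is not a step function, and
non-equilibrium frequency spectra (the generator is the equilibrium
snapshot; demography-aware tables must come from the forward simulator).
Passing tests therefore validate the estimator against its own model class
and the equilibrium theory, not against those real-data complications.

## Reproducing published-scale analyses

The published height/BMI meta-analysis hit tables have the shape the reader
ingests (`snp`, `freq`, `beta`, optional `n`); the README documents the
recipe: express per-locus variances as 2 beta^2 pq in units of V_P, set
v* from the study size, fit, and report v_s, target size and projections.
Those external tables are not shipped and their headline numbers are not
asserted by the suite; a synthetic stand-in of the same shape and scale
exercises the pathway end to end.

## Numerical choices, in brief

* log-space sojourn evaluation; erf-based psi integrals; midpoint fallback
  for underflowing narrow intervals.
* log-spaced, mirrored frequency grids (3000/side default); MAF cutoffs are
  inserted as exact grid points.
* chi^2_3 / Beta(3/2, .) tail identities turn G into one-dimensional
  quadratures; no indicator discontinuities reach the integrator.
* inverse-CDF sampling interpolates the integrated sojourn mass linearly
  between grid points.
* optimization in log v_s over +/- 12 nats around a moment seed; E1 via
  pracma.
* all stochastic entry points take a seed and draw through R's RNG (the
  compiled kernels included).

## Known limitations

Free recombination and infinite sites are assumed throughout; there are no
dominance, epistasis, linked-selection or ascertainment corrections. The
closed G forms are corner asymptotics — between regimes use `G_numeric()`.
The effective-traits reduction (real n) covers anisotropy only through the
selection–effect relationship, not full mutational covariance structure.
Site-weighted fitting needs v* > 0 and at least a few dozen loci to be
informative (the implementation warns below 20).
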