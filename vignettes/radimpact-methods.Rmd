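---
title: "Methods: from facility utilisation to lives saved"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from facility utilisation to lives saved}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radimpact)
```

`radimpact` chains four models: a synthetic-data generator for
cluster-randomised facility-consultation counts, proportional compression of
multi-diagnosis counts, an interrupted time-series (ITS) estimator of
period-specific utilisation effects with BCa cluster-bootstrap inference, and
a LiST-style deaths-averted engine with scenario algebra on top. This
vignette sets out each model, its assumptions, the tunable parameters, and
the numerical and design choices made where more than one reasonable option
existed.

## 1. The synthetic trial

Routine facility data from the motivating trial (14 rural clusters in 7
matched pairs, monthly under-five consultation counts by clinical diagnosis,
January 2011 – December 2014) are not publicly deposited, so every
downstream stage is developed and tested against a generator that emulates
their statistical structure.

For cluster $i$, calendar month $t$ (0-based), category $c$, the generator
draws

$$Y_{itc} \sim \mathrm{Poisson}(\mu_{itc}), \quad
\log \mu_{itc} = \log(\beta_0 \pi_c) + \tau t + s_{m(t)}
 + \alpha\,\mathrm{arm}_i + \gamma x_i + b_i + \log \mathrm{RR}_{c,p(t)}\,
 \mathrm{arm}_i,$$

with baseline rate $\beta_0$ (default 1000 diagnoses/cluster-month, a
plausible volume for a rural cluster served by several primary facilities),
category mix $\pi_c$ (defaults follow the trial's reported shares: malaria
55%, lower respiratory infections 18%, diarrhoea 3%, the remainder split
across URTI, malnutrition and other), log-linear trend $\tau = 0.005$/month
(≈ 27% growth over 4 years, matching the rising consultation volumes routine
systems showed over the period), a 12-point seasonal profile (default a
cosine with amplitude 0.3 peaking in September, the malaria high season in
the Sahel), an arm offset $\alpha = 0.1$ (systematic baseline differences
between arms were a feature of the trial), a standard-normal cluster
confounder score with coefficient $\gamma = 0.2$, and cluster random
intercepts $b_i \sim N(0, \sigma^2)$ with $\sigma = 0.25$ (substantial
between-cluster heterogeneity). True intervention rate ratios
$\mathrm{RR}_{c,p}$ apply per category and campaign period; defaults are the
trial's estimates (malaria 1.56/1.37/1.35, LRTI 1.39/1.25/1.11, diarrhoea
1.73/1.60/2.07, and 1 for non-targeted categories).

Campaign periods default to 12-month blocks from March 2012 (months 14, 26,
38), the campaign's start, with January–February 2012 assigned to baseline
and year 3 truncated at December 2014; the breaks are configurable because
the original count analysis does not state the year-3 truncation.

**Multiplicity.** Health workers record several diagnoses per consultation,
so diagnosis counts exceed consultations. The generator divides the summed
category counts by an arm-specific diagnoses-per-consultation ratio to
produce the all-cause total, interpolated linearly from 1.23 to 2.17
(control) and 1.51 to 2.29 (intervention) over the window — only start and
end averages are reported for the trial, so linear-in-month is the least
structured choice. `inject_multiplicity()` exposes the inverse operation for
records built at multiplicity 1.

**Deliberate simplifications.** Counts are Poisson conditional on the
cluster intercept — marginally overdispersed across clusters, but with no
extra within-cluster overdispersion and no cluster-by-period heterogeneity
in the true effects. A negative-binomial option is intentionally absent: the
analysis model is Poisson with a cluster random effect, and the generator
mirrors the model it is meant to identify. Consequences worth keeping in
mind: synthetic confidence intervals are far narrower than the trial's
(which reflect real effect heterogeneity between clusters), and passing
recovery tests demonstrates correctness of the estimator, not that real
facility data are this well behaved. Individual children, catchment
populations and distance effects are out of scope. The confounder score is
drawn standard normal per cluster; the PCA construction of the original
score is not reproduced.

## 2. Compression

Per cluster-month, compression rescales category counts to sum to exactly
the all-cause consultation total: target shares $y_c A / \sum_c y_c$,
integerised by largest-remainder (Hamilton) apportionment with ties broken
by category order. Integer outputs keep the Poisson ITS well defined on
compressed data; conservation ($\sum_c \tilde y_c = A$ exactly), idempotence
and scale invariance are tested properties. Records with consultations but
no recorded diagnoses are kept (zero counts) and tallied in a data-quality
report rather than dropped.

One substantive caution, found and documented while validating recovery:
because the diagnoses-per-consultation ratio differs by arm and rises over
time, compression (division by that ratio) injects an arm-by-period signal
of its own. On generator output the uncompressed counts carry the true rate
ratios; compressed counts recover them with a predictable distortion. The
pipeline therefore reports both, and parameter-recovery tests target
uncompressed counts, where the generator's truth is defined.

## 3. Interrupted time-series estimation

For one category, `fit_its()` maximises the marginal likelihood of

$$Y_{it} \sim \mathrm{Poisson}(\mu_{it}), \quad
\log \mu_{it} = \beta_0 + \beta_1 t + s_{m(t)} + \beta_2\,\mathrm{arm}_i +
\beta_3 x_i + \sum_{p} \delta_p\, \mathrm{arm}_i 1[t \in p], \quad
b_i \sim N(0, \sigma^2),$$

i.e. trend, month-of-year indicators, arm, confounder score and
period-by-arm interactions, with a cluster random intercept. Period main
effects are off by default (the trend and seasonality carry the control-arm
time course; a `period_main` flag adds them). No exposure offset is used:
routine systems provide no reliable denominators, so the model describes raw
counts. The period effect is $\mathrm{RR}_p = e^{\delta_p}$, displayed as
$100(\mathrm{RR}_p - 1)$% rounded half away from zero to integers.

Integration is adaptive Gauss–Hermite quadrature (9 nodes by default,
`nagq`), falling back to the Laplace approximation if quadrature fails;
non-convergence is flagged, never silently returned, and a campaign period
with all-zero counts in one arm raises a separation warning. `method =
"glm"` drops the random intercept — exact when $\sigma = 0$, and the fast
refit path used inside the bootstrap, where the point estimate is a
within-cluster difference-in-differences that the random intercept cancels
out of anyway.

**Inference.** Monthly counts within a cluster are dependent, and the
randomisation unit is the cluster, so `its_boot()` resamples clusters with
replacement stratified by arm (preserving 7 + 7 in the default design;
matched-pair resampling is available via `unit = "pair"`). Intervals are BCa:
bias correction $z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)$,
acceleration from the leave-one-cluster-out jackknife
$a = \sum (\bar\theta - \theta_{(i)})^3 / \{6 [\sum (\bar\theta -
\theta_{(i)})^2]^{3/2}\}$, and endpoints at the remapped quantile levels
$\Phi(z_0 + (z_0 + z_{\alpha})/(1 - a(z_0 + z_{\alpha})))$, using
interpolation between order statistics on the normal-quantile scale (the
standard BCa quantile rule). Replicate seeds derive deterministically from
the master seed. Two p-values are reported: the primary one inverts the BCa
interval family (smallest level at which the interval excludes RR = 1, by
bisection, floored at $1/B$), and a Wald p-value from the information matrix
is reported alongside, since the original analysis does not say which
convention its p-values follow.

**Small-sample behaviour, measured honestly.** With 7 clusters per arm the
bootstrap estimates a variance from 6 effective degrees of freedom per arm;
quantile-based intervals do not account for that estimation noise, and the
cluster bootstrap's variance is biased low by roughly $(n-1)/n$ per arm. In
the package's null-coverage experiment (trial design, all true RRs = 1, 200
replicates, B = 500, plain-Poisson refits) the 95% BCa intervals cover RR =
1 for 88–91% of period effects depending on the seed — a one-to-three point
shortfall that is intrinsic to cluster-level resampling at this cluster
count, not a defect of the formulas (which are verified against an
independent implementation to 10 decimal places). Analyses with few clusters
should read "95%" intervals as approximately 90% intervals.

## 4. The deaths-averted engine

The envelope converts per-year under-five mortality rates $q_y$ (per 1000
live births) and live births $L_y$ into deaths $D_y = q_y L_y / 1000$,
split across causes by fractions $f_c$ (defaults in the shipped scenarios
follow a WHO-2011-style structure; the exact fractions are Spectrum
internals, so the shipped values are labelled synthetic). Utilisation
effects $r_y$ map to coverage as

- treatment-with-receipt (malaria ACT, diarrhoea ORS):
  $C_y = C_0 (1 + r_y q)$ with receipt proportion $q$ (54.3% of fever
  attenders received an antimalarial, 34.5% of diarrhoea attenders received
  ORS);
- care-seeking proxy (pneumonia antibiotics) and direct (ANC, facility
  delivery): $C_y = C_0 (1 + r_y)$;

capped at 1 with a saturation warning. The multiplicative (relative)
application is chosen because the effects are measured as relative increases
in attendance; a rural/national baseline adjustment is a single configurable
multiplier on $C_0$ (default 1). The impact fraction

$$\varphi = \frac{E \cdot AF \cdot (C_1 - C_0)}{1 - E \cdot AF \cdot C_0}
 = 1 - \frac{1 - E \cdot AF \cdot C_1}{1 - E \cdot AF \cdot C_0}$$

is the standard residual-risk construction (effectiveness 87% for malaria
treatment, 70% for pneumonia antibiotics, 93% for ORS; affected fractions
1.0), combined across interventions on one cause as
$\varphi_{\mathrm{comb}} = 1 - \prod_i (1 - \varphi_i)$ (permutation
invariant), and applied to $D_{c,y} = D_y f_c$. Only modelled interventions
contribute, so lives saved by non-targeted programmes are excluded by
construction. Negative $r$ (the LRTI year-3 lower bound is −20%) flows
through as a negative $\varphi$. ANC is one bundle intervention standing for
the three routine pregnancy interventions sharing a coverage path; its
effectiveness default is a small illustrative value, clearly not a LiST
constant. The full Spectrum machinery — demographic projection, nutrition
and birth-outcome pathways, herd effects — is out of scope, which is why the
engine is validated by its algebraic properties and the published scenario
algebra rather than by matching absolute lives-saved totals.

## 5. Scenario algebra

Penetration: impact is assumed proportional to media exposure, so national
results scale by $p_{\mathrm{target}}/p_{\mathrm{ref}}$ (52% trial-zone
listenership → 45.2% national = a 13.1% reduction). Discounting: a
spots-only national campaign is represented by scaling lives saved by
$1 - d$, $d \in \{0, 0.1, 0.2\}$; percentage reductions scale identically
because the envelope is unchanged. Sensitivity: the whole engine reruns with
every utilisation effect pinned at its lower (upper) confidence bound.
Scale-up grids apply the trial's effects to per-country envelopes, baseline
coverages and penetrations.

Display rounding is half away from zero (lives to integers, percentages to
one decimal), applied once at display; row totals sum rounded per-year
cells, matching how the published tables are assembled. Recomputing the
published five-country discount grid from its printed undiscounted row
reproduces 22 of 30 cells exactly; the other eight differ by exactly one
life, a pattern consistent with the original tables discounting unrounded
engine output before rounding — with only printed integers as input those
cells are reproducible only to ±1, and the tests treat them so.

Population scaling operates on the envelope's live births by default;
a post-hoc multiplier on lives saved is also exposed (`population_scale_mode
= "posthoc"`) since the trial-zone adjustment was historically applied to
national projections after the fact. The two paths agree because the engine
is linear in the envelope.

## 6. Problem sizes and determinism

Simulation-based checks use: 100 replicates of the 7-pair, 48-month design
for parameter recovery (mean fitted malaria RRs within 3 Monte-Carlo
standard errors of 1.56/1.37/1.35); 200 replicates at B = 500 for null
coverage; B = 999 fixed streams for the dual-implementation BCa comparison
at $10^{-10}$; 1000 random draws for the impact-fraction oracle at
$10^{-12}$. These sizes make Monte-Carlo error small relative to the
tolerances while keeping the default test run fast. All stochastic stages
take explicit seeds; `run_pipeline()` derives stage seeds from one master
seed via hashing, stamps every output with a configuration hash, and is
byte-identical under a repeated seed.

## Known limitations

- The generator omits within-cluster overdispersion and effect
  heterogeneity, so synthetic intervals are unrealistically narrow; it
  validates estimators, not data realism.
- BCa intervals undercover by a few points at 7 clusters per arm (section 3).
- Absolute lives-saved totals from the shipped scenario files depend on
  synthetic envelope internals and are illustrative; the defensible outputs
  are the algebraic transforms (penetration, discounts, weighted averages,
  sensitivity ranges) and relative structure.
- The maternal pathway is the same algebra on a maternal envelope; no
  maternal cause structure is shipped.
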