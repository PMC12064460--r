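---
title: "Validating polytomous item banks: GRM calibration, assumption checks, DIF, linking, and post-hoc CAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating polytomous item banks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmcat)
```

grmcat implements the psychometric workflow used to validate
patient-reported-outcome item banks on the PROMIS T-score metric: check the
item-response-theory assumptions, calibrate a graded response model, test
item fit and measurement invariance, link calibrations across metrics, and
replay a computerized adaptive test (CAT) against recorded responses to
learn how short an adaptive administration can be at a target reliability.
This vignette is the package's account of the underlying models, the
numerical choices, and what the bundled simulations do and do not show.

## The measurement model

Respondents answer five-category ordinal items ("never" ... "almost
always", coded 0–4 internally; a 1–5 file dialect is an I/O option). The
latent trait $\theta$ — symptom severity — lives on a standard-normal
reference metric and is reported as a T-score, $T = 10\theta + 50$.

Samejima's graded response model gives each item a discrimination $a > 0$
and ordered thresholds $b_1 \le \dots \le b_4$. The boundary curves are
logistic with scaling constant $D = 1$,

$$P^*_k(\theta) = \frac{1}{1 + e^{-a(\theta - b_k)}}, \qquad k = 1, \dots, 4,$$

and category probabilities are adjacent differences, with $P^*_0 = 1$ and
$P^*_5 = 0$. The $D = 1$ logistic metric matches the convention of the
mainstream GRM calibration software from which the bundled parameter tables
originate; no 1.7 normal-ogive rescaling is applied anywhere.

Fisher information per item is
$I(\theta) = \sum_k (P^{*\prime}_k - P^{*\prime}_{k+1})^2 / P_k$ with
$P^{*\prime}_k = a P^*_k (1 - P^*_k)$; test information adds over items and
$SE(\theta) = 1/\sqrt{I(\theta)}$. On the standard-normal metric
reliability is $1 - SE^2$, so $SE = 0.316$ corresponds to reliability 0.90
and $SE = 0.548$ to 0.70 — the two anchor points used throughout.

```{r anchors}
se_to_reliability(c(0.316, 0.548))
theta_to_tscore(0)
```

## Quadrature, scoring, and calibration

All latent-trait integrals use one fixed grid: 61 equally spaced nodes on
$[-4, 4]$ — the range the trait is taken to span — with standard-normal
weights renormalized to sum to one. The same grid serves the EM
calibration, EAP scoring, and the information summaries, so scores and
likelihoods are mutually consistent. Tests verify the 61-node EAP against a
10,001-point trapezoid rule on $[-6, 6]$: agreement is within $10^{-4}$ in
$\theta$, because the posterior is smooth and carries negligible mass
beyond $\pm 4$ for any realistic response pattern.

Scoring is expected a posteriori (EAP): the posterior mean under the
standard-normal prior, with the posterior standard deviation as its
standard error. The posterior SD — not $1/\sqrt{I}$ at the point estimate —
is the quantity the CAT stopping rule monitors, matching common CAT
practice; the $1/\sqrt{I}$ relation is used for full-bank reliability
curves. With no answered items EAP returns the prior (0, 1).

`fit_grm()` is a Bock–Aitkin marginal-maximum-likelihood EM. The E-step
computes each response pattern's posterior over the grid nodes (patterns
are collapsed for speed); the M-step maximizes each item's expected
complete-data log-likelihood by L-BFGS-B on an unconstrained
reparameterization — log discrimination, first threshold, log threshold
gaps — which enforces $a > 0$ and monotone thresholds without constraint
handling and keeps estimates inside $a \in [0.01, 20]$, $b_1 \in [-6, 6]$.
Convergence is declared when the largest parameter change in a cycle falls
below $10^{-4}$ (at most 500 cycles); the marginal log-likelihood trace is
returned and is non-decreasing, as EM theory requires. Starting values come
from marginal category proportions through the logistic quantile map.
Parameter-recovery simulations at $n = 1000$ from the bundled anxiety bank
give correlation above 0.9 between true and estimated discriminations and
mean absolute threshold error below 0.15; a two-item bank at $n = 5000$
agrees with a direct joint maximization of the marginal likelihood to
within 0.03 on every parameter.

Item fit is Orlando–Thissen's $S\text{-}X^2$: observed category frequencies
conditional on the total summed score are compared with model-expected
frequencies, where the summed-score distributions come from the
Lord–Wingersky recursion (verified in tests against exhaustive pattern
enumeration). Within each summed-score group, adjacent category cells merge
until every expected count reaches 1; groups reduced to a single cell drop
out. Degrees of freedom are cells minus groups minus the five item
parameters when the parameters were estimated from the same data — the
parameter correction is skipped (`params_estimated = FALSE`) when computing
the statistic with known generating values, as in the package's own type-I
simulations, which recover the nominal $\alpha = 0.001$ rate within
binomial error over 200 replicates at $n = 700$. Fit is flagged adequate at
$p > 0.001$.

## Assumption checks

The IRT workflow presumes unidimensionality, local independence, and
monotonicity. `check_irt_assumptions()` randomly halves the sample so that
exploration (KMO, parallel analysis, EFA) and confirmation (one-factor
model, residual correlations) never use the same respondents; Mokken
scalability uses the full sample.

*Polychoric correlations* are two-step maximum-likelihood estimates:
thresholds from marginal proportions via normal quantiles, then a
one-dimensional likelihood search over $\rho \in (-0.999, 0.999)$. The
bivariate-normal rectangle probabilities use the package's own vectorized
Gauss–Legendre evaluation of the single-integral representation of
$\Phi_2$, accurate to near machine precision (tested against an independent
implementation). Two-step estimation was chosen over joint ML because it is
the field standard, fast, and accurate at these sample sizes; the matrix is
eigenvalue-clipped to positive semi-definiteness when sampling noise makes
it indefinite.

*Parallel analysis* compares polychoric eigenvalues against the mean
eigenvalues of 100 (configurable) datasets of independent ordinal variables
resampled from the observed margins, retaining the leading run of
eigenvalues above the random means. The mean — rather than a 95th
percentile — rule is a declared default, as is the replicate count; neither
is prescribed by the validation conventions this package follows.
*Unidimensionality* is called when the first factor explains at least 20%
of the variance, the first/second eigenvalue ratio exceeds 4, and parallel
analysis retains exactly one factor.

*EFA/CFA* use least-squares factor extraction (quasi-Newton on the
off-diagonal discrepancy, principal-component start, Heywood communalities
clipped with a warning). The one-factor fit indices (CFI, TLI, RMSEA, SRMR)
are computed from the maximum-likelihood discrepancy at the least-squares
solution with the standard formulas. They are deliberately documented as
approximations: they are not the scaled/robust DWLS indices a structural
equation package would report for ordinal data, so published scaled CFA
values are not comparison targets for this package. Local dependence is
flagged for any residual correlation above 0.20.

*Monotonicity* uses Loevinger-type Mokken scalability:
$H_{ij} = \mathrm{cov}(X_i, X_j)/\mathrm{cov}_{\max}(X_i, X_j)$, where the
maximal covariance comes from the comonotonic (Guttman-ordered) coupling of
the two items' margins; item and scale coefficients are covariance-weighted
aggregates, and the conventional cut-offs apply (items $\ge 0.30$, scale
$\ge 0.50$). A bootstrap standard error is available but off by default.

## Differential item functioning

`dif_scan()` follows the ordinal-logistic-regression approach: for each
item, three nested proportional-odds models on the item response — trait;
trait + group; trait + group + trait×group — with the EAP trait estimate
from all bank items as the matching variable (a continuous matching
variable, not a summed score). The flagging statistic is the McFadden
pseudo-$R^2$ change, $R^2 = 1 - \ell/\ell_0$, with a 2% change as the
critical value: model 1→2 flags uniform DIF, model 2→3 non-uniform DIF. One
purification round — re-estimating the matching trait without flagged
items, then rescanning — runs by default and is configurable, since the
number of purification iterations is a free choice in this family of
procedures. Fits go through `MASS::polr`, with a ridge-stabilized direct
optimization as fallback under complete separation. Monte-Carlo empirical
thresholds are intentionally out of scope; the fixed 2% rule is the
stated criterion. In simulations with no DIF the scan flags under 5% of
item–seed combinations; a planted uniform shift of 0.5 on a
well-discriminating item is flagged in over 90% of seeds, with
$\Delta R^2$ values (0.03–0.07) in the range typically reported for real
flagged items. Note that the planted-shift detectability scales with
$a \times \text{shift}$: the same 0.5 shift on a weakly discriminating item
sits near the 2% threshold.

## Stocking–Lord linking

Two calibrations of the same items on different metrics are linked by the
affine trait map $\theta_{ref} = A\,\theta_{focal} + B$; focal parameters
move to the reference metric by $a \mapsto a/A$, $b_k \mapsto A b_k + B$.
`stocking_lord()` minimizes the standard-normal-weighted squared distance
between the reference test characteristic curve and the transformed focal
one over the quadrature grid (the weighting is a declared choice), by
Nelder–Mead from $(1, 0)$ with a coarse grid-search fallback. Constructed
inverse problems are recovered to $10^{-4}$, and the optimum beats 25
random restarts in tests. `build_hybrid_bank()` assembles the
practice-standard hybrid: reference parameters everywhere except the
language-DIF items, which carry Stocking-Lord-transformed local parameters,
with the constants estimated on the non-DIF anchor items. Because no
official reference (U.S.) parameter table is bundled, examples and tests
use perturbed copies of the local fixtures as synthetic stand-in reference
banks, and no numeric linking constants are claimed as reproduction
targets.

## Post-hoc CAT

`run_cat()` replays the adaptive algorithm against an already-recorded full
response vector — responses are looked up, never generated. The first item
maximizes information at $\theta = 0$ (the population average); after each
response the EAP estimate updates, and the next item maximizes information
at the current estimate (maximum Fisher information selection,
deterministic bank-order tie-break). The test stops when the posterior SD
reaches the stopping value — 0.316 by default, i.e. reliability 0.90 — or
when the bank is exhausted. No exposure control or content balancing is
implemented, matching the plain post-hoc design.

`posthoc_cat_simulation()` summarizes a whole validation sample: persons
are ranked by a reference trait — the full-bank EAP estimate by default, to
match the "CAT versus full item bank" framing; optionally the true
generating trait — and cut into ten equal deciles (ties by person order).
Each decile reports mean trait, RMSE, bias, test length, SE, the proportion
stopping by the SE rule, and reliability $1 - \overline{SE}^2$. EAP
posterior SDs can occasionally rise when an answer surprises the posterior,
so monotone shrinkage is asserted only in aggregate (over 95% of steps in a
1000-person simulation).

## The synthetic cohort generator

No respondent-level data ship with the package; every test and simulation
runs on synthetic data drawn from the bundled calibrated parameter tables.
`generate_cohort()` emulates a two-group school/clinical design: 637 school
and 291 clinical respondents, group trait means $-0.23$ and $0.50$
(obtained by inverting the T-score map from known-group means 47.7 and
55.0), within-group SD 1.0, 3.4% missingness completely at random, and
group-specific female proportions used only as DIF grouping labels. The
within-group SD is configurable because published T-score SDs (11.8–12.9)
mix the two groups and imply roughly 1.2 on the pooled scale; unit SD per
group is the declared default. Missingness is MCAR because only overall
missing rates, not a mechanism, are reported for such designs.

`thetas_from_decile_means()` rebuilds a validation sample from a published
decile profile: counts per decile at the decile mean plus Normal(0, 0.15)
jitter — small relative to the decile spacing, seed-controlled. The bundled
profiles (`decile_profile()`) hold the anxiety ($n = 196$) and depressive
($n = 199$) validation trait distributions; the lowest published decile
pools the distribution floor, so rebuilt samples place its mass at the
pooled mean.

What passing simulations show — and what they do not: generated cohorts are
exactly unidimensional, locally independent, monotone GRM data, so the
assumption checks passing on them validates the *decision rules*, not any
claim about real respondents. Real data features deliberately absent from
the generator include non-normal trait distributions, careless responding,
item-level missingness mechanisms, and local dependencies; conclusions
about a real cohort require running the pipeline on that cohort.

## Reporting pipeline

`run_full_pipeline()` chains the stages in the published order: listwise
deletion → half-split assumption checks → evaluation/validation split
(default fraction 0.78, "slightly under 80%") → GRM calibration on the
evaluation sample → $S\text{-}X^2$ → DIF scans → optional hybrid-bank
linking → post-hoc CAT on the validation sample, emitting tables with the
conventional schemas (parameter/fit table; decile-level CAT table) plus a
JSON summary. Known-group validity uses a Welch t-test — the unequal-
variance form, chosen because fractional degrees of freedom are the norm in
the designs this mirrors — and pooled-SD Cohen's d with a normal-
approximation 95% CI ($d \pm 1.96\,SE_d$), a declared choice where the CI
method is otherwise unspecified. Floor/ceiling effects flag above 15% of
respondents at the minimum/maximum raw score. Every stochastic stage takes
a seed derived from the master seed, making the whole pipeline reproducible
run-to-run.

## Problem sizes and numerical choices, collected

- Quadrature: 61 nodes on $[-4, 4]$; EAP tested against a 10,001-point
  trapezoid oracle.
- EM: tolerance $10^{-4}$ on the largest parameter change, max 500 cycles;
  recovery tested at $n = 1000$ (15 items) and $n = 5000$ (2 items).
- $S\text{-}X^2$: expected-cell floor 1; type-I calibration over 200
  replicates at $n = 700$, 5 items.
- Polychoric search bound $\pm 0.999$, optimizer tolerance $10^{-5}$;
  48-node Gauss–Legendre $\Phi_2$.
- Parallel analysis: 100 replicates by default; the bundled tests use
  10–20 replicates on cohorts of 400–900 persons.
- DIF simulations: two groups of 750, 20 seeds for the specificity and
  sensitivity sweeps.
- CAT reproduction: validation samples of 196/199 rebuilt from the decile
  profiles, 10 seeds.
- Tie thresholds: duplicate or non-monotone thresholds are rejected at
  validation; the EM's log-gap floor ($10^{-6}$) keeps fitted thresholds
  strictly ordered.
- Degenerate categories: calibration requires at least two observed
  categories per item (error otherwise); the DIF fitter merges unobserved
  categories upward.

## Known limitations

- The CFA fit indices approximate, and will not reproduce, scaled robust
  DWLS values from structural-equation software.
- Only unidimensional GRM is supported — no dichotomous 2PL/3PL shortcuts,
  no multidimensional or bifactor models, no MCMC calibration.
- DIF is two-group only, by the fixed 2% pseudo-$R^2$ rule; no
  Mantel–Haenszel, SIBTEST, or Monte-Carlo thresholds.
- Linking offers Stocking–Lord only (no Haebara, mean-mean, mean-sigma, or
  concurrent calibration).
- The CAT engine is post-hoc: it cannot administer live tests, and persons
  missing a selected item simply skip it.
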