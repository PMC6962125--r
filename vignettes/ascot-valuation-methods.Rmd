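---
title: "Valuing ASCOT SCT4 states: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing ASCOT SCT4 states: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascotval)
```

## The problem

The Adult Social Care Outcomes Toolkit four-level self-completion
questionnaire (ASCOT SCT4) describes social care-related quality of life
(SCRQoL) with eight scoring domains — control over daily life, personal
cleanliness, food and drink, personal safety, social participation,
occupation, accommodation cleanliness, and dignity — each at one of four
levels (1 best to 4 worst). A *state* is one level per domain, written as
an 8-digit string in questionnaire order with control first: `"24313222"`
is second-level control with fourth-level personal cleanliness, and the
state space holds $4^8 = 65{,}536$ states. (The instrument itself has a
ninth item, the first dignity question; it supports interpretation of the
second dignity question and is not scored, so it does not appear in the
domain model.)

To use ASCOT in economic evaluation, states need utilities on the
quality-adjusted life-year scale: 1 for the best state, 0 for dead,
negative for states worse than dead. National valuation studies obtain
these in two stages — profile-case (case 2) best–worst scaling (BWS) for
the relative weight of each (domain, level) item, and composite time
trade-off (cTTO) to anchor the resulting latent scale to dead = 0. This
package implements that estimation pipeline, ships the published Japanese
and UK value sets, and, because the raw survey data behind them are not
public, validates the estimators by parameter recovery on synthetic
surveys generated under the same design.

## Utility model and choice coding

Respondents see one profile at a time and pick, sequentially, the best
domain (from 8), the worst (from the remaining 7), the second-best (6)
and the second-worst (5). Under random utility, the utility respondent
$j$ attaches to item $i$ is $U_{ij} = V_{ij} + \varepsilon_{ij}$ with
i.i.d. Gumbel noise, and

$$V = \sum_{p \ne 5} \beta_p X_p + \sum_{p,\,q \le 3} \beta_{pq} X_{pq},$$

where $X_p$ indicates the item's domain and $X_{pq}$ its (domain, level)
pair. Control over daily life ($p = 5$) is the reference domain and
level 4 the reference level, leaving $7 + 24 = 31$ parameters. Worst-side
choices enter with indicators set to $-1$, so a worst pick is modelled as
maximizing $-V$ plus fresh Gumbel noise. Each task thus explodes into
four conditional-logit occasions with 26 alternative rows, and the
exploded likelihood treats the four occasions as independent.

`explode_bws()` performs the sequential removal, `bws_design_matrix()`
builds the sign-coded 31-column matrix, and `fit_bws_mnl()` maximizes the
exploded likelihood (analytic gradient, BFGS, then Newton polishing with
the analytic Hessian; convergence is declared when the mean score drops
below $10^{-5}$ per occasion, and polishing in practice drives it far
below that). Standard errors are cluster-robust by respondent, since the
32 occasions of one respondent share tastes.

### Mixed logit

`fit_bws_mixed()` relaxes the independence-of-irrelevant-alternatives
assumption by letting the domain constants vary across respondents:
$\beta_p = \beta_p^m + \beta_p^s \eta$ with standard-normal $\eta$, or
$\beta_p = \exp(\beta_p^m + \beta_p^s \eta)$ for log-normal mixing. The
simulated likelihood averages each cluster's product of occasion
probabilities over Halton draws (burned-in, Cranley–Patterson rotated,
one fixed segment per cluster so results are seed-deterministic and
independent of data ordering). Two clustering schemes are supported: the
whole respondent, or the respondent's best-side and worst-side choices
as separate clusters — the latter reflecting the view that best and
worst picks may be driven by heterogeneous tastes.

Design choices worth stating explicitly:

* **Random coefficients sit on the 7 domain constants only.** The mixing
  equation is written for $\beta_p$; level effects stay fixed. This keeps
  the random-coefficient dimension small enough for stable simulated
  maximum likelihood at survey scale.
* **The scale parameters are estimated unconstrained.** The likelihood is
  symmetric in the sign of $\beta_p^s$, so the raw scale is left free
  (the objective stays smooth at zero) and $|\hat\beta_p^s|$ is reported.
* **Draws default to 500**; recovery experiments in the test suite use
  100, which at 800 respondents already gives scale SEs around 0.03–0.1.
* **Standard errors are BHHH/OPG** (outer product of per-cluster score
  gradients). The per-cluster scores fall out of the analytic gradient at
  no extra cost, whereas a finite-difference Hessian in 38 parameters
  costs about eighty additional likelihood passes.
* **Zero scales sit on a boundary.** When a true mixing scale is zero the
  Wald statistic $|\hat s|/\mathrm{SE}$ is not asymptotically standard
  normal (the classic boundary problem for variance components), so the
  validation suite judges recovery of degenerate scales by magnitude
  rather than by t-statistics; Wald checks are reserved for parameters in
  the interior.
* **Log-normal reporting convention:** the reported location/scale are
  the log-scale parameters of $\exp(m + s\eta)$, not the moments of
  $\beta_p$. Published tables using a different convention for their
  log-normal model cannot be compared entry-for-entry.

## From coefficients to a tariff

Item coefficients are sums of domain and level effects,
$c_{pq} = \beta_p + \beta_{pq}$ (zero for control level 4 by double
reference), and the tariff rescales them linearly so control level 1
maps to 1 and control level 4 to 0 — with this reference structure,
simple division by $c_{5,1}$. `rescale_weights()` keeps full precision
internally; the published 3-decimal rounding is applied only when
writing. The latent BWS score of a state is the sum of its eight
applicable weights.

## cTTO scoring and anchoring

Better-than-dead responses score $x/10$; worse-than-dead responses use
the lead-time protocol and score $y/10 - 1$, bounding utilities at $-1$.
State values are unweighted means over retained respondents. The linear
anchoring map $TTO_i = a\,\mathrm{BWS}_i + b + e_i$ is fitted over the 64
valued states subject to $a\,\mathrm{BWS}_{\max} + b = 1$ (the best state
must score 1), which leaves one free parameter with the closed form

$$\hat a = \frac{\sum_i (TTO_i - 1)(\mathrm{BWS}_i - \mathrm{BWS}_{\max})}
               {\sum_i (\mathrm{BWS}_i - \mathrm{BWS}_{\max})^2},
\qquad \hat b = 1 - \hat a\,\mathrm{BWS}_{\max}.$$

$R^2$ is reported as $1 - SSR/SST$ about the mean of the observed state
values; because the fit is constrained this can differ from the squared
correlation between fitted and observed values, which is reported
alongside. The slope's SE uses the one-parameter residual variance
($n - 1$ degrees of freedom) and the intercept's follows by the delta
method through $b = 1 - a\,\mathrm{BWS}_{\max}$; t-statistics from an
unconstrained two-parameter fit would be a different quantity and are
deliberately not computed. States valued by zero retained respondents
(possible only under aggressive filtering at small synthetic sample
sizes) are flagged with a warning and excluded from the regression.

## Exclusion rules

Respondents with total BWS time under 4.5 minutes are excluded from the
BWS analysis set, and respondents with total cTTO time under 5.0 minutes
from the TTO analysis set. Both thresholds are strict (a respondent
exactly at the threshold is retained) and the two filters are
independent, matching the separate exclusion counts reported by the
valuation studies.

## The synthetic-survey generator

With no public raw data, the generator is the ground truth against which
every estimator is validated. Its defaults are the study conditions of
the Japanese valuation survey:

* 1050 respondents; 4 BWS blocks × 8 profiles from a 32-profile design;
  8 cTTO blocks × 8 states (64 states); one valuation per
  (respondent, state).
* The true coefficients default to the published Japanese
  conditional-logit estimates, so simulated data resemble the real
  preference structure.
* Choices are generated occasion by occasion with fresh Gumbel draws —
  exactly the independence structure the exploded likelihood assumes.
* cTTO values are the truth conversion applied to the latent score under
  the truth-implied tariff (the same rescaling the analyzer uses, keeping
  generator and analyzer on one scale), plus Gaussian noise
  (SD 0.1 by default), clamped to $[-1, 1]$; answers are rounded to a
  0.5-year grid, the granularity we assume for the 0–10 graduated bar the
  instrument shows (the instrument documentation does not state one).
* Response times are log-normal with medians matching the reported ones
  (9.6 min BWS, 10.1 min TTO) and dispersions placing roughly 3–5% of
  respondents under the exclusion thresholds, so the filters are
  exercised without being asserted as targets.
* The published 32-profile fractional-factorial design and the identity
  of the 64 cTTO states are attributed to prior work and not printed;
  `make_bws_design()` substitutes a level-balanced random design (each
  level of each domain appears equally often) that is deterministic in
  its seed.

What the generator does *not* emulate: interviewer effects, learning or
ordering effects, the randomized on-screen ordering of domain
descriptions (a presentation device, not a model term), item non-response,
and any response-quality problems beyond short completion times. Passing
recovery tests therefore demonstrate correctness of the estimators under
the model's own assumptions, not robustness to real-world violations of
them.

## Numerical choices

* Conditional logit: BFGS with analytic gradient from a zero start,
  Newton polish, relative log-likelihood tolerance $10^{-10}$; occasion
  log-sum-exp is max-subtracted whenever linear indices grow large, so
  log-probabilities stay finite for $|V| \le 700$.
* Simulated likelihood: the draw loop is compiled (C++); per-cluster
  log-likelihoods are max-subtracted across draws before averaging.
  Relative tolerance $10^{-8}$.
* Rank deficiency of the design matrix raises an identifiability error
  naming the collinear columns rather than silently dropping them.
* Ties in simulated choices (zero-probability events) resolve to the
  first index; sign conventions make best- and worst-side coding exact
  mirrors.
* Pipeline reproducibility: a single master seed fans out to per-stage
  seeds (`seed * 10 + offset`), and the run manifest records config and
  file checksums, so reruns are hash-stable.

## Scoring with the published value sets

```{r}
jp <- ascot_tariff("JP")
uk <- ascot_tariff("UK")
scqaly_score(c("11111111", "24313222", "44444444"), jp, ascot_conversion("JP"))
scqaly_score(c("11111111", "24313222", "44444444"), uk, ascot_conversion("UK"))
```

Both published tariffs are stored exactly as printed (3 decimals) and
are monotone: worsening any single domain never raises the score. The
printed conversions reproduce the published Japanese score range
$[-0.38, 1.00]$ exactly.

One caveat a user of the cross-country comparison should know: scoring
all 65,536 states under both printed tariffs and conversions yields
*more* states with a higher UK score (63,528, i.e. 96.9%), a higher
Pearson correlation (0.95) and a higher agreement ICC (0.76, stable
across ICC variants — see the `icc_sweep` field of `compare_tariffs()`)
than the originally reported trio (59,666 / 0.91 / 0.70). Pearson
correlation is invariant to affine rescaling, so no choice of linear
conversion parameters can reconcile the printed weight tables with the
printed correlation; the original statistics were evidently computed
from unrounded internal quantities that were never published. The
package reports what the printed tables imply.

## Sizes used in the validation suite

Recovery experiments run at the published scale where that is what is
being claimed (500 respondents for conditional-logit recovery, 800 for
mixed-logit scale recovery with 100 draws, 1050 respondents and 64
states for anchoring and the end-to-end pipeline); structural unit tests
use 10–200 respondents. At these sizes the whole validation suite runs
in minutes on one core.

## Known limitations

* Table-level reproduction of the original coefficient estimates is
  impossible without the raw survey data; recovery on synthetic data is
  the substitute, and it cannot detect discrepancies between the
  published estimates and the published data collection.
* The mixed logit integrates over at most seven random coefficients with
  independent mixing; correlated tastes across domains are not modelled.
* No imputation: states or respondents with incomplete pick sequences
  are rejected, not repaired.
* The balanced random design is a stand-in for the original
  fractional-factorial design; efficiency comparisons between designs
  are out of scope.
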