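---
title: "From stated choices to MCDA criterion weights for orphan drugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stated choices to MCDA criterion weights for orphan drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dceweights)
library(dplyr)
```

## The problem

Reimbursement bodies deciding whether an orphan drug enters a basic
medical insurance formulary must weigh value dimensions that conventional
cost-effectiveness analysis does not capture: how severe the disease is,
whether alternatives exist, what the drug does for quality of life, its
safety and evidence base, and its cost to the insurance fund. A
multi-criteria decision analysis (MCDA) framework makes those dimensions
explicit, but it needs *criterion weights*. `dceweights` implements a
complete workflow for deriving such weights from a discrete choice
experiment (DCE) among decision-makers, alongside the simpler SMART
direct-rating benchmark.

The packaged value schema has seven attributes, three levels each —
disease severity, unmet needs, drug efficacy, improvement in
health-related quality of life (HRQoL), drug safety, quality of drug
evidence, and annual treatment cost (500,000 / 200,000 / 80,000 RMB per
year). Six attributes are categorical and dummy coded against their least
attractive level; cost is continuous in units of 10,000 RMB per year, so
its levels enter as 50, 20 and 8. The design vector therefore has 13
entries, matching the 13 part-worth coefficients of the utility model.

## The choice model

Respondent $i$'s utility for alternative $j$ in a choice task is the
linear random-utility model
$$U_{ij} = \beta_i^\top x_{ij} + \varepsilon_{ij},$$
with i.i.d. Gumbel errors, an alternative-specific constant on the
opt-out ("neither drug") alternative, and, in the mixed logit,
independent normal heterogeneity $\beta_i \sim N(\mu, \mathrm{diag}(\sigma^2))$
on the twelve categorical dummies. Cost and the opt-out constant are held
fixed across respondents in the default specification; with 13 means, one
constant and 12 standard deviations the model counts $k = 26$ parameters.
This particular split is not arbitrary: it is the unique allocation under
which the AIC ($2k - 2\ell$) and BIC ($k\ln N - 2\ell$) identities
reproduce the information criteria of the reference analysis bundled in
`reference_fit_stats()` with $N$ equal to 3 alternatives × 10 scored
tasks × the group size, which also implies that the repeated consistency
task is excluded from estimation. `build_long_format()` follows both
conventions by default.

The panel mixed logit is estimated by maximum simulated likelihood,
$$\hat\ell = \sum_i \log \frac1R \sum_{r=1}^R \prod_t
P(y_{it} \mid \mu + \sigma \odot z_{ir}),$$
with $R$ Halton draws per respondent (default 500, first 10 points
burned; draw count and seed are recorded in every fit). The likelihood
and its analytic score are computed in compiled code; optimization is
BFGS with a relative log-likelihood tolerance of `1e-8`, started from the
conditional-logit fit with standard deviations at 0.1. Standard errors
come from the inverse negative Hessian of the simulated likelihood,
obtained by central finite differences of the analytic score; if that
matrix is singular the standard errors are reported as `NA` rather than
fabricated, and non-convergence is flagged on the result rather than
raised, so pipelines can log and continue. Reported standard deviations
are sign-normalized to be non-negative (the likelihood is even in each
$\sigma_k$).

## Design of the choice sets

A full factorial of the schema has $3^7 = 2187$ profiles, far too many to
field, so `generate_design()` searches for a D-efficient fractional
design of 30 paired sets: coordinate exchange sweeps every (set,
alternative, attribute) position, keeps any level swap that increases the
determinant of the multinomial-logit information matrix, and repeats to
convergence over several random restarts. The D-error reported is
$\det(I)^{-1/K}$. The default prior is zero (utility-neutral) because no
prior coefficients are assumed at design time; a nonzero prior vector is
accepted. Identical alternatives within a set are excluded during the
search (they carry no information); dominated pairs are not forbidden.
Accepted swaps never increase the D-error, so the result is never worse
than the random design it starts from.

The 30 sets are split into three blocks of ten with a greedy
pairwise-swap heuristic that balances attribute-level frequencies across
blocks (the blocking objective is a design choice; any equal split is
admissible). Each block becomes an 11-task questionnaire: its ten sets in
seeded random order plus a repeat of one seed-chosen set, inserted at
least two positions after its original, as an internal-consistency probe.
An opt-out alternative is offered on every task; it is deliberately
excluded from design optimization and appended at questionnaire assembly,
since the paired sets are designed first and the opt-out is a constant
alternative with no attribute content.

## What the simulator emulates — and what it does not

Because raw survey data of this kind are typically not public, the
package ships a generator whose defaults are the study conditions the
analysis assumes, and they are fixed once:

* part-worth means equal to the pooled published estimates
  (`reference_estimates("all")`), opt-out constant 2.454 attached to the
  opt-out utility (its published definition; `asc_on = "drugs"` is
  available because the sign convention is ambiguous in principle);
* between-respondent standard deviations of $0.5\,|\mu|$ — the published
  tables report no heterogeneity magnitudes, so a moderate, scale-free
  default was chosen once and is used throughout the tests;
* a careless fraction of 15/84, drawn as a deterministic count, choosing
  uniformly at random with completion times below the 8-minute validity
  threshold — so a default 84-respondent panel filters to exactly 69
  valid respondents, mirroring the reference study's disposition;
* attentive completion times lognormal with median 12 minutes truncated
  at the 8-minute threshold (attentive respondents never fail the time
  rule by construction), careless median 5 minutes truncated above;
* SMART scores equal to each respondent's own part-worth ranges rescaled
  to a maximum of 100 plus $N(0, 10)$ noise clipped to $[0,100]$, with
  ranks the descending order of scores. DCE-derived and SMART weights are
  therefore correlated but not identical, which is the qualitative
  pattern the two methods show in practice.

The generator does not model attribute non-attendance, learning or
fatigue across tasks, item nonresponse, or correlated random
coefficients. Passing tests therefore demonstrate that the estimation and
weighting machinery is correct under the stated data-generating process,
not that real decision-makers behave this way.

## Validity screening

`filter_survey()` applies three rules: completion time $\ge$ 8 minutes
(compared exactly, sub-minute precision preserved); an identical choice
on the repeated task (the strict reading of an internal-consistency
test); and, for respondents failing consistency only, a SMART fallback —
the respondent is kept when their importance ranking is logically aligned
with their scores, formalized as weak-order concordance: no pair may have
a strictly higher score and a strictly worse rank, ties unconstrained.
Verdicts depend only on the respondent's own record, so filtering is
idempotent and order-invariant; every respondent receives an audit row
with reason codes.

## From coefficients to weights

Three summaries convert a fitted model into decision weights:

* **Relative importance.** Each attribute's share of the total utility
  range, $RI_a = (\beta_a^{\max} - \beta_a^{\min}) / \sum_c
  (\beta_c^{\max} - \beta_c^{\min})$. For categorical attributes the
  range includes the reference level at 0 — important when an
  intermediate level beats the highest-coded one (drug evidence behaves
  this way: "Moderate" can exceed "High"). For the continuous cost
  attribute the range is $|\beta_{cost}|$ times the span of its level
  values ($50 - 8 = 42$ in 10,000 RMB). The published formula speaks only
  of coefficient ranges; this reading of the continuous case is an
  interpretation, adopted because it reproduces all 21 published weight
  cells from the published coefficients within rounding error of the
  3-decimal printed values (the package's acceptance tests assert
  exactly that).
* **Willingness to pay.** $WTP = -\beta_{level}/\beta_{cost}$ per
  non-reference level, in 10,000 RMB per year; reference levels are 0 by
  convention. Delta-method standard errors are attached when a
  coefficient covariance is available. A cost coefficient within `1e-8`
  of zero is an error, not an infinite answer.
* **SMART weights.** Per-respondent score normalization, then averaging;
  mean ranks are reported alongside, and *both* orderings (by mean
  weight and by mean rank) are returned without reconciliation, since
  they legitimately differ. All-zero score vectors are excluded from
  score averaging and logged.

`compare_weighting_methods()` quantifies DCE/SMART agreement with
Spearman and Kendall rank correlations and top-3 overlap.

## A worked run

```{r pipeline, eval = FALSE}
report <- run_pipeline(pipeline_config(seed = 1))
report$weights$all$ri
autoplot(report$weights$all$ri)
```

The default configuration generates the 30-set design, simulates 84
respondents, filters to 69, fits conditional and mixed logit per group,
and derives the three weight tables. (The vignette chunk is not executed
at build time; the fit takes a few minutes.)

## Numerical choices and problem sizes

Fixed numerical conventions, chosen once: coordinate-exchange swaps are
accepted only when the log-determinant improves by more than `1e-12`;
ties in SMART ranks break by first occurrence; the categorical sampler
inverts a single uniform per respondent-task; Halton dimensions map to
the first 25 primes with optional digit-permutation scrambling (the
identity permutation on digit 0 keeps points in the open interval). The
test suite exercises the estimator at 500 respondents × 10 scored tasks ×
500 draws — the scale at which parameter recovery is asserted (at least
90% of the 26 parameters within 3 estimated standard errors of truth) —
and smaller panels elsewhere; the design benchmark compares 20 paired
seeded trials of coordinate exchange against random designs of equal
dimensions.

## Known limitations

Standard errors are conventional inverse-Hessian errors, not
sandwich/clustered; there is no latent-class or correlated-coefficient
mixing, no WTP-space estimation, no Bayesian-prior efficient design, no
interaction-effect designs, and no aggregation of weights with drug
performance into an overall MCDA score. Sensitivity analysis of the
weights is out of scope. The simulated-likelihood surface is noisy in
the standard deviations at small draw counts; with the default 500
Halton draws the likelihood changes by less than 0.1% when draws double,
which the tests assert on a fixture.
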