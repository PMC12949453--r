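---
title: "Stated-preference analysis of treatment attributes with dcepref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stated-preference analysis of treatment attributes with dcepref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcepref)
```

## The problem

When a clinical trial platform must choose which candidate drugs to evaluate
first, the views of patients and the public are part of the evidence. Two
survey instruments are common. A *ranking task* asks each respondent to place
a small set of named candidate drugs in strict order of preference. A
*discrete choice experiment* (DCE) asks the respondent to choose repeatedly
between pairs of hypothetical drugs whose attributes — dosing schedule,
monitoring burden, strength of evidence, side-effect risk — are varied
systematically, or to take neither. The choices reveal how much weight each
attribute carries.

dcepref implements the full analysis chain for such a survey: construction of
an efficient choice design, a generative simulator used for testing and power
exploration, mixed logit estimation, rank aggregation, attribute-importance
calculation, subgroup comparison and a subsample stability check.

The built-in study instance (`adsmart_attributes()`) has five attributes:
dosage frequency (once daily / divided daily), monitoring requirement
(required / not required), type of evidence (pre-clinical animal trials /
human trials), and the probabilities of mild and of severe side effects
(common or very common / uncommon / rare or very rare). That is a
2×2×2×3×3 factorial of 72 distinct hypothetical drug profiles. Reference
levels are once-daily dosing, monitoring required, animal evidence, and
common-or-very-common side effects; with dummy coding the model has 7
attribute coefficients.

## The choice model

Respondent $i$ derives utility from alternative $j$ in task $t$:

$$U_{ijt} = x_{jt}'(\beta + \eta_i) + \alpha\,\mathrm{optout}_j + \varepsilon_{ijt},$$

where $x_{jt}$ are the dummy-coded attribute levels, $\beta$ are mean
part-worth utilities relative to the reference levels, $\eta_i \sim
N(0,\mathrm{diag}(\sigma^2))$ are respondent-specific deviations constant
across that respondent's tasks (the panel structure), $\alpha$ is an
alternative-specific constant for the "neither" option (whose attribute
vector is zero), and $\varepsilon_{ijt}$ is iid Type I extreme value
(Gumbel). Conditional on $\eta_i$ the choice probabilities are softmax
(`mnl_probability()`); integrating over $\eta_i$ gives the mixed logit.

`fit_mixed_logit()` maximises the simulated log-likelihood

$$\mathrm{SLL}(\beta,\sigma,\alpha) = \sum_i \log \frac{1}{R} \sum_{r=1}^R
\prod_t P\big(\text{choice}_{it} \mid \beta + \sigma \circ z_{ir}\big),$$

with $z_{ir}$ standard-normal quantiles of a Halton sequence (prime bases
2–17, first 10 points skipped, one consecutive block of $R$ draws per
respondent). The optimizer is BFGS with the analytic score, followed by a
Newton polish using a finite-difference Hessian of the score; convergence is
declared when the gradient infinity-norm falls below `tol` (default `1e-5`).
Spreads are reported as $|\sigma|$ because the sign of a normal spread is not
identified. Standard errors come from the inverse observed information at
the optimum. `fit_mnl()` is the fixed-coefficient special case
($\sigma \equiv 0$), used both on its own and as a nesting oracle: the
simulated likelihood at $\sigma = 0$ equals the MNL likelihood for any
number of draws, which the test suite asserts to $10^{-6}$.

### Choices the model fixes by convention

* **Random coefficients.** The published results report one coefficient per
  non-reference level, so all 7 level coefficients carry their own
  independent normal deviation by default (`mixlogit_spec(random = ...)`
  restricts this; correlated deviations are out of scope). A lognormal
  option exists in the simulator for sign-constrained coefficients.
* **Opt-out.** "Neither" enters as a constant-only alternative, both in the
  generative model (default constant −2, making the opt-out rare, as in a
  survey where most respondents pick a drug) and in estimation.
* **Draws.** Default $R = 500$ Halton draws per respondent; parameter
  recovery work in the test suite uses $R$ between 50 and 200 to stay fast.

## Design construction

`generate_defficient_design()` minimises the D-error
$\det(I^{-1})^{1/K}$ of the multinomial-logit information matrix of a
paired design, evaluated at a prior coefficient vector (default zero, the
utility-neutral design; an informative prior can be supplied). The search is
profile-swap coordinate exchange: starting from a random design, each
alternative of each task is offered every factorial profile in turn and the
first strict improvement is accepted, until a full pass finds none. Accepted
moves never increase the D-error, so the result is never worse than its
random start; restarts (`n_restarts`) guard against local optima — on a 2×2
toy factorial the search with a handful of restarts attains the exhaustively
enumerated optimum, which the tests verify. The opt-out alternative carries
no attribute information and is excluded from design evaluation — a
deliberate simplification, standard when the opt-out is modelled as a bare
constant.

Blocking splits the tasks into equal subsets (the study instance: 12 tasks
into 4 blocks of 3) so each respondent answers only a few tasks. The
assignment is a greedy heuristic that places each task in the open block
minimising the sum of squared attribute-level counts, i.e. spreading every
level as evenly as possible across blocks; ties go to the lowest block
index, making the assignment deterministic.

`make_attention_check()` builds a task whose alternative A holds the most
desirable level of every attribute while B is strictly worse in at least two
attributes and never better. "Desirable" follows the `desirability` ranks of
the attribute set (rarer side effects, human evidence, once-daily dosing,
and — matching the sign of the estimated monitoring coefficient — monitoring
required). The check's content is this package's own construction; survey
instruments rarely publish theirs.

## The synthetic cohort

`simulate_cohort()` emulates the structure of a ~3,250-respondent
web survey so that every downstream stage can be tested without access to
raw data (none is deposited with the study this package models):

* demographics drawn independently from the published margins: 8 age bands
  (31.3% aged 65–74; 71.2% aged 55+), gender 68.0% female / 31.3% male /
  0.7% other categories, and six dementia-experience categories
  (46.4% friend-or-family, 16.7% carer, 5.6% work, 2.8% living with
  dementia, 27.2% none, 1.4% prefer not to say);
* a blocked design answered three tasks at a time (blocks assigned
  round-robin), plus one attention-check task with configurable pass
  probability (default 1, so the filtered and unfiltered cohorts coincide
  and tests are deterministic);
* choices generated from the mixed logit above, one coefficient draw per
  respondent reused across tasks;
* rankings of the four candidate drugs from a random-utility
  (Plackett–Luce / exploded logit) model: utility = drug worth + Gumbel
  noise, ranking = descending sort.

The default drug worths are the logs of the published first-rank shares
(metformin 35.5%, isosorbide mononitrate 27.4%, atomoxetine 25.7%,
levetiracetam 11.3%), so the model's implied first-choice probabilities
reproduce those shares exactly — a calibration to printed values, not a free
parameter. The default mean part-worths are the published mixed-logit means
and the default spread is 0.5 per coefficient.

Preferences may differ by stratum (`cohort_config(stratum_prefs = ...)`),
keyed by the age-65-by-gender strata; magnitudes of such effects are user
configuration, never asserted as ground truth. What the simulator does *not*
emulate: joint dependence between age, gender and experience (margins are
independent), country or language effects, attitude items, free text, or
missing data. Tests that pass on this cohort therefore certify the analysis
pipeline, not the behaviour of any real population.

A note on cohort size: the study this package models reports 3,250
respondents in its abstract and 3,251 in its results table; the generator's
default is `n_respondents = 3250` and the descriptive recomputations in the
tests use the 3,251 denominator of the published table. The discrepancy is
in the source and is left unresolved.

## Rank aggregation

`tabulate_ranks()` counts, per drug, the times it was ranked 1st–4th
($\eta_1,\dots,\eta_4$); `weighted_scores()` applies the Borda-style scheme

$$\text{weighted score} = 4\eta_1 + 3\eta_2 + 2\eta_3 + 1\eta_4 .$$

Since every respondent distributes $4+3+2+1 = 10$ points, the four drugs'
scores always sum to $10n$ — a conservation law the tests assert. Rank
percentages are rounded half-up to one decimal, matching the published
presentation (base `round()` rounds halves to even, which would not).
Respondents with missing or partial rankings are excluded listwise from
ranking analyses.

## Relative importance and subgroups

`relative_importance()` computes, per attribute, the range of its level
coefficients *including the implicit zero of the reference level*
($\max(0, \hat\beta_k) - \min(0, \hat\beta_k)$) and expresses each range as
a share of the sum of ranges. Including the reference zero is essential:
attributes whose single coefficient is negative (dosage frequency,
monitoring) would otherwise have zero range. The ranges use mean
coefficients only, the shares are scale-invariant, and feeding in the
published means (−0.525, −0.128, 1.261, 1.037/1.311, 3.247/3.340)
reproduces the published shares 50.88 / 19.97 / 19.21 / 8.0 / 1.95 percent
exactly — the package's primary reproduction target.

Subgroup analysis (`stratify_and_fit()`) fits independent models per
stratum. Two stratifiers are supported, with 65 years as the age cutoff:
age-65-by-gender (four strata; respondents outside the female/male
categories are excluded from this stratifier but retained overall) and the
four dementia-experience roles. Strata below `min_size` (default 50) are
fitted but flagged exploratory, mirroring how small patient subgroups are
treated in underpowered surveys. `compare_groups()` tests a coefficient
between two strata with the two-sample z statistic
$z = (\hat b_a - \hat b_b)/\sqrt{se_a^2 + se_b^2}$ on the separately fitted
models — the reading consistent with "separate models and between-group
comparisons" — unadjusted by default (significance stars per pair at
0.05/0.01/0.001), with an optional Bonferroni adjustment. Under a null
simulation the p-values are uniform, which the tests check by
Kolmogorov–Smirnov.

`stability_curve()` refits the model on ascending-id prefixes of the
respondents (e.g. first 500, 1,000, 1,500, all) and reports the maximum
absolute coefficient change between successive cuts, a post hoc check that
estimates have stabilised.

## Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction; probabilities sum to 1 to
  $10^{-12}$ and are shift-invariant.
* A design task comparing a profile with itself contributes no information;
  a design whose information matrix is rank-deficient gets D-error `Inf`
  rather than an error.
* Collinear coded columns abort the fit naming the offending columns;
  indicator columns that are always (or never) chosen trigger a separation
  warning.
* Tiny strata whose model cannot be fitted are skipped with a warning;
  comparisons lacking a standard error are skipped with a warning by the
  batch wrapper while the single-pair function errors, so silent NAs never
  propagate.
* Halton draws are deterministic, so every fit is bit-reproducible given its
  specification; the simulator is seeded through `withr::with_seed` and
  never disturbs the caller's RNG state.

## Test scales and what they show

The test suite runs everything on synthetic data at reduced scale: design
searches at 12 tasks, estimation checks at 150–5,000 respondents, parameter
recovery for the mixed logit at 1,500–2,000 respondents with 50–200 draws,
and the null-uniformity study at 200 replicates of 160 respondents on a toy
design. One caveat established quantitatively during development and worth
restating: with only three tasks per respondent — the blocked design a real
respondent actually answers — the random-deviation spreads $\sigma$ are
weakly identified. The inverse information at the true parameters puts
their sampling SEs at 0.22–0.42 (and up to 0.25 for the largest mean
coefficients), so point recovery of every $\sigma$ within a tight band
cannot be expected at n = 2,000; with all twelve tasks per respondent the
same estimator recovers both $\beta$ and $\sigma$ comfortably. Analyses of
such designs should treat fitted spreads as noisy, and the package reports
their standard errors so users can see this.

## Known limitations

Bayesian-prior (distributional) D-efficiency, designs with more than two
profile alternatives, adaptive designs, correlated random coefficients,
latent-class models, willingness-to-pay transforms and formal interaction
models pooling strata are all out of scope. The simulator's independence
assumptions are listed above.
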