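# dcepref

Design, simulation and analysis of stated-preference surveys on treatment
attributes: discrete choice experiments (DCEs) paired with a drug-ranking
task, for researchers eliciting patient and public preferences to inform
trial design.

The package covers the whole chain:

* **D-efficient choice designs** — profile-swap coordinate exchange
  minimising `det(I⁻¹)^(1/K)` of the multinomial-logit information matrix,
  blocked for respondent burden, plus dominated attention-check tasks;
* **a synthetic-respondent simulator** — a random-utility generator for
  choices (panel mixed logit with Gumbel errors and an opt-out alternative)
  and for strict drug rankings (Plackett–Luce), with configurable
  demographic strata;
* **mixed logit estimation** — simulated maximum likelihood with Halton
  draws, analytic scores, Newton polishing and observed-information standard
  errors; multinomial logit as the nested special case;
* **rank aggregation** — per-position tallies η₁…η₄ and the Borda-style
  weighted score `4η₁ + 3η₂ + 2η₃ + 1η₄`;
* **attribute relative importance** — each attribute's coefficient range
  (including the implicit 0 of its reference level) as a share of the sum of
  ranges;
* **subgroup comparison and stability** — independent per-stratum fits with
  two-sample z tests, and refits on growing respondent prefixes.

The built-in study instance is a five-attribute drug-profile experiment
(dosage frequency, monitoring, type of evidence, mild and severe side-effect
risk; a 2×2×2×3×3 factorial of 72 profiles, 12 tasks in 4 blocks) together
with a ranking of four candidate dementia drugs.

## The model

Respondent *i* chooses among two hypothetical drugs and a "neither" option;
utility is

```
U_ijt = x_jt' (β + η_i) + α·optout_j + ε_ijt,   η_i ~ N(0, diag(σ²)),
ε_ijt ~ Type I extreme value
```

with dummy-coded attribute levels `x_jt` relative to reference levels. The
simulated log-likelihood averages each respondent's product of softmax task
probabilities over `R` Halton-based normal draws. Attribute importance is
`range_k / Σ_j range_j` with `range_k = max(0, β̂_k) − min(0, β̂_k)` over the
attribute's level coefficients.

## Worked example

```r
library(dcepref)

attrs  <- adsmart_attributes()
design <- generate_defficient_design(attrs, n_tasks = 12, n_blocks = 4, seed = 1)
attr(design, "d_error")
#> [1] 0.4580859

cohort <- simulate_cohort(cohort_config(n_respondents = 500, seed = 1), design)
kept   <- apply_attention_filter(cohort$respondents, cohort$choices, "exclude-fail")

weighted_scores(tabulate_ranks(cohort$rankings))[, c("drug", "eta1", "weighted_score")]
#> # A tibble: 4 × 3
#>   drug                    eta1 weighted_score
#>   <chr>                  <int>          <int>
#> 1 metformin                175           1452
#> 2 isosorbide mononitrate   138           1332
#> 3 atomoxetine              131           1304
#> 4 levetiracetam             56            912

fit <- fit_mixed_logit(kept$choices[!kept$choices$is_attention, ],
                       mixlogit_spec(n_draws = 100))
glance(fit)
#> # A tibble: 1 × 7
#>   model log_likelihood n_respondents n_tasks n_draws  grad_norm converged
#>   <chr>          <dbl>         <int>   <int>   <int>      <dbl> <lgl>
#> 1 mixed          -543.           500    1500     100 0.00000472 TRUE

relative_importance(fit, attrs)
#> # A tibble: 5 × 4
#>   attribute  range share share_pct
#>   <chr>      <dbl> <dbl>     <dbl>
#> 1 severe     3.36  50.2      50.2
#> 2 mild       1.47  21.9      21.9
#> 3 evidence   1.16  17.3      17.3
#> 4 frequency  0.567  8.48      8.48
#> 5 monitoring 0.137  2.04      2.04
```

The weighted scores say metformin collects the most rank-1 points under the
4/3/2/1 scheme (each respondent hands out 10 points, so the four scores sum
to 10 × 500). The importance table says severe side-effect risk drives about
half of the utility variation a drug profile can span, with dosing frequency
and monitoring nearly irrelevant — at n = 500 the fitted shares sit within a
couple of points of the generating values.

`run_pipeline(run_config(...))` chains design → simulation → attention
filter → rank summaries → estimation → importance → subgroups → stability
and writes every table (plus a JSON manifest with seeds and a config hash)
as commented CSV. A thin command-line wrapper lives at
`inst/cli/dcepref.R`:

```sh
Rscript inst/cli/dcepref.R run-all --config config.yaml
```

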