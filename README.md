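# irmpro

Item-based pharmacometric analysis of daily patient-reported outcome
diaries, built around the 14-item EXACT COPD symptom instrument and its
11-item E-RS:COPD subset.

## The problem

Phase-II COPD trials often analyse a daily symptom diary by collapsing the
14 ordinal items into one total score and fitting a mixed-model repeated
measures (MMRM) analysis to it.  An item response model (IRM) instead
keeps every item response: a graded response model links each item to a
single latent disease severity $\psi_i(t)$,

$$P(y_{ij} \ge k) = \mathrm{logit}^{-1}\!\big(a_j(\psi_i - b_{j,k})\big),$$

the latent severity follows a longitudinal model (the headline form is a
step function, $\psi_i(t) = \psi_{0i} + R_{\max,i}\,\mathbb{1}\{t > T_{R,i}\}$,
with arm-specific $R_{\max}$ and $T_R$), and a continuous-time Markov
layer with a mean equilibrium time MET$(t)$ captures the day-to-day
correlation of responses.  Because the IRM uses the full item-level
information, its estimate of the end-of-trial arm difference is much more
precise, which translates directly into better go/stop decision operating
characteristics.

The package implements the whole chain for this comparison:

* **scales** — instrument structure, RS-Total/subscale/EXACT-Total
  scoring, long-format diary CSV reader/writer (`exact_items`,
  `rs_total`, `score_diary`, `read_diary_csv`, `default_score_map`);
* **model core** — ICFs, five latent-trajectory forms, Markov transition
  kernel, item-level forward simulation (`category_probabilities`,
  `trajectory_value`, `transition_matrix`, `simulate_trial`);
* **estimation** — two-step maximum likelihood: step 1 fits the ICFs
  treating every subject-day as an independent pseudo-subject
  (Gauss-Hermite quadrature, analytic gradients); step 2 fits the
  longitudinal + Markov model with ICFs fixed (per-subject Laplace
  approximation in compiled code, Gauss-Hermite integration of the
  step-time effect); LRT/AIC model comparison (`fit_icfs`,
  `fit_longitudinal`, `compare_models`);
* **diagnostics** — visual predictive checks at total-score, item and
  transition level, non-parametric ICF smooth checks (`vpc_total_score`,
  `vpc_items`, `vpc_transitions`, `icf_smooth_check`);
* **trial simulation** — parameter-uncertainty propagation (normal fixed
  effects, inverse-Wishart variances with SE-matched degrees of freedom)
  into the distribution of end-of-trial arm differences
  (`uncertainty_spec`, `simulate_endpoint_distribution`);
* **decision layer** — sample-size ratio, go/stop probability tables
  under a 80/20 mixture prior, PPV/NPV, power curves, ROC/AUC — each
  Monte-Carlo procedure paired with a closed-form oracle
  (`sample_size_ratio`, `decision_table_analytic`, `decision_table_mc`,
  `power_curve`, `roc_and_auc`);
* **synthetic data** — a ground-truth trial generator emulating the
  motivating study (93 subjects, 365 days, ~19% drop-out), used by the
  whole test suite (`generate_trial`, `make_fixture`);
* **pipeline / CLI** — a JSON-configured pipeline and an `Rscript` entry
  point (`run_pipeline`, `inst/cli/irmpro.R`).

## Worked example

The decision layer reproduces the published comparison from printed
summaries alone.  The MMRM 95% CI for the E-RS:COPD arm difference was
(-4.77, 2.04); the IRM interval was (-3.16, 0.48):

```r
library(irmpro)
w_mmrm <- ci_width(-4.77, 2.04)   # 6.81
w_irm  <- ci_width(-3.16, 0.48)   # 3.64
round(sample_size_ratio(w_mmrm, w_irm), 1)
#> [1] 3.5
```

so the summary-score analysis needs a 3.5-fold larger trial to match the
item-based precision.  Decision table for the MMRM on the EXACT scale
(decision SD 2.70, target value -2, mixture prior with an 80% point mass
at no effect):

```r
decision_table_analytic(decision_inputs(tv = -2, sigma_delta = 2.70))
#> decision_table (analytic): TV = -2, sigma = 2.7
#>             stop    go
#> true > TV  0.678 0.222
#> true <= TV 0.039 0.061
#> P(Go) = 0.284, P(Stop) = 0.716, PPV = 0.216, NPV = 0.946
```

A go decision is right only 22% of the time.  The same table with the
IRM's E-RS precision (SD back-derived from its CI):

```r
decision_table_analytic(decision_inputs(tv = -2,
                                        sigma_delta = sd_from_ci(-3.16, 0.48)))
#> decision_table (analytic): TV = -2, sigma = 0.928588
#>             stop    go
#> true > TV  0.864 0.036
#> true <= TV 0.024 0.076
#> P(Go) = 0.113, P(Stop) = 0.887, PPV = 0.677, NPV = 0.973
```

PPV rises from 0.22 to 0.68 purely through precision.  Go probabilities
at a strong true effect of -5 points:

```r
round(100 * p_go(-5, 2.70, -2))   # 87  (EXACT-scale MMRM)
round(100 * p_go(-5, 1.74, -2))   # 96  (E-RS-scale MMRM)
```

A full synthetic trial with the default (study-emulating) configuration:

```r
g <- generate_trial(trial_config(seed = 1))
g$data
#> diary_dataset: 93 subjects (45 drug / 48 placebo), 31089 present days
sc <- score_diary(g$data)
round(tapply(sc$rs_total[sc$day == 0], sc$arm[sc$day == 0], mean), 1)
#>    drug placebo
#>    12.4    10.7
```

matching the observed baseline RS-Total of about 11.  From here,
`fit_icfs()` + `fit_longitudinal()` recover the generating parameters
(see `tests/testthat/test-acceptance.R` for the full recovery run), and
`uncertainty_spec()` + `simulate_endpoint_distribution()` +
`decision_inputs()` turn a fit into the decision tables above.

## Documentation

The methods vignette (`vignettes/item-based-diary-analysis.Rmd`) explains
the model, the two-step estimator and its numerics, the synthetic world,
and every design decision taken where the source was silent.
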