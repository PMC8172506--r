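---
title: "Item-based analysis of daily symptom diaries: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Item-based analysis of daily symptom diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`irmpro` implements an item-based pharmacometric analysis of daily
patient-reported COPD symptom diaries (the 14-item EXACT instrument and its
11-item E-RS:COPD subset), and the decision-confidence layer used to compare
this item response model (IRM) analysis against the conventional
summary-score mixed-model (MMRM) analysis.  This vignette is the package's
own account of the science: the model and its assumptions, the parameters
that matter, what the synthetic-data generator does and does not emulate,
the numerical choices, and the design decisions taken where the design was
genuinely open.

## The probabilistic model

**Item characteristic functions (ICFs).**  Each of the 14 items is an
ordinal response (nine items scored 0-4, five scored 0-3) driven by a
single latent disease status $\psi_i(t)$ through a graded response model:

$$P(y_{ij} \ge k) = \frac{e^{a_j(\psi_i - b_{j,k})}}{1 + e^{a_j(\psi_i - b_{j,k})}},
\qquad P(y_{ij} = k) = P(y_{ij} \ge k) - P(y_{ij} \ge k+1),$$

with discrimination $a_j > 0$ and strictly ordered difficulties
$b_{j,1} < \dots < b_{j,K_j}$.  Higher $\psi$ means more severe symptoms, so
a beneficial drug effect is *negative* on the latent scale and produces
*negative* score differences (drug minus placebo).  This orientation is
used consistently throughout the decision layer.

**Latent trajectories.**  The population time course of $\psi_i(t)$ can be
linear, power, asymptotic, Weibull or a step function; the step function —
baseline level $\psi_{0i}$ jumping to $\psi_{0i} + R_{\max,i}$ strictly
after a response time $T_{R,i}$ — is the headline model, with arm-specific
fixed effects for everything except the baseline mean (fixed at 0; baseline
heterogeneity is carried by the $N(0,1)$-anchored $\psi_0$ variability).
$R_{\max}$ and slope-type parameters carry additive normal inter-individual
variability; $T_R$, $T_{\mathrm{PROG}}$ and MET are lognormal (exponential
IIV).

**Day-to-day correlation (Markov layer).**  Responses on consecutive days
are not conditionally independent: an item re-equilibrates to its marginal
ICF distribution on a time scale MET (mean equilibrium time), which grows
linearly with study day, $\mathrm{MET}(t) = \mathrm{MET}_0 + s \cdot t$,
with lognormal subject-level variability.  The default transition kernel
over a gap $\Delta t$ shrinks the identity toward the stationary ICF
distribution $\pi(\psi)$:

$$P(\Delta t) = e \cdot I + (1 - e) \cdot \mathbf{1}\pi', \qquad
e = \exp(-\Delta t / \mathrm{MET}).$$

This satisfies every contract the analysis relies on: first-order
dependence, stationary distribution equal to the marginal ICF
probabilities, identity as $\Delta t \to 0$, full equilibration as
$\Delta t \to \infty$, Chapman-Kolmogorov within a constant-MET window, and
a deviation-from-stationarity half-time of $\mathrm{MET}\cdot\ln 2$ (MET is
the *mean* of the exponential re-equilibration time).  The construction is
kept behind the `transition_matrix()` interface so an intensity-matrix
variant (e.g. an adjacent-state chain in detailed balance with $\pi$) could
be swapped in; such a variant would share all stationary properties but
differ in transient behaviour between non-adjacent states.  MET's linear time-dependency is applied to MET itself (not log-MET), evaluated at the
current day, piecewise-constant between observations — the simplest reading
consistent with positivity over the study horizon.

## Two-step estimation

**Step 1 (ICFs, independent occasions).**  Every present subject-day
becomes an independent pseudo-subject.  Baseline (day 0) occasions get a
fixed $N(0,1)$ latent distribution — this anchors the scale and makes the
item parameters identifiable — and all later occasions share one estimated
$N(\mu, \omega^2)$.  (Whether the original analysis used one distribution
per later occasion or a shared one is ambiguous; we chose *shared* and flag
it here.)  The marginal likelihood integrates the latent variable by
Gauss-Hermite quadrature on the occasion distribution (61 nodes by
default); the optimiser is BFGS with *analytic* gradients on a transformed
scale (log discriminations, first difficulty plus log-gaps, log variance),
up to a handful of jittered restarts.  Standard errors come from the
observed-information Hessian (finite differences of the analytic gradient)
with a delta-method return to the natural scale.  A category that never
occurs in the data is collapsed into its lower neighbour (reported in the
fit's `collapsed` diagnostics) so the remaining thresholds stay ordered and
identified.  The quadrature-adequacy convention is that doubling the node
count moves the objective by less than 0.01.

**Step 2 (longitudinal model, ICFs fixed).**  With item parameters fixed
from step 1, the subject-level likelihood multiplies the marginal ICF
probability of each subject's first present day with transition
probabilities across the subsequent gaps (missing days simply widen
$\Delta t$; whole-day missingness is treated as ignorable, and no drop-out
model is fitted).  Subject random effects are integrated out by a
per-subject Laplace approximation, computed in compiled code with analytic
gradients and Hessians for the trajectories that are linear in their smooth
effects (linear, power, step).  One subtlety dictated the numerics: with
daily sampling the step model's likelihood is *piecewise constant* in the
response-time effect $\eta_{T_R}$ (only the pre/post split of observed days
matters), so a Laplace approximation in that dimension is undefined.  That
dimension is therefore integrated by Gauss-Hermite quadrature on its
lognormal prior (9 nodes by default) with the Laplace approximation applied
to the remaining smooth effects.  The inner Newton iterations run to a
start-independent tolerance so the objective is a deterministic, smooth
function of the fixed effects; the outer BFGS then uses finite-difference
gradients (step $10^{-4}$ on the transformed scale).  Standard errors again
come from a numeric Hessian of the objective.

**Model discrimination.**  Nested models are compared by the likelihood
ratio test on the change in the -2 log-likelihood objective (5% level for
adopting the more complex model); non-nested models by AIC = OFV +
2 · n_params.  Simulation-based checks (`vpc_total_score()`, `vpc_items()`,
`vpc_transitions()`, `icf_smooth_check()`) always re-simulate under the
*observed* design — same subjects, arms and present days — so the bands
answer "could this model have produced these data" rather than "some data".
Binning is equal-count (14 bins by default, configurable); the ICF smooth
uses a Gaussian kernel with Silverman's bandwidth.  Because occasion-level
latent values are posterior means — shrunken towards the prior — the
observed smooth is *systematically steeper* than the pure expected-score
curve $E[y\,|\,\psi]$; the agreement check therefore compares the observed
smooth against the same smooth computed on model-simulated
pseudo-occasions (shrinkage affects both sides identically), with the pure
curve returned for display only.  The 0.15-score-unit agreement threshold
used in the smooth-check test is a package convention (the original
graphical criterion has no stated tolerance).

## Uncertainty propagation and the decision layer

`uncertainty_spec()` + `simulate_endpoint_distribution()` propagate
estimation uncertainty into the end-of-trial endpoint: fixed effects are
drawn multivariate-normal from the asymptotic covariance; each scalar
random-effect variance is drawn scaled-inverse-chi-square — the scalar case
of the inverse-Wishart — with degrees of freedom matched to its standard
error by $\mathrm{df} = 2(\omega^2/\mathrm{SE})^2 + 1$.  Per replicate
(defaults: 2000 replicates, 5000 subjects/arm; tests run scaled-down
versions and say so) a large two-arm virtual trial is simulated over the
evaluation window and the arm difference in mean score recorded, per scale.
"Month 12" is implemented as the mean over days 351-365 — the published
analysis reports month-12 scores without stating a window, and a window
stabilises daily noise;
it is configurable.  The replicate SD is the decision SD $\sigma_\Delta$;
the 2.5th-97.5th percentile range is the 95% CI.  Item parameters enter at
their point estimates (they are fixed quantities in step 2, where the
propagated covariance lives).

The decision layer is deliberately closed-form wherever the original
procedure was Monte Carlo, with the MC versions kept as separate code paths
so each can check the other:

* the true effect prior is a mixture — probability 0.8 of no effect (point
  mass at 0), 0.2 of an effective compound with effect
  $N(\mathrm{TV}, 1)$ — reflecting phase-II success rates;
* go is declared when the *estimated* difference is at or below the target
  value TV (inclusive); TV defaults: -2 for EXACT and
  E-RS:COPD, -1 for breathlessness, -0.7 for the two remaining subscales;
* one sign convention required a decision: the printed power function
  $1 - \Phi((\mathrm{TV}-\Delta)/\sigma_\Delta)$ contradicts the worked
  go-probabilities when benefit is negative; the implementation uses
  $P(\mathrm{Go}) = \Phi((\mathrm{TV}-\Delta)/\sigma_\Delta)$, which
  reproduces them exactly.  Numbers beat notation;
* PPV = P(correct go)/P(go), NPV = P(correct stop)/P(stop); the analytic
  table integrates the go probability over each mixture component with
  adaptive quadrature rather than bivariate-normal tables, avoiding an
  extra dependency;
* ROC/AUC treats each arm's endpoint as normal with its mean and SE,
  positive class = drug arm (lower scores), thresholds swept over the
  pooled support, empirical AUC by rank statistic with a 2000-resample
  percentile bootstrap CI, and the closed form
  $\Phi(|\mu_d - \mu_p| / \sqrt{SE_d^2 + SE_p^2})$ reported alongside.

The published 80%-power thresholds differ from the closed form
$\mathrm{TV} - \sigma\,\Phi^{-1}(0.8)$ by about 1% (their grid/simulation
resolution is not recoverable), so those numbers are treated as soft
cross-checks, not targets.

## The synthetic world

No raw diaries from the motivating trial are deposited, so
`generate_trial()` builds ground-truth trials with the structure the
analysis assumes, and the estimation/diagnostic/decision stages are tested
against that known truth.  The default configuration *is* the stated world
of the emulated study: 45 drug / 48 placebo subjects, days 0-365, step
trajectories with typical $R_{\max}$/$T_R$ of -0.16/54.8 d (drug) and
0.18/51.1 d (placebo), MET rising from 1.23 d to 3.09 d over the study,
~19% drop-out (uniform stop day between days 30 and 350 — the observed
median stop day was earlier, but drop-out is purely descriptive here) and a
2.5% whole-day missingness rate (completers had a median of ~9 missing
days).  Magnitudes the emulated study does not report were chosen once, as
plausible for this population, and not revisited: IIV variances of 1
($\psi_0$; fixed by the step-1 anchor), 0.05 ($R_{\max}$, additive), 0.1
($T_R$ and MET, log scale).  The item bank pins the three non-respiratory
discriminations to their reported values (1.24, 0.56, 1.05) and draws the
rest in [0.5, 2]; difficulty placement (first threshold uniform on
[-0.5, 0.3], ordered gaps of 0.8-1.3) was calibrated so the baseline
RS-Total mean lands near the observed ~11, which is the binding constraint
on the bank.

What a green test establishes, therefore, is that the pipeline recovers
the truth of *this* world — item parameters, arm effects, Markov time
scale — and that the decision layer reproduces the published operating
characteristics from printed summary inputs.  What it cannot establish:
agreement with the undeposited trial data, the official (proprietary)
EXACT sum-to-0-100 scoring table — `default_score_map()` reproduces its
*structure* (monotone expected-a-posteriori transform anchored at 0 and
100) but not its absolute values, and a user-supplied official table is
accepted — or behaviour under informative drop-out, which is deliberately
out of scope.

## Known limitations

* The step-1 independent-occasion approach ignores the within-subject
  correlation of occasions by construction (as in the original analysis);
  its standard errors are honest only to the extent that correlation is
  weak or the information about item parameters is conditional on $\psi$.
  The parameter-recovery acceptance run checks this empirically in the
  default world.
* The exact intensity parameterisation of the original minimal
  continuous-time Markov construction is not recoverable from the
  published description;
  the shrinkage kernel matches every stated property but may differ in
  transient behaviour.
* Laplace approximations can bias variance components on small samples;
  no importance-sampling refinement is currently applied on top of the
  (quadrature + Laplace) integration.
* Configuration files are JSON rather than YAML (no YAML parser in the
  supported dependency set).
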