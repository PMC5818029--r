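---
title: "Methods: the CT and genetic diagnostic model for CAA-associated lobar ICH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CT and genetic diagnostic model for CAA-associated lobar ICH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caadx)
```

## The scientific problem

Lobar intracerebral haemorrhage (ICH) has two main small-vessel causes:
cerebral amyloid angiopathy (CAA) and arteriolosclerosis. Distinguishing
them matters — CAA-associated ICH recurs more often and changes
antithrombotic decisions — but the MRI-based Boston criteria cannot be
applied when MRI is contraindicated, intolerable or unavailable. This
package implements a diagnostic prediction model for moderate/severe CAA
among lobar ICH built from two non-contrast CT features — any
subarachnoid extension of the haemorrhage (SAH) and finger-like
projections from the haematoma (FLP) — plus *APOE* ε4 possession, along
with the derived rule-in and rule-out criteria.

The reference standard is neuropathological: parenchymal CAA scores from
the left hemisphere are summed to 0–12 and graded none (0), mild (1–4),
moderate (5–8), severe (9–12); `grade_caa_burden()` encodes this, and the
binary outcome is a burden of moderate or severe.

## The Firth model and why plain logistic regression fails here

FLP is observed only among moderate/severe-CAA cases: the predictor
completely separates one outcome group, so the ordinary maximum-likelihood
estimate of its coefficient is infinite. The model is therefore fitted by
Firth penalised likelihood,

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det\, X^\top W X, \qquad
  W = \mathrm{diag}\{\pi_i(1-\pi_i)\},$$

whose gradient is the modified score
$U^*_j(\beta) = \sum_i \{y_i - \pi_i + h_i(\tfrac12 - \pi_i)\}\, x_{ij}$,
with $h_i$ the hat diagonals of the weighted design. `fit_firth()` runs
Newton–Raphson on $U^*$ with step-halving whenever a step would decrease
$\ell^*$. For a saturated 2×2 design this penalty is exactly equivalent to
adding one half to each cell, so the univariable Firth odds ratio equals
the Haldane–Anscombe corrected cross-product ratio — a property the test
suite exploits as an independent check, alongside a coarse-to-fine
grid-search maximiser of $\ell^*$ that never touches the Newton path.

Numerical choices:

* convergence requires the modified score to vanish
  (`max|U*| < tol = 1e-8`) together with either a sub-tolerance step or a
  numerically stationary objective — the latter matters in near-separated
  2×2 designs where the curvature collapses and the step direction can
  oscillate at machine precision while the gradient is already ~1e-9;
* at most 50 iterations and 10 halvings per step (generous for p ≤ 4 at
  this scale); the accepted-step objective trace is retained and tested to
  be non-decreasing;
* standard errors come from the inverse penalised information at the
  optimum, which is what reproduces the published coefficient/SE pairs and
  Wald p-values (3.11/1.01 → 0.0021; 2.31/0.94 → 0.014), so Wald is the
  default p-value method and the penalised LR test (`plr_test()`) is the
  explicit alternative;
* confidence intervals default to profile penalised likelihood
  (`profile_ci()`) because the published intervals are far too asymmetric
  to be Wald (e.g. an OR interval of 4–862): each bound solves
  $2\{\ell^*(\hat\beta) - \max_{\beta:\beta_j=b}\ell^*(\beta)\} =
  \chi^2_1(0.95)$ by bracketed root-finding over BFGS inner profiles, and a
  side with no root before $|b| = 15$ on the log-odds scale is flagged
  "not reached" rather than given a number;
* the AIC is computed as $-2\ell + 2p$ with the *unpenalised*
  log-likelihood at the Firth estimates. The original analysis does not
  state its convention; this one reproduces the published full-model AIC
  (49.9) on the fixture, and both log-likelihoods are carried in the fit
  object so either convention can be formed.

## Performance and internal validation

`performance_metrics()` reports Nagelkerke R² (null log-likelihood at the
observed prevalence), Brier score, AIC, c statistic (midrank-based, equal
to the trapezoidal ROC area to machine precision), discrimination slope,
and the Hosmer–Lemeshow test. With three binary predictors the model emits
at most 8 distinct probabilities (6 observed in the fixture), so
Hosmer–Lemeshow groups by distinct predicted value when there are at most
10, falling back to deciles of risk otherwise; the statistic is
$\sum_g (O_g - E_g)^2 / \{E_g(1 - E_g/n_g)\}$ with $g - 2$ degrees of
freedom.

`bootstrap_validate()` implements Harrell's optimism correction: simple
unstratified resampling with replacement at full n (the original analysis
states no stratification), refit on each resample, evaluate each refit on
its own resample and on the original cohort, optimism = mean difference,
corrected = apparent − optimism. Firth penalisation is what makes this
workable at B = 2000 on n = 62 — resamples that aggravate the separation
remain estimable. Replicates that still fail are counted and excluded; a
failure rate above 5% is an error rather than a silent omission.

## Risk categories, criteria, and decision curves

Risk categories are defined by predictor *patterns*, not numeric cutoffs:
low = neither SAH nor ε4, high = SAH plus at least one other predictor,
medium otherwise. With the published coefficients these correspond to the
labelled probability bands ≤7%, 44–64% and ≥95%, which
`enumerate_profiles()` computes rather than hard-codes. Two patterns sit
awkwardly in this scheme and are deliberately left as the pattern rule
dictates: ε4 + FLP without SAH predicts 0.98 yet is "medium" (it fails the
high clause), and FLP alone predicts 0.66 yet falls in the low/ruled-out
group. Neither pattern occurs in the derivation data — FLP appeared only
alongside CAA-positive lobar ICH — so the printed band boundaries describe
the observed patterns only, and the package documents rather than resolves
the tension.

The rule-out criteria (absence of SAH and ε4) and rule-in criteria (SAH
with ε4 or FLP) are evaluated with `accuracy_stats()`: continuity-corrected
Wilson intervals for proportions and log-method intervals for likelihood
ratios. The Wilson-with-continuity-correction choice is deliberate: it is
the interval that reproduces the published bounds (88 for 36/36, 78 for
25/26, 73 for 32/36, 84 for 26/26), where exact Clopper–Pearson would give
90 for 36/36. Likewise, association tests use Pearson χ² *without* Yates
correction, switching to Fisher's exact test (two-sided,
point-probability) when any expected count is below 5 — the combination
that reproduces the published univariable p-values (0.0004, 0.0003, 0.077,
0.17, 1.00, 0.027). Zero-cell odds ratios are governed by a policy switch
(`haldane` adds ½ to every cell; `na` returns a not-available marker)
because the published table itself applies both conventions to different
rows; the default is `haldane`.

`decision_curve()` computes net benefit
$NB(p_t) = TP/n - (FP/n)\, p_t/(1-p_t)$ over a 0.01–0.99 grid (step 0.01)
against treat-all and treat-none references; on the fixture the model
dominates both references throughout the 0.25–0.80 threshold band
containing the rule-in/rule-out cutoffs.

## The fixture cohort and the simulator

The individual-level derivation dataset is deposited by its authors but
has no stable accession, so the package ships a **synthetic
reconstruction**, `fixture_cohort()`: 62 lobar ICH participants (36
moderate/severe CAA, 26 absent/mild) whose per-group predictor margins
(SAH 11/26 and 32/36; ε4 2/26 and 18/36; FLP 0/26 and 14/36) match the
published table exactly. The joint cells are pinned by the published
accuracy statistics: 100% rule-out sensitivity forces all four non-SAH
cases to carry ε4; 96% specificity forces exactly one control with
SAH∧ε4; LR+ 16.6 forces 23 rule-in positives among cases, hence 9 FLP
cases in SAH∧¬ε4 cells. The one remaining degree of freedom — the 9 vs 5
split of FLP across ε4 strata among cases — is an assumption and is
flagged as such in the function documentation. Covariates (age, sex,
volume, ε2, anticoagulant use, strictly lobar location, burden sums) are
deterministic fillers matching the published group counts and medians
where printed; they are labelled synthetic and should not be mined for
individual-level structure.

On this fixture the fitted model lands on the published coefficients and
SEs to 2 d.p., AIC 49.9, apparent c 0.92 and corrected 0.91, Brier 0.11 →
0.12. That is a satisfying consistency check, but the published apparent
performance values depend on the unpublished joint covariate distribution,
so they are treated as descriptive, not as assertions.

`simulate_cohort()` generates cohorts under either a conditional design
(fixed group sizes, per-group multinomial pattern probabilities — what a
case-control re-analysis assumes) or a logistic design (pattern
distribution plus a coefficient vector — the model's own data-generating
process). Defaults used in tests mirror the study conditions: the
published coefficient vector (−2.55, 3.11, 2.31, 3.20) and, where a joint
pattern law is needed without published information, a uniform pattern
distribution. Parameter-recovery tests (n = 5000, 200 replicates, mean
absolute bias < 0.1 per coefficient) and goodness-of-fit tests of the
pattern law (n = 10⁵, 20 seeds, α = 0.001) run at sizes chosen to make
sampling noise negligible while keeping the default suite under a minute
for these components. Randomness flows through R's own generator from a
single integer seed recorded in the cohort's provenance.

What the simulator does *not* emulate: covariate correlation with
predictors, rater disagreement on CT features, secular drift of CT signs
with time from onset, and the selection pressures of an autopsy cohort
(older, larger haemorrhages, earlier death). Passing tests on simulated
and fixture data therefore demonstrate the statistical machinery and the
published-number arithmetic, not transportability of the criteria to new
populations — which is exactly the external-validation gap the original
analysis flags.

## Limitations

* The fixture is a constrained reconstruction, not the deposited dataset;
  quantities not pinned by published statistics (e.g. the exact VIFs, the
  Hosmer–Lemeshow p) will differ from the original analysis.
* Only binary-logit models are supported; no ordinal or survival
  endpoints.
* Agreement statistics (`cohen_kappa()`, `icc()`) use large-sample
  standard errors; the ICC form is two-way single-measure absolute
  agreement, tagged in the output because the original analysis does not
  state its variant.
* The model-χ² and AIC conventions (penalised vs unpenalised
  log-likelihood) are both available because the original report does not
  specify them; outputs are labelled.
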