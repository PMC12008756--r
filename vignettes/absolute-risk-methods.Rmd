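---
title: "Methods: combined breast-cancer absolute-risk estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined breast-cancer absolute-risk estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrisk)
```

## The problem

Breast cancer in sub-Saharan Africa is typically diagnosed at an advanced
stage, and no population-wide screening programme exists. Risk-stratified
screening needs a risk model built for the population it serves: risk-factor
distributions, allele frequencies, pathogenic-variant (PV) carrier rates and
incidence rates in West African women all differ from the European-ancestry
populations in which most comprehensive models (e.g. BOADICEA or the Gail
model) were developed.

`bcrisk` implements the full analysis pipeline for a combined model of this
kind: a relative-risk model assembled from questionnaire-based epidemiologic
factors, a polygenic risk score (PRS), and PV carrier status in nine high- or
moderate-penetrance genes (*BRCA1, BRCA2, PALB2, ATM, CHEK2, BARD1, RAD51C,
RAD51D, TP53*); absolute-risk projection to age 80 under competing mortality;
and discrimination/reclassification evaluation. Coefficients, PRS weights
and rate tables are consumed as inputs — the package never fits them.

## The relative-risk model

For woman $i$ the log relative risk is a linear predictor
$LP_i = \mathbf{x}_i^\top \boldsymbol\beta$ over encoded covariates:

* age at menarche (per year) and breastfeeding (per month), continuous,
  centered at configurable reference values (defaults 15 years, 0 months);
* parity as a linear spline with a knot at one child: an indicator of any
  live birth plus $\max(\text{parity} - 1, 0)$;
* height per 10 cm centered at 160 cm;
* BMI in four bands ($<18.5$, $18.5$–$24.9$ reference, $25$–$29.9$,
  $\ge 30$), categorized *after* imputation of the continuous value;
* benign breast disease, family history, alcohol intake as binaries;
* the PRS as a single continuous covariate with its own log-OR (1 by
  default, since the score is already a sum of per-allele log-ORs);
* one binary carrier term per PV gene.

$LP = 0$ defines the reference woman, so $e^{LP}$ is the relative risk
versus that reference. Four nested variants are supported: `epi_only`,
`prs_only`, `prs_plus_pv` and `combined`.

Mean imputation is by case/control status: each missing epidemiologic value
takes the mean of observed values in the same status group; binary fields
take the group proportion as a fractional value (the predictor is linear, so
fractional binaries integrate exactly to the group mean contribution);
missing PV carrier flags are recoded to non-carrier, since carrying a PV is
far rarer than not. Categorizing BMI after imputing the continuous value is
the only order in which "mean imputation" is well defined for a categorical
model term.

## Family-history attenuation

Family history and the modeled variants partly encode the same heritability:
a woman's relatives share half her polygenic load, so a model that includes
both the variants and a family-history indicator double-counts. The
family-history log-OR is therefore attenuated by the familial component of
the modeled variants:

$$\beta^A_{FH} = \max\Bigl(0,\;\beta_{FH} - \sum_k f_k(1-f_k)\beta_k^2\Bigr),$$

summing over the SNVs and PVs active in the variant. Under Hardy–Weinberg
equilibrium, $2f_k(1-f_k)\beta_k^2$ is the genotypic variance of variant
$k$'s log-risk contribution; a first-degree relative inherits half of it
(kinship $1/2$), and a second-order expansion of the exact
genotype-pair odds ratio shows that $f_k(1-f_k)\beta_k^2$ is precisely the
family-history log-OR induced by that variant in the rare-disease limit.
The rule is therefore an approximation valid for per-variant effects of the
size that occurs in practice ($|\beta_k| \ll 1$ for PRS SNVs; PV terms are
large per carrier but contribute $f_k(1-f_k)\beta_k^2 < 0.01$ at realistic
allele frequencies). Its truncation error grows as
$\beta^3 f(1-f)(1-2f)$, which is why the simulation-based agreement test in
the package compares formula and Mendelian genotype-pair simulation at
sample sizes whose Monte-Carlo resolution matches that regime, while the
closed form itself is pinned exactly in unit tests.

When the PRS enters as a precomputed score with no per-SNV weight table,
its attenuation contribution uses the aggregate identity
$\sum_k f_k(1-f_k)\beta_k^2 = \tfrac12\operatorname{Var}(PRS)\,\beta_{PRS}^2$,
with the PRS variance supplied in the coefficient set (default: the
control-group variance of the synthetic defaults).

The adjustment always restarts from the stored unadjusted $\beta_{FH}$, so
it is idempotent and order-independent across variants, and it is floored
at zero (a negative family-history coefficient would claim that modeled
variants more than exhaust the observed familial association).

## Absolute risk under competing mortality

The baseline hazard is calibrated non-iteratively against a reference
sample of controls, which supplies the population's risk-factor
distribution:
$$\lambda_0(t) = \frac{\lambda_{pop}(t)}{\overline{e^{LP}}},$$
so that the reference-mean model hazard reproduces the population incidence
at every age — the testable contract
$\mathrm{mean}_i\,\lambda_0(t)e^{LP_i} = \lambda_{pop}(t)$. An
age-attrition-weighted refinement (as in iCARE) is deliberately not used:
the reference here is a single cross-sectional control set with no
age-varying composition to exploit.

Projection uses an annual discrete recursion with cause allocation. With
$\lambda(t) = \lambda_0(t)e^{LP}$, competing mortality $m(t)$ and total
hazard $h(t) = \lambda(t) + m(t)$:

$$\text{risk}(a, b) = \sum_{t=a}^{b-1} S(t)\,\frac{\lambda(t)}{h(t)}
  \bigl(1 - e^{-h(t)}\bigr), \qquad S(t+1) = S(t)\,e^{-h(t)},\; S(a) = 1.$$

This is the standard discrete-time competing-risk decomposition, exact when
hazards are piecewise constant within years. Rate tables are supplied per
100 000 person-years over half-open age bands tiling $[18, 80)$ and
expanded piecewise-constant to single years. Projection runs from each
woman's enrollment age to 80 by default (a fixed common start age is a
model option); "lifetime risk" for an enrollee therefore means her
remaining risk, which is the clinically actionable quantity and the one a
case-control comparison can use without assuming counterfactual younger
ages. Enrollment ages at or above 80 are outside the rate coverage and are
clamped to 79 at prediction time.

## Evaluation

*Discrimination.* The AUROC is the Mann–Whitney pair statistic (ties count
one half) with a DeLong variance for the confidence interval. Because cases
are systematically older than controls and age correlates with several
covariates, an age-adjusted AUROC is also computed: scores are stratified
into age bins (default 10 years), each case's placement value is the
proportion of same-stratum controls scoring above her, and the adjusted
AUROC is one minus the mean placement value. This nonparametric stratified
estimator was chosen over parametric ROC regression because it is
distribution-free, invariant under monotone score transforms, and testable
by enumeration; its confidence interval is a seeded stratified bootstrap
(default 1000 replicates). Strata lacking cases or controls are dropped
with a warning. Adjusted values are therefore comparable to, but not
bit-identical with, parametric ROC-regression output.

*Reclassification.* Risk categories use half-open threshold bins (defaults
3/5/10% for stratification tables, 3/10% for reclassification). The
categorical net reclassification index is
$(up_{case} - down_{case})/n_{case} - (up_{ctrl} - down_{ctrl})/n_{ctrl}$
over the per-status cross-tabulations. Percentages are rounded half away
from zero to one decimal, and only at the reporting layer.

## The synthetic cohort generator

No public individual-level dataset of this kind exists, so the package
ships a generator with two modes.

*Marginal mode* draws each covariate independently within status from
distributions matching published-style marginal summaries of a
West-African case-control study (≈1000 cases, ≈700 controls): e.g. control
age 41.5 (SD 13.8) vs case age 49.5 (12.2); breastfeeding 67.0 (54.3) vs
54.3 (39.4) months; control PRS mean 0.182 (SD 0.314) vs case 0.268
(0.317); control family-history prevalence 2.0% vs 3.6%. Continuous fields
use truncated normals whose location is moment-matched so the truncated
mean equals the configured mean (naive truncation would inflate heavily
censored fields such as breastfeeding by several months); realized SDs
shrink slightly under truncation. PV carriers are Bernoulli per gene and
status, with small nonzero control frequencies so generated data cannot
produce infinite odds ratios. Missingness is injected per field at
configurable rates; PV missingness applies to all nine genes jointly
(panel-sequenced or not) and may differ by status, mimicking differential
sequencing coverage. Because only marginals are emulated — no
correlation structure between covariates, and case status is *assigned*,
not generated — marginal mode validates plumbing and imputation, not
inference.

*Generative mode* provides ground truth the study data cannot: covariates
are drawn once from the control (population) distributions, a true
coefficient set determines each woman's $LP$, the baseline is calibrated to
the supplied rates against that population, and each life course is
simulated year by year; women diagnosed before their enrollment age become
cases (enrolled at diagnosis), disease-free survivors become controls,
deaths are discarded. Case-control differences in PRS, PVs and covariates
then emerge solely through selection on $e^{LP}$, the true linear
predictors are recorded, and parameter-recovery tests can check that the
pipeline's combined model out-discriminates the epidemiologic model
whenever the true genetic effects are nonzero, and that the empirical
AUROC of the true $LP$ matches the binormal identity
$\Phi(\delta/\sqrt{\sigma_1^2+\sigma_0^2})$.

The default rate table is a smooth unimodal incidence curve over 5-year
bands peaking at 64.6 per 100 000 (the upper range reported for Nigeria)
at age 50 with a 15-year Gaussian width, and Gompertz-style competing
mortality (50 per 100 000 at age 18, growing 5.5%/year). These are
synthetic stand-ins for registry rates, labeled as such, as are the default
coefficients (`default_coefficients()`): epidemiologically plausible in
sign and magnitude but not estimates from any published model.

## Numerical and design choices

* **Determinism.** Every stochastic routine requires an explicit seed;
  the pipeline writes a manifest (seed, path-independent config hash,
  package version) sufficient to reproduce a run byte for byte.
* **Problem sizes.** Tests exercise the generators at $10^4$ draws for
  marginal moments, $10^5$ replicates for Monte-Carlo projector checks,
  and ten generative cohorts of 5000 for parameter recovery — sizes at
  which 3-standard-error bands are tight enough to be informative while a
  full run of the suite stays near a minute.
* **Degenerate inputs.** Zero total hazard contributes zero risk (the
  $\lambda/h$ factor is defined as 0 when $h=0$); empty reference samples,
  unsorted thresholds, gapped rate tables, out-of-range dosages and
  missing coefficient terms raise immediate, named errors rather than
  propagating.
* **Ties.** All rank-based quantities use the midrank/one-half convention
  consistently.
* **Subtype proportions.** The hybrid PRS weight for ER-positive disease
  is a parameter of `combine_hybrid_prs()` with no default baked into the
  model, since the appropriate proportion is population-specific.
* **Allele vs carrier frequency.** PV terms enter the attenuation sum with
  their risk-allele frequency, applying the per-variant Hardy–Weinberg
  formula uniformly; at realistic frequencies the numerical difference
  from a carrier-frequency convention is far below every other
  uncertainty in the model.

## Limitations

Passing tests on generator output demonstrates internal consistency of the
pipeline, not fidelity to any real cohort: marginal mode has no covariate
correlation and generative mode inherits whatever the true coefficient set
assumes. Coefficients shipped with the package are synthetic. The
non-iterative calibration assumes the control sample represents the
population risk-factor distribution at every age; the stratified
age-adjusted AUROC is an estimator choice, not a reimplementation of any
particular ROC-regression software; and linkage disequilibrium, pedigree
structure and subtype-specific disease modelling are out of scope.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(
  generator = list(n_cases = 996, n_controls = 690, mode = "generative"),
  seed = 1, out_dir = "out"))
res$evaluation$combined$auroc_unadjusted
res$reclassification$nri
```
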