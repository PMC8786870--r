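---
title: "Methods: unweighted genetic risk scores and the GRS-by-BMI interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unweighted genetic risk scores and the GRS-by-BMI interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsbmi)
```

## The problem

Depression and obesity co-occur far more often than chance predicts, and a
share of the genetic susceptibility to depression appears to overlap with
body-mass regulation. `grsbmi` implements a complete case-control analysis
built around that observation: a panel of candidate depression SNPs is
quality-controlled, reduced to the markers whose in-sample effect direction
agrees with the literature, summed into an *unweighted* genetic risk score
(GRS), and entered into a ladder of logistic risk models in which BMI acts
first as a covariate and finally as an interaction partner of the GRS. The
package targets the cohort structure of a multicentre primary-care study:
roughly 1650 adults recruited in 7 provinces, about 104 depression cases
(6.3% prevalence), and a candidate panel of 30–56 biallelic SNPs with
MAF ≥ 0.05.

## The score

For subject $i$ with risk-oriented dosages $g_{ij} \in \{0,1,2\}$ over the
selected panel $S$,

$$\mathrm{GRS}_i = \sum_{j \in S} g_{ij},$$

i.e. every SNP contributes its risk-allele count with weight one. The
unweighted form is deliberate: most candidate markers come from individual
association studies without robust effect estimates, so weighting by
published betas would import noise. Protective-minor-allele SNPs are flipped
($g \mapsto 2-g$) before summing. The score is undefined for a subject
missing any selected genotype; such subjects are removed (complete-case
rule) and counted.

Selection into $S$ is by *concordance*: a per-SNP covariate-adjusted
logistic model is fitted, and a SNP is kept when the sign of its fitted
per-allele log-odds matches the literature direction — significance is not
required, because the point of the score is to pool small effects that are
individually indistinguishable from noise. Exactly-zero betas count as
discordant. Whether the screen uses adjusted or crude betas is not
standardised in the field; the scan is covariate-adjusted here
(sex, age, province) and the adjustment set is an argument, so the crude
variant is one call away.

## The model ladder

Five nested logistic models are fitted on the same complete-case sample:

| Model | Terms |
|---|---|
| 1 | sex + age + province |
| 2 | sex + age + province + BMI |
| 3 | sex + age + province + GRS |
| 4 | sex + age + province + GRS + BMI |
| 5 | sex + age + province + GRS × BMI (marginals + product) |

Province enters as unordered dummies with the first site as reference.
Model 5's `GRS*BMI` notation is read in the standard way: both marginal
terms plus the product. GRS and BMI enter in raw units by default; the
`center` flag of `interaction_model()` re-parameterises them at their
sample means, which leaves the product coefficient untouched and makes the
GRS main effect "per allele at mean BMI" — the scale on which per-allele
odds ratios are usually quoted. All inference is Wald
(estimate ± 1.96·SE); explained variation is reported as
$D^2 = 1 - \text{deviance}/\text{null deviance}$.

Model improvement is quantified four ways: AUC with DeLong confidence
intervals and the paired DeLong test; the integrated discrimination
improvement (IDI, the gain in discrimination slope); the categorical net
reclassification improvement (NRI) over the conventional low/medium/high
risk bands at 5% and 25% (boundaries belong to the upper band); and the
category-free NRI, which counts any directional change of predicted risk.
Since depression has no established clinical risk categories, the cfNRI and
IDI are the primary reclassification metrics and the categorical NRI is
reported for completeness. NRI/cfNRI/IDI standard errors are the standard
asymptotic (Pencina-type) forms; because the field does not agree on a CI
estimator for these metrics, a stratified percentile bootstrap is available
via `boot = TRUE`.

Beyond the in-sample evaluation (the primary mode — the models are meant to
be interpretable, trained and assessed on the whole sample), `kfold_cv()`
runs outcome-stratified 5-fold cross-validation: with ~104 cases the folds
must be stratified or a fold can end up with almost no events. Fold metrics
are combined by unweighted means, and the out-of-fold AUC is printed next
to the in-sample AUC so shrinkage is visible.

## Quality control

`run_qc()` applies, in order: exclusion of underweight subjects
(BMI ≤ 18.5 kg/m², before marker QC so call rates describe the analysis
sample); SNP call rate < 95% excluded (exactly 95% is retained); MAF < 0.05
excluded; the Hardy–Weinberg exact test *in controls only* at α = 0.05; and
greedy LD pruning of pairs with genotype R² > 0.8. The HWE test is the
exact conditional test: given the observed allele counts, the heterozygote
count is enumerated over all admissible values and the p-value sums the
probabilities of configurations no more probable than the observed one. It
is implemented with the log-scale heterozygote recurrence, and the test
suite checks it against full enumeration for every genotype triple with
total ≤ 50 to 10⁻¹². Whether HWE failures should be removed or only flagged
is genuinely ambiguous in practice; removal is the default and
`drop_hwe_failures = FALSE` switches to flag-only.

LD pruning needs a deterministic tie-break to be reproducible: of a pair in
excess of the R² ceiling, the member with the lower call rate is dropped,
ties resolved against the later column. A constant dosage column has
undefined R² and is reported as not prunable with a warning.

## The synthetic cohort

No individual-level data ship with the package; `simulate_study()`
generates cohorts with the statistical structure the analysis assumes, and
every pipeline stage is tested against it.

* **Genotypes** are drawn under Hardy–Weinberg proportions
  $((1-p)^2,\,2p(1-p),\,p^2)$ at each SNP's MAF. Default MAFs are
  Uniform(0.05, 0.35): at 30 SNPs this gives a GRS variance near 9, i.e. an
  SD near 3 alleles, matching the dispersion such candidate panels show in
  practice. LD blocks couple SNPs through a Gaussian copula whose latent
  correlation is calibrated numerically (bivariate-normal orthant
  probabilities inverted with `uniroot`) so the *genotype* correlation hits
  the requested target — naive use of the target as the latent correlation
  would undershoot after thresholding. This is deliberately not a model of
  human LD maps: no phasing, no recombination, no population structure.
* **Covariates**: sex Bernoulli(0.62 female), age truncated normal(50, 15)
  on [18, 75], site uniform over 7 provinces, BMI normal(27, 4) truncated
  at 15 kg/m² — a plausible adult primary-care profile; exact values are
  configurable and immaterial to the correctness tests.
  `underweight_rate` injects BMI ≤ 18.5 subjects to exercise the exclusion
  filter.
* **Outcome**: logistic, with mean-centred covariates. Each SNP carries a
  per-allele log-odds (default log 1.35, the per-allele odds ratio such
  scores exhibit per risk allele); the interaction term is
  $\gamma \,(\mathrm{GRS}-\mathbb{E}[\mathrm{GRS}])(\mathrm{BMI}-\overline{\mathrm{BMI}})$
  with $\gamma = \log 1.14$ per allele·kg/m² by default. Covariate effects
  for sex/age/province are free parameters (no published estimates exist
  for them); defaults are small. SNPs can be flagged *discordant*, flipping
  their true effect sign against the annotated literature direction, to
  exercise the concordance screen (a 56-SNP panel with discordant fraction
  26/56 reproduces a 56 → ~30 selection).
* **Prevalence targeting**: with centred covariates the intercept is
  approximately logit(prevalence), but the product term's dispersion
  (SD ≈ 1.6 on the log-odds scale at the defaults) inflates the realized
  case fraction if the intercept is left there. `simulate_study()` therefore
  calibrates the intercept by solving
  $\mathbb{E}[\mathrm{expit}(\beta_0 + \eta)] = \text{prevalence}$ with
  `uniroot` on the realized linear predictor, giving an expected case count
  of ~104 at n = 1650. `calibrate_intercept = FALSE` restores the plain
  logit(prevalence) intercept (exact under the global null, and the form the
  type-I-error tests rely on conceptually).

One consequence of a per-product-unit interaction of this magnitude is
worth stating plainly: even with a zero marginal BMI coefficient, the
interaction induces a *marginal* BMI–depression association (risk is convex
in the linear predictor, so strata with larger predictor variance have a
higher case rate). The simulated signal is therefore stronger than what the
emulated cohort reported — the emulation is structural and qualitative, not
a numerical replica. Passing tests demonstrate that the pipeline recovers
the parameters it simulates and holds its error rates, not that real
genotype data would show effects of this size.

## Determinism and numerics

Every stochastic function takes a `seed` and fixes its output bit-for-bit;
`simulate_study()` derives stage seeds from the master seed. Logistic fits
use `stats::glm` (IRLS); separation is detected from the fitted-probability
warning, missing coefficients, or runaway estimates, and surfaces as a flag
on the fit rather than silent output. Quartile assignment uses type-7
sample quantiles with values equal to a cut-point going to the lower
stratum; fully tied cut-points collapse every subject into Q1 with a
warning, and downstream quartile contrasts refuse to fit with an empty
stratum. The post-hoc power of the GRS model uses the Hsieh-style normal
approximation for a continuous predictor,
$\Phi(|\log\mathrm{OR}\cdot\sigma_x|\sqrt{n\,\bar p(1-\bar p)}-z_{1-\alpha/2})
+ \Phi(-|\log\mathrm{OR}\cdot\sigma_x|\sqrt{n\,\bar p(1-\bar p)}-z_{1-\alpha/2})$,
which returns the two-sided size α at OR = 1 and is monotone in both n and
|log OR|; at per-allele OR 1.35, GRS SD 2.97, prevalence 104/1650 and
n = 1650 it exceeds 99.99%.

## Problem sizes used in the test suite

Distributional checks on the generator use 10⁵ subjects; the
parameter-recovery study runs 500 replicates of the full n = 1650 design;
the interaction type-I-error calibration runs 2000 replicates; the
model-ladder pattern check runs 50 replicates of the whole pipeline. These
sizes keep Monte-Carlo error comfortably inside the asserted bands.

## Worked example

```{r example, eval = FALSE}
res <- run_all(list(seed = 1))
res                       # manifest counts, interaction OR, per-model AUC
res$quartile_model$contrasts
reclass_table(res$suite)  # NRI / cfNRI / IDI ladder
cv <- kfold_cv(res$data, k = 5, seed = 1)
```

## Known limitations

* The simulator's LD is block-exchangeable and copula-based; it cannot
  emulate realistic human haplotype structure, imputation dosages or
  population stratification.
* NRI/cfNRI/IDI p-values are asymptotic and anti-conservative in small
  strata; prefer the bootstrap CIs when case counts are low.
* The power approximation ignores covariate adjustment (a variance-inflation
  factor would generalise it) and assumes a normally distributed predictor.
* Strand harmonisation is out of scope: alleles are compared as given, and
  A/T, C/G SNPs are the caller's responsibility.
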