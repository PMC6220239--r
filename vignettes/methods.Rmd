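---
title: "Models and design choices in eduwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in eduwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eduwas)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters with their defaults
and units, what the synthetic-data generator does and does not emulate, and
the choices made where the design was genuinely open.

## The exposure: stratified ridit scores

Educational attainment is recorded on an ordinal 7-point scale (1 = primary
school only … 7 = university). Treating the raw category as numeric would
impose equal spacing, and schooling expanded dramatically across the 20th
century, differently for men and women, so the same category means something
different for a woman born in 1930 and a man born in 1980. `ridit_transform()`
therefore scores category $k$ within a sex × birth-cohort stratum as

$$R_k = \sum_{j<k} p_j + p_k/2,$$

the proportion of the stratum below the category plus half the proportion
within it. Ridits live in $(0,1)$, are monotone in the category whenever all
categories are occupied, and have stratum mean exactly $0.5$ by construction
(the package asserts this to $10^{-12}$). An EWAS effect per ridit unit is
thus the difference between the notionally lowest- and highest-ranked person
of the same sex and generation.

**Open choice — stratum width.** No binning rule is canonical; the default
is decade-of-birth bins (`birth_bin_width = 10`), with strata under
`min_stratum = 10` samples merged into the nearest bin of the same sex (with
a warning). Scoring is pooled over whatever samples are passed in; to score
per cohort, call the function per cohort.

## Site-wise models and clustered inference

At each CpG the beta value (methylated fraction, in $[0,1]$) is regressed on
the ridit score and covariates by OLS. The standard covariate sets are
`model1` (sex, age at blood sampling, array row, bisulphite plate,
white-blood-cell percentages), `model2` (+ smoking status), `model3`
(+ smoking status and BMI); cohorts that record a two-part differential
(monocytes + granulocytes) pass their own covariate list. Rows with missing
values are dropped listwise (no imputation), sites with fewer than
`n_min = 30` complete cases are skipped and logged, and rank-deficient
designs (e.g. a constant exposure in a subset) fail per site without
stopping the run. Two-sided p-values use the normal reference, matching the
downstream z-based correction; at the sample sizes involved the difference
from the t reference is negligible.

Cohorts with related individuals (twin registers) violate independence.
The default variance estimator is the cluster-robust sandwich on the OLS
point estimates, clustering on `family_id`, with the CR1 finite-sample
factor $\frac{G}{G-1}\frac{n-1}{n-p}$ (the convention of Stata and
`sandwich::vcovCL`); without it the hat-matrix shrinkage of OLS residuals
makes genome-wide tail inference visibly anti-conservative. With every
cluster a singleton the estimator reduces to HC1. An
exchangeable-working-correlation estimating-equation fit (moment-estimated
within-family correlation, analytic block inverse, model-based covariance)
is available per site via `se_type = "exchangeable"`; under balanced designs
its point estimates coincide with OLS, which is why the sandwich default is
a faithful and much faster stand-in at genome scale.

All sites sharing one design matrix are solved in a single QR factorisation,
so a 10,000-CpG × 2,000-sample cohort fits in about a second.

## Bias and inflation of the test statistics

Genome-wide vectors of z statistics routinely show a shifted and/or
over-dispersed null (unmodelled confounding, correlation between sites).
`fit_mixture()` fits

$$z_i \sim \pi_0\,N(\mu_0,\sigma_0^2) + \pi_1\,N(\mu_1,\sigma_1^2) +
\pi_2\,N(\mu_2,\sigma_2^2),$$

by Gibbs sampling with conjugate updates — Dirichlet(1,1,1) on $\pi$,
normal priors $N(0,10^2)$, $N(-3,10^2)$, $N(3,10^2)$ on the means,
inverse-gamma(2, 1) on the variances — under the ordering constraint
$\mu_1 \le \mu_0 \le \mu_2$, enforced by truncated draws in every iteration.
The centre component is the empirical null: its mean is the *bias*, its sd
the *inflation*. Identification by ordering (not by largest weight) stays
correct when the signal fraction is large. `bacon_correct()` then applies
$z' = (z-\mu_0)/\sigma_0$, $SE' = SE\cdot\sigma_0$,
$effect' = effect - \mu_0\,SE$.

The method's defining property, asserted in the tests: with 10% of sites
drawn from $N(\pm4,1)$, genomic-control $\lambda$ exceeds 1.3 while the
mixture inflation estimate stays within 0.05 of 1.

**Numerical choices.** Defaults are 5000 iterations with 2000 burn-in and
posterior-median point estimates (robust to the skew of variance
posteriors). Initial values are moment-based. A split-chain potential-scale-
reduction diagnostic above 1.1 sets `converged = FALSE` with a warning. For
a pure-Gaussian dataset the three-component mixture is not identified — the
outer components can trade mass with the null along a likelihood ridge — so
individual posterior medians of $(\mu_0, \sigma_0)$ wander by a few
hundredths between seeds even for 50,000 statistics; averaging over chains
(or replicates, as the tests do) removes this. Statistic vectors shorter
than 1000 trigger a warning: the empirical null is then weakly identified.

## Meta-analysis, multiplicity, power

`fixed_effects_meta()` combines cohorts per site with weights $1/SE_i^2$; no
random-effects model is offered (Cochran's Q is reported for diagnostics
only). The pipeline applies the mixture correction per cohort before
combining and once more to the meta z statistics, with both steps
toggleable and both fits retained. Significance is Bonferroni at
`fwer/n_tests` over the realized number of tests, unrounded.

`required_n()`/`power_at_n()` compute power for a single linear-model
predictor explaining $R^2$ of outcome variance from the noncentral-F
distribution with $f^2 = R^2/(1-R^2)$, one numerator degree of freedom,
$n-2$ denominator degrees of freedom and noncentrality $f^2 n$. The exact
method behind the published figure of ~3735 participants for $R^2=0.01$,
$\alpha=10^{-7}$, 80% power is not recorded; the noncentral-F default gives
3781 (1.2% higher) and a Fisher-z approximation is available as an option.

## Mediation by smoking

`mediate()` uses the difference-in-coefficients decomposition: total effect
from the model without smoking, direct effect from the model with it,
indirect = total − direct, proportion mediated = indirect/total. Under
linear no-interaction models this equals the product-of-coefficients
estimator. Ratios explode when the total effect is tiny, so proportions are
only reported when $|total| \ge 0.001$ on the beta scale (`small_total`
flag) and inside $[0,1]$ (`sign_reversal` flag otherwise). Point estimates
are deterministic; percentile bootstrap intervals (`mediate_bootstrap()`,
default 500 seeded resamples, resampling individuals and refitting both
models) are opt-in.

## Twin-pair discordance

`build_pairs()` keeps complete MZ/DZ pairs, orders members by sample id so
difference signs are reproducible, and assigns smoking-concordance strata
(discordant = current vs never; concordant-current; concordant-never; all
other combinations excluded from stratified runs).
`within_pair_regression()` regresses the within-pair methylation difference
on the within-pair ridit difference. Anything shared within a pair —
family environment, and in MZ pairs the full genotype — cancels in the
differences, so the slope estimates the within-family (direct) association.
An intercept is included by default to absorb birth-order-like asymmetries;
the no-intercept variant is numerically identical to a pair-fixed-effects
regression on the stacked data (asserted to $10^{-8}$ in the tests).
Smoking adjustment uses the within-pair difference of a numeric coding
never = 0, former = 1, current = 2 — a repository convention, documented
here because the source analyses do not state their coding.

## Cross-study comparison and annotation

`correlate_effects()` reports the Pearson correlation between internal and
external per-CpG effects over matched sites, with no rescaling even when
the external study reports group differences rather than slopes — the
comparison is of direction and relative magnitude patterns, not calibrated
units. `gwas_proximity()` flags CpGs within 500 kb of a SNP passing
p < 10⁻⁴, as a closed interval on either side; open-vs-closed at the exact
boundary is not specified anywhere, so the closed rule is fixed and tested
at 500,000 vs 500,001 bases. BED-like annotation (0-based, half-open) is
converted to 1-based positions at the boundary.

## Cis eQTM association

Transcripts are filtered in fixed order — detection (a read in ≥ 1% of
samples) first, then the 1% least variable by log₂-CPM variance, ties broken
by transcript order — because the order changes the outcome and the source
only fixes this one. Log-CPM uses a half-count offset:
$\log_2((c+0.5)/(lib+1)\cdot 10^6)$. Cis pairs are all CpG–transcript pairs
within 100 kb (closed) of the transcript start (`anchor = "body"` measures
to the nearest edge instead); CpGs with no eligible transcript are dropped
and counted. Each pair is an OLS fit of log₂-CPM on methylation plus
observed covariates (age, sex, monocyte/lymphocyte/neutrophil percentages);
the published analysis additionally used latent expression factors, which
this package deliberately replaces with observed covariates — a fidelity
limitation to keep the module self-contained. Per-cohort results combine
through the same fixed-effects meta machinery keyed on
(CpG, transcript).

## The synthetic-data generator

`generate_cohort()` draws, per cohort: demographics from the four published
cohort profiles (sample sizes 2172/668/608/704, percent female, age and BMI
moments, birth-year ranges, smoking-status and education distributions);
education categories; ridits via the package's own transform; smoking status
from a logistic model on the ridit whose slope and intercept are calibrated
numerically so the current-smoking prevalence matches the profile and the
education–smoking correlation hits its target (−0.11 by default; an
infeasible target fails naming the constraint); pack-years from the
cigarettes/day and years-smoked draws; cotinine consistent with status
(smokers ≥ 15 ng/mL; never smokers mostly < 1, a 150/586 second-hand
fraction in [1, 15) and a 5/591 misclassified fraction ≥ 15 — the published
rates); cell percentages; plate and row labels.

Methylation is generated on the beta scale,

$$m = \mathrm{clip}(base + \beta_{edu}\,ridit + \beta_{smk}\,I(current)
+ \text{covariate terms} + \text{familial} + \varepsilon,\ 0,\ 1),$$

with $|\beta_{edu}^{total}|$ uniform on $[0.006, 0.060]$ (76% positive) at
200 of 10,000 CpGs by default, smoking-only effects uniform on
$[-0.18, 0.07]$ at another 500, residual sd 0.04 (a typical 450k residual
spread; no published value exists, chosen once), and clipping logged and
held below 1% of entries. Generating on the beta scale with clipping rather
than a logit-normal model matches the analysis scale of the site-wise
models; a logit option would be a straightforward extension. The mediated
fraction is routed exactly: the smoking coefficient at causal CpGs is
$\beta_{smk} = \frac{mf}{1-mf}\,\beta_{direct}/\hat\gamma$ with
$\hat\gamma$ the realized education→current-smoking slope in that cohort's
sample, so the difference-in-coefficients proportion is $mf$ (default 0.3)
in expectation in every cohort. Study-level truth (which CpGs are causal,
their effects, covariate coefficients) comes from one stream seeded by the
master seed; each cohort then uses its own derived stream, so adding
cohorts never perturbs earlier ones, and between-cohort effect
heterogeneity is off by default (`effect_jitter_sd = 0`).

Twin cohorts share a familial-plus-genetic latent per pair ($F$; genetic
part fully shared in MZ, half in DZ pairs). The education latent loads on
$F$ with share `edu_familial_share` (0.5); causal CpGs optionally load on a
confounder built from the same latent with loading `confound_sd`, of which
`familial_variance_share` is the pair-shared part — at share 1 the
confounding vanishes from within-MZ-pair differences while remaining in the
population cross-section, which is exactly the contrast the twin design
exploits.

Expression counts are Poisson draws around
$2^{base + \beta_{cis}(m - 0.5) + \varepsilon}$ CPM with $\beta_{cis} =
-4.5$ log₂-CPM per methylation unit at active cis pairs and lognormal
library sizes. Two realism constraints matter and were found the hard way:
baseline CPMs are scaled to compose the full library, and the default
simulated transcriptome is 2000 transcripts, so the cis-active transcripts
are a negligible, non-coherent share of the library — with few transcripts
the normaliser itself co-varies with methylation and attenuates every cis
slope, an artifact a genome-wide transcriptome does not have.

**What the generator does not emulate:** probe-level array noise, bimodal
genome-wide beta distributions, correlated CpGs (LD-like co-methylation or
meQTL structure), batch missingness, or count overdispersion beyond
Poisson-lognormal. Passing tests therefore show that the estimators recover
the generating model's parameters under realistic effect sizes and
confounding structure — not that they are robust to every artefact of real
array data; the upstream QC/normalisation that handles those artefacts is
explicitly out of scope.

## Problem sizes used in the test suite

The suite exercises the study-scale dataset (4 cohorts × 2000 samples ×
10,000 CpGs) for the effect-recovery and family-wise-error checks (20 null
replicates), 50,000-statistic vectors for the mixture-recovery grid (nine
bias/inflation combinations × 10 replicates, 2000-iteration chains), 5000
samples for mediation recovery, and 150 MZ pairs × 20 replicates for the
twin-design contrasts. Unit tests run on miniature fixtures (hundreds of
samples and CpGs). These sizes were chosen so the statistical tolerances
stated in the tests are comfortably identified while the whole suite runs
in minutes on a single CPU.

## Known limitations

* The exchangeable estimating-equation path is per-site R code; at genome
  scale use the (default) sandwich estimator.
* The mixture model assumes three Gaussian components; heavy-tailed or
  asymmetric signal distributions will load partly on the null component.
* Difference-in-coefficients mediation is biased in the presence of
  exposure–mediator interaction or unmeasured mediator–outcome confounding;
  no counterfactual estimator is provided.
* eQTM inference uses OLS on log-CPM; strongly overdispersed low-count
  transcripts would call for a count model, which the detection filter only
  partially mitigates.
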