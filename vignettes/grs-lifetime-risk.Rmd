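---
title: "Genomic risk scores and lifetime CHD risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic risk scores and lifetime CHD risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grslife)
```

# Scope

`grslife` implements the full analysis chain used to evaluate a polygenic
(genomic) risk score, GRS, for incident coronary heart disease against and
alongside clinical 10-year risk scores: score construction from GWAS
summary statistics with LD thinning, age-timescale Cox survival modelling
with delayed entry, truncated concordance and its jackknife comparison,
risk reclassification (NRI, IDI), nonparametric lifetime-risk curves with
competing risks, and fixed-effect meta-analysis. Because individual-level
cohort and consortium data cannot be shipped, the package includes a
synthetic cohort generator whose defaults emulate a Finnish-style
population cohort; every stage of the pipeline is exercised and tested
against it, and the published reclassification cross-tabs bundled under
`inst/extdata/reclass/` provide exact worked examples on real counts.

# The genomic risk score

For subject $i$ and SNP $j$ with per-allele log-odds weight $w_j$ (from an
external GWAS meta-analysis) and effect-allele dosage $g_{ij} \in [0, 2]$,

$$\mathrm{GRS}_i \;=\; \sum_{j \in S} w_j\, g_{ij},$$

reported per standard deviation: the score is standardized to mean 0, SD 1
(denominator $n-1$) within the evaluation cohort. The SNP set $S$ is
obtained by greedy LD thinning: SNPs are visited in ascending p-value
(ties: chromosome, then position) and kept unless their dosage $r^2$ with
an already-kept SNP within a 1 Mb window exceeds a threshold; the
threshold is chosen from a grid (default $\{1, 0.9, \dots, 0.1\}$) by
maximizing the AUC of the standardized score against a binary
case/control outcome, ties resolved toward the larger threshold.

Choices the data cannot dictate, made once and documented here:

* **Thinning priority.** p-value-ordered greedy selection is the standard
  clumping convention and is deterministic; position- or effect-ordered
  visiting is not offered.
* **Missing dosages** contribute their Hardy–Weinberg expectation
  $2 \cdot \mathrm{EAF}_j$, keeping scores comparable across subjects with
  different missingness instead of silently shrinking them.
* **Strand-ambiguous SNPs** (A/T, C/G) are dropped during allele
  harmonization unless both the reported and observed allele frequencies
  are decisive (more than 0.08 from 0.5) and then oriented by frequency
  concordance. The margin is conservative; every drop is counted in the
  harmonization log.

# Survival machinery

All hazard models use **attained age as the time scale** with delayed
entry at the baseline age: the risk set at age $a$ is
$\{j : \text{entry}_j < a \le \text{exit}_j\}$, so comparisons are
age-matched by construction. Fits are sex-stratified cause-specific Cox
models (competing events censored), maximized by `survival::coxph` with
the Efron tie correction — less biased than Breslow when rounded ages
produce ties. The per-stratum baseline cumulative hazard is the Breslow
estimator evaluated at the uncentered linear predictor, and the
model-based 10-year risk of a subject entering at age $a_0$ is

$$1 - \exp\!\big(-[H_{0s}(a_0 + 10) - H_{0s}(a_0)]\, e^{\mathrm{lp}}\big),$$

with flat extrapolation (and a flag) beyond the last observed event age.

Cohort rules mirror prospective-cohort practice: subjects with prevalent
cardiovascular disease are excluded, baseline age below 30 years is
excluded, and follow-up is censored at attained age 75 (events beyond it
recoded as censored). The filter is idempotent and logs its exclusions.

Kaplan–Meier curves (delayed entry, Greenwood variance, log-scale 95%
band) and the left-truncated Aalen–Johansen estimator
$\widehat{F}_c(t) = \sum_{a \le t} \widehat{S}(a^-)\, d_c(a)/n(a)$ provide
lifetime cumulative risk; with no competing events the two coincide
exactly, which the tests assert. The age at which a group's cumulative
incidence first reaches a level (default 10%) summarizes how much earlier
high-genomic-risk groups reach clinically relevant risk; a group that
never attains the level within follow-up returns `NA`. The
Aalen–Johansen confidence band, when requested, is a normal approximation
using the multistate `survfit` standard error; the estimate itself is
computed directly and cross-checked against `survfit` in the tests.

**Combined clinical + genomic model.** The "clinical + GRS" model is a
sex-stratified Cox model with two covariates: the logit of the clinical
10-year risk and the standardized GRS. For risk binning, the
clinical-score-alone risk is the published-equation risk itself (how
reclassification tables bin the clinical score), while the combined risk
is the model-based 10-year risk above. This definition is recorded in the
pipeline's provenance block.

# Discrimination and reclassification

The **truncated Harrell C-index** restricts comparable pairs to events
within the horizon (default 10 years of follow-up time from entry): pair
$(i, j)$ is comparable iff $i$ has the event at $t_i \le$ horizon and
$t_j > t_i$; score ties count 0.5. Follow-up time, not attained age, is
used for the horizon because the quantity of interest is "events within
10 years". The difference between two models on the same subjects uses
the **correlated jackknife**: leave-one-out values of $\Delta C$ are
exact and cheap because the implementation keeps per-subject pair
tallies; $\mathrm{var} = \frac{n-1}{n} \sum_i (\Delta C_{(-i)} -
\overline{\Delta C})^2$, with $p = 1$ defined for the degenerate
$\Delta C = 0$ case. Among jackknife variants, leave-one-out of the
difference was chosen; the tests check its SE against a bootstrap within
25%.

Categorical NRI over the 0–7.5 / 7.5–10 / 10–20 / 20–100% bins
(half-open intervals, 7.5% exactly falls in the second bin) is
$(\text{up} - \text{down})/n_\text{events} + (\text{down} -
\text{up})/n_\text{non-events}$ with the standard binomial-difference
variance and normal intervals (Pencina-style; no variance method is
prescribed by the sources the tables come from). Subjects censored before
the horizon count as non-events — forced by the margins of the published
tables this module reproduces, and a documented limitation (no IPCW
correction). Continuous NRI uses unweighted sign proportions; IDI is the
difference in discrimination slopes with a two-sample SE.

# Meta-analysis

Fixed-effect inverse-variance pooling with Cochran's $Q$, its chi-square
p-value, and $I^2 = \max(0, (Q - \mathrm{df})/Q) \cdot 100$. Hazard
ratios are pooled on the log scale; when only a published 95% CI is
available the SE is recovered as $(\log \mathrm{hi} - \log
\mathrm{lo})/3.92$. Random-effects models are deliberately out of scope.

# The synthetic cohort generator

The generator produces, from one seed, bit-identical genotypes, summary
statistics and survival records.

* **Genotypes.** Two independent haplotypes per subject, each from a
  block-wise AR(1) latent Gaussian (block size 20, $\rho = 0.8$)
  thresholded at $\Phi^{-1}(1-\mathrm{MAF})$, summed to exact $\{0,1,2\}$
  dosages; MAF uniform on $[0.05, 0.5]$. This yields tunable within-block
  LD and independence across blocks. Blocks are spread over 22
  chromosomes, 5 kb between SNPs in a block, 10 Mb between blocks.
* **Summary statistics.** A random 20% of SNPs carry true effects
  $N(0, 0.05^2)$ (log-odds per allele); reported weights add noise with
  $\mathrm{SE} = 1/\sqrt{2p(1-p)N}$ at $N = 185{,}000$, the scale of a
  large CHD meta-analysis. A configurable fraction of rows is reported on
  the opposite allele, and ~5% of SNPs get strand-ambiguous allele pairs,
  so harmonization is always exercised.
* **Covariates** follow a Finnish-style baseline table: age 45.97 (SD
  12.7, truncated to 25–74) years, SBP 134.93 (19.7) mmHg, total
  cholesterol 5.58 (1.11) mmol/L, HDL 1.45 (0.38) mmol/L, 26% smokers, 5%
  diabetes, 11% antihypertensive and 3% lipid-lowering treatment.
* **Events.** CHD ages follow a Weibull proportional-hazards model on
  attained age, shape 5, scale 115, with linear predictor
  $\log(1.74)\cdot \mathrm{score}_\mathrm{std}$ plus covariate terms
  (smoking 0.55, diabetes 0.60, male 0.70 on the log-hazard scale; ±0.25
  to ±0.35 per SD for SBP, cholesterol and HDL). Competing non-CHD death
  is an independent Weibull (shape 6, scale 80) with its own smoking and
  sex effects. Administrative censoring at 15 years of follow-up matches
  a 10–20-year collection. Under the default configuration about 6.5% of
  the filtered cohort has an incident CHD event before age 75 and roughly
  a fifth dies of other causes — enough competing risk that the
  Aalen–Johansen curve visibly departs from $1 - \mathrm{KM}$. The shape
  and scale were calibrated once against these targets and then frozen;
  they are configuration, not estimates of any real cohort's hazard.
* **Family history** is Bernoulli with logit linear in the standardized
  true score (coefficient 0.3, base prevalence 15%) — a stand-in for
  first-degree-relative history without pedigree simulation. A small
  age- and score-dependent fraction carries prevalent CVD for the
  exclusion filter to act on.

**What the generator does not emulate:** realistic recombination maps or
reference-panel LD, genotyping/imputation error, pedigrees, secular
trends in risk factors, or the miscalibration structure of real clinical
scores. Consequences worth knowing:

* On synthetic data the AUC-selected thinning threshold is usually 1.0
  (no thinning): with homogeneous noise and exchangeable block LD,
  redundant SNPs average the weight noise rather than distort the score.
  The 0.7 optimum seen on real consortium data reflects LD and weight
  structure the generator does not reproduce. The selection machinery is
  therefore tested for correctness (oracle equality, tie rules), not for
  reproducing any particular optimum.
* The published-equation clinical risks are miscalibrated for the
  synthetic population, so synthetic categorical NRI and IDI between the
  published-equation risk and the refit model-based risk are small or
  even sign-indefinite despite a clearly positive $\Delta C$ — NRI and
  IDI are calibration-sensitive where concordance is not. The exact
  reproduction of the published reclassification tables goes through the
  bundled counts instead.

# Parameter recovery and null calibration

The headline recovery check fits the age-timescale, sex-stratified Cox
model on the **standardized true score** of freshly simulated cohorts
(n = 5000, M = 2000, 50 replicates) and asks that the model-based 95% CI
cover the generative hazard ratio 1.74 per SD in at least 90% of
replicates. The true score is used because 1.74 is its estimand; a GRS
built from noisy weights is an error-in-variables covariate whose per-SD
hazard ratio is attenuated toward the null by a factor depending on the
GWAS sample size, so recovery of the generative parameter must be
measured on the generative score. A separate check asserts exactly that
attenuation direction for the noisy-weight GRS.

Null calibration: with the score's hazard effect set to zero, the
in-sample $\Delta C$ of clinical + GRS over clinical carries only the
refitting optimism of one noise covariate, which decays like
$1/(2\cdot\text{events})$; the centred-on-zero check therefore runs at
n = 20,000 (~1200 events), where the optimism (~0.001) is an order of
magnitude below the asserted bound, and the GRS-by-smoking interaction
p-values are checked for uniformity across replicates at the default
cohort size. Problem sizes throughout the test-suite (n of a few hundred
to 20,000, 40–50 Monte-Carlo replicates) were chosen as the smallest
that make the Monte-Carlo error comfortably smaller than the asserted
tolerances.

# Numerical conventions

* Ages are continuous years; risk sets use half-open $(\text{entry},
  \text{exit}]$ intervals; a record whose truncated exit does not exceed
  its entry is dropped with a warning.
* Newton iterations run to a gradient tolerance of $10^{-9}$ with a cap
  of 100; non-convergence, singularity and separation (|log HR| > 15)
  are hard errors, never silent.
* Standardization requires a positive SD and errors on constant scores;
  monomorphic SNPs get missing weights and are skipped with a flag;
  zero-variance dosage columns are treated as $r^2 = 0$ in thinning and
  as missing (with a warning) in `ld_r2`.
* GRS quintiles use type-7 sample quantiles of the standardized score.
* All confidence intervals use 1.96; reported p-values are two-sided
  normal or chi-square as stated above.

# Known limitations

Beyond the generator's simplifications: no IPCW-adjusted reclassification
or time-dependent AUC; no Fine–Gray subdistribution hazards (cause-
specific models only); no reference-panel LD or cross-chromosome
thinning; no penalized score training; clinical-score coefficient tables
are applied as published, without recalibration to the cohort at hand —
the white-stratum pooled-cohort coefficients are used where race is not
recorded, and this is logged in the score manifest.
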