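---
title: "Genetic risk scores and age at onset: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores and age at onset: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`grsonset` implements a complete analysis path for one study design: a
clinical cohort of patients undergoing first-time coronary
revascularization, genotyped at a panel of SNPs previously associated with
coronary artery disease (CAD) and with LDL cholesterol (LDL-C), asking
whether a higher burden of risk alleles is associated with earlier onset.
This vignette explains the models, the choices that were genuinely open and
how they were resolved, what the synthetic-data generator does and does not
emulate, and the numerical conventions.

## Scores

For subject $i$ with effect-allele dosage $s_{ij} \in [0,2]$ at SNP $j$ of
an $N$-SNP panel,

$$\mathrm{uGRS}_i = \sum_{j=1}^{N} s_{ij}, \qquad
  \mathrm{wGRS}_i = \frac{N}{\sum_j \beta_j} \sum_{j=1}^{N} \beta_j\, s_{ij},$$

where $\beta_j$ is the published GWAS effect size of the risk-increasing
allele. Dividing the weighted sum by the average effect size keeps both
scores on the allele-count scale; when all $\beta_j$ are equal, the two
coincide exactly (the implementation short-circuits the normalization in
that case so the equality is bitwise, not just to rounding). Scores are
standardized to mean 0, SD 1 (sample SD, $n-1$ denominator) within the
analysis sample, so regression coefficients read as years per SD. The
reference population for standardization was an open choice — the source
design could have standardized in the full genotyped biobank or the
analysis subset — and the analysis sample was chosen because it makes the
per-SD interpretation internally consistent with the fitted models.

### Harmonization

The weight table names an effect and an other allele per rsID; the VCF
encodes a ref and an alt allele. `harmonize()` matches variants primarily
by rsID (chrom:pos disambiguates colliding IDs), uses the designated proxy
variant (LD $r^2 > 0.8$) when an index rsID is absent, flips dosages
($s \mapsto 2 - s$) when the effect allele is the reference allele, and
drops variants whose allele pair matches neither orientation. Harmonizing
an already-oriented matrix is an error, never a silent double flip, and the
report satisfies matched + dropped = $N$ by construction.

Strand-ambiguous SNPs (A/T and C/G pairs) cannot be disambiguated from
allele labels alone. The default policy is to *keep* them with a warning,
on the argument that a single-platform, single-pipeline cohort has
consistent strand; `strand_policy = "drop"` supports the conservative
alternative. Allele-frequency-based strand inference is deliberately out of
scope.

### Missing genotypes

Two policies are provided because the right answer is not derivable from
the design itself:

- `mean_impute` (default): a missing cell takes the variant's in-sample
  mean dosage. This keeps the effective SNP count constant across subjects
  and is the convention of standard PRS tooling.
- `rescale`: missing cells contribute zero and the subject's score is
  scaled up by $N/n_\text{used}$ (unweighted) or by the ratio of the full
  to the observed beta sum (weighted).

The two differ per subject but agree closely in ranking (rank correlation
> 0.95 at 10% missingness in the test suite). Imputed dosages (`DS` VCF
fields) are used only when `prefer_dosage = TRUE`; the default is hard
genotype calls, and both paths are tested.

## Cohort analyses

Age strata are sex-specific with boundaries closed on the right: men
$\le 40$, $(40,55]$, $(55,70]$, $>70$; women $\le 50$, $(50,65]$,
$(65,80]$, $>80$ years. (A conflicting narrative definition of "very
young" — men < 35, women < 45 — exists for this design; the tabulated
cutoffs were used because the stratified results are organized by them.)
Premature CAD is a first event strictly before 55 (men) / 65 (women) years.

"P for trend" across the four strata uses the Cochran–Armitage test for
binary characteristics — the $Z$ form with equally spaced scores $1..K$
centered at their count-weighted mean, normal reference, no continuity
correction; the statistic is affine-invariant in the scores and its square
equals the score chi-square of `stats::prop.trend.test`, which serves as an
independent cross-check in the tests — and, for continuous characteristics,
the slope $t$-test of an OLS regression on the group index.

Age-at-onset models are ordinary least squares on complete cases per model:
sex-adjusted models per factor (GRS models additionally adjusted for
genetic principal components 1 and 2, exactly as captioned in the source
design — whether the non-GRS factors were also PC-adjusted is unstated
there, and the captioned reading is implemented), and multivariable models
per score adjusting for sex, PC1, PC2, familial CAD, smoking, BMI, diabetes,
hypertension and known high cholesterol. Confidence intervals and p-values
come from the $t(n-p)$ distribution. Rank-deficient designs are a fatal
error naming the collinear terms. Effect modification is tested by adding a
score-by-modifier product term to the multivariable model. The
"P for difference" across clinical presentations is one-way ANOVA for score
means and Pearson chi-square (no continuity correction) for familial CAD —
conventional defaults, since the source design does not name its test. Two-
sided $\alpha = 0.05$ throughout; no multiple-testing correction, matching
the design being reproduced.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; the defaults are the package's
definition of a realistic cohort of this kind and are not adjusted per
analysis:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 1599 | analysis-set size of the emulated cohort |
| `n_snps_cad`, `n_snps_ldl` | 67, 58 | panel sizes of the two scores |
| `n_shared` | 9 | shared SNPs; gives weighted scores an expected correlation $\approx 9/\sqrt{67\cdot 58} = 0.14$, the weak overlap reported for such panels |
| `n_proxy_*` | 3 each | proxy-substituted SNPs per panel |
| `n_imputed_*` | 16, 11 | records carrying a `DS` field |
| `freq_range` | [0.05, 0.95] | uniform allele-frequency law, common-variant panels |
| `beta_mean`, `beta_sd` | 0.08, 0.05 | betas $\sim \lvert N(0.08, 0.05)\rvert$, GWAS-scale effects |
| `gamma_cad`, `gamma_ldl` | −0.51, −0.70 y/SD | true onset-age effects of the standardized true weighted scores |
| `gamma_fam` | −3.2 y | familial-CAD effect |
| `gamma_sex` | +9 y | female−male onset difference, consistent with the 55/65-year premature thresholds |
| `mu` | 62.8 y | baseline so the cohort mean age lands near 64 |
| `noise_sd` | 11 y | residual SD; at $n \approx 1600$ this reproduces per-SD regression CIs of roughly $\pm 0.55$ years, the precision scale of such cohorts |
| `frac_female`, `fam_prevalence` | 0.28, 0.41 | cohort composition |
| `age_range` | [29, 96] | truncation of onset ages |

Genotypes are Binomial(2, $p$) per subject — Hardy–Weinberg equilibrium
with no linkage disequilibrium between panel SNPs. Onset age is

$$\text{age}_i = \mu + \gamma_\text{sex}\,\text{female}_i
 + \gamma_\text{fam}\,\text{fam}_i + \gamma_\text{cad}\, z^{CAD}_i
 + \gamma_\text{ldl}\, z^{LDL}_i + \varepsilon_i,$$

with $z$ the standardized true weighted scores (computed with the same
formulas as the scoring module) and $\varepsilon \sim N(0, \sigma^2)$.
Familial CAD is drawn independently of the scores, mirroring the observed
near-independence of self-reported family history and common-variant
scores. The binary covariates (smoking, diabetes, hypertension, known high
cholesterol), BMI and the four-category clinical presentation are drawn
with prevalences that depend on the *non-genetic* component of onset age
(logistic in age for binaries, multinomial logits for presentation, STEMI
declining and stable angina rising with age). Driving them off the
non-genetic component gives them the qualitative age gradients seen in
real stratified tables while keeping them exactly independent of the
scores, so multivariable adjustment for them leaves the score effect
unbiased — which is what makes the parameter-recovery tests sharp.

Two consequences are worth stating plainly. First, effects are defined per
SD of the *true* score; the pipeline estimates per SD of the *observed*
score. On artifact-free data the two are identical (and the end-to-end test
asserts score equality to 1e-10); under missingness the estimate attenuates
slightly. Second, because the two panels share SNPs, a model containing one
score at a time (the design being emulated fits them separately) estimates
the direct effect plus the correlation-weighted effect of the omitted
score; at the defaults that is about $-0.70 + 0.14 \times (-0.51)$ for the
LDL-C score. The recovery tests bound the estimate around the configured
truth with this coupling included.

What the generator does **not** emulate: LD structure and realistic MAF
spectra, relatedness, genotyping error beyond the injected missingness and
ref/alt swaps, proxy imperfection (proxies are carried as perfect
surrogates despite their recorded $r^2 < 1$), the joint distribution of
covariates (only their marginal age trends are mimicked), and any
selection processes such as pre-hospital mortality. Passing tests therefore
demonstrate correctness of the computational pipeline and calibration of
the statistics under idealized population-genetic assumptions, not fidelity
to any real cohort's joint data distribution.

## Numerical conventions and edge cases

- Dosages live in $[0,2]$; hard calls in $\{0,1,2\}$; `NA` is the missing
  marker; matrices are stored as doubles so re-encoding checks can assert
  bitwise identity.
- Degenerate trend tables (pooled proportion 0 or 1) return $p = 1$ with a
  warning; an all-constant continuous trend does the same; a zero-variance
  score is a fatal standardization error.
- A subject with every panel SNP missing gets an `NA` score and a warning;
  a variant missing in all subjects cannot be mean-imputed and is fatal.
- Zero beta sum makes the weighted normalization undefined and is fatal.
- Determinism: every generator stage seeds its own RNG stream from the
  config seed, so identical configs give byte-identical file bundles and
  repeated `simulate → score → analyze` runs reproduce every output file
  exactly (manifests record checksums, not timestamps, for this reason).

## Problem sizes used by the checks

The test suite exercises the brute-force score oracles on 100 random
50×67 instances; trend-test calibration on 1,000 null tables with 200
subjects per group; OLS interval coverage on 500 replicates; and parameter
recovery on 200 replicates of 1,600-subject cohorts — sizes chosen so the
whole suite runs in about a minute while keeping Monte-Carlo error well
inside the asserted bounds. `scripts/acceptance.R` re-runs the pooled
summary arithmetic and the 200-replicate recovery study from a single
command-line seed.

## Limitations

The package fits linear mean models of onset age among cases only; it does
not model time-to-event (no survival analysis), does not compute principal
components (they are consumed as covariates), does not discover proxies or
compute LD, and applies no genotype QC — inputs are assumed to be
post-QC, post-imputation. These boundaries are deliberate: the package
reproduces an analysis, not a genotyping pipeline.
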