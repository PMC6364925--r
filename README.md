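# grsonset

Genetic risk scores and age at onset of coronary artery disease.

`grsonset` is an R package for asking a simple clinical-genetics question:
do patients who carry more known risk alleles need their first coronary
revascularization earlier in life? It implements the full analysis path for
a clinical angiography cohort — from genotypes in a VCF and GWAS
effect-weight tables to per-subject genetic risk scores (GRS) and
age-at-onset regression models — together with a synthetic cohort generator
so that every stage is testable without access to individual-level patient
data.

## The scores

For subject *i* with effect-allele dosages *s<sub>ij</sub>* over the *N*
SNPs of a score panel:

- unweighted GRS (one point per risk-increasing allele, additive model):

  uGRS<sub>i</sub> = Σ<sub>j</sub> s<sub>ij</sub>

- weighted GRS (each allele weighted by its GWAS beta, normalized by the
  average effect size so both scores share the allele-count scale):

  wGRS<sub>i</sub> = ( N / Σ<sub>j</sub> β<sub>j</sub> ) ·
  Σ<sub>j</sub> β<sub>j</sub> s<sub>ij</sub>

Before scoring, `harmonize()` orients every variant so the risk-increasing
allele is the counted (alternative) allele regardless of how the VCF encodes
ref/alt, substituting proxy variants (LD r² > 0.8) for index SNPs that are
absent, and dropping variants whose allele pair cannot be reconciled.
Scores are standardized to mean 0, SD 1, so regression effects read as
*years of earlier/later onset per SD of the score*.

Downstream, the package reproduces the standard epidemiological toolkit for
this design: sex-specific age strata with Cochran–Armitage and linear trend
tests, between-score Pearson correlation, sex-adjusted and multivariable
linear models of age at onset, effect-modification (interaction) tests, and
clinical-presentation summaries (STEMI / NSTEMI / UAP / SAP).

## Worked example

Simulate a cohort, score it, and fit the age-at-onset models:

```r
library(grsonset)

bundle <- run_simulate("sim", config = list(n_subjects = 300), seed = 7)
scored <- run_score(bundle$paths$vcf, bundle$paths$weights_cad,
                    bundle$paths$weights_ldl, out = "score")
scored$reports$cad
#> <harmonization_report>
#>   matched: 67 (3 via proxy, 0 flipped, 23 strand-ambiguous kept)
#>   dropped: 0

res <- run_analyze(scored$paths$scores_cad, scored$paths$scores_ldl,
                   bundle$paths$phenotypes, out = "analysis")
res$models[res$models$focal & res$models$model == "model4_wgrs_ldl", ]
#> # A tibble: 1 × 9
#>   model           term       estimate    se ci_low ci_high     p     n focal
#>   <chr>           <chr>         <dbl> <dbl>  <dbl>   <dbl> <dbl> <int> <lgl>
#> 1 model4_wgrs_ldl z_wgrs_ldl   -0.570 0.617  -1.78   0.644 0.356   300 TRUE
```

The harmonization report says all 67 CAD-panel SNPs were matched, 3 of them
through proxy variants. The model row is the multivariable estimate for the
weighted LDL-C score: in this 300-subject simulation each 1 SD higher score
is associated with 0.57 years earlier revascularization (95% CI −1.78 to
+0.64); the generator's true value of −0.70 sits well inside the interval,
and at this small n the estimate is, as expected, not significant. `analysis/report.txt` collects the age-stratified
characteristics tables, presentation summaries, model estimates,
correlations and interaction tests, each traceable to a TSV next to it.
`plot_model_estimates()` draws the estimates as a forest plot and
`autoplot()` on a score set shows the score distributions.

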