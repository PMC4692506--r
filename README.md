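# mdrpipe

Gene–gene interaction analysis for case-control candidate-gene studies,
built around a from-scratch **multifactor dimensionality reduction
(MDR)** engine.  The package is aimed at genetic-epidemiology analysts
who have categorical genotypes at a handful of candidate polymorphisms
(SNPs, insertion/deletion markers, multi-allelic markers such as ApoE
ε2–4), a binary disease phenotype with optional etiologic subtypes, and
clinical covariates — and who want the classical single-locus screen,
an interaction search, and adjusted odds ratios in one reproducible,
seeded pipeline.

## The method

For a combination of *k* loci, MDR labels each genotype cell *c*
(with *a<sub>c</sub>* cases and *b<sub>c</sub>* controls) **high risk**
when

> *a<sub>c</sub>* / *b<sub>c</sub>* ≥ *T*,  *T* = n<sub>cases</sub> / n<sub>controls</sub>

of the training data, collapsing the k-locus genotype into one binary
attribute.  That attribute is scored by balanced accuracy
(sensitivity + specificity)/2 under stratified 10-fold
cross-validation; the search over all combinations per order reports
the model with the highest **CV consistency** (folds won) and lowest
prediction error, with an exact binomial sign test and a
label-permutation test (add-one estimator) for significance.  The
selected high/low recode then feeds a 2×2 crude odds ratio (Woolf CI)
and a covariate-adjusted logistic odds ratio.  Around this sit
Hardy–Weinberg chi-square tests (gene-counting expected counts,
df = genotypes − alleles), uncorrected Pearson genotype chi-squares
with Bonferroni correction, and a calibrated synthetic cohort generator
that plants a known two-locus interaction so the whole pipeline is
verifiable without external data.  See the vignette
(`vignettes/mdr-interaction-analysis.Rmd`) for the full model and
design choices.

## Worked example

Generate a cohort with a planted ACE × β-FG T148C interaction
(odds ratio 2.5), search orders 1–3, and estimate the adjusted OR:

```r
library(mdrpipe)

cfg <- default_config(n_cases = 300, n_controls = 300,
                      interaction_or = 2.5, seed = 7)
co <- generate_cohort(cfg)
folds <- make_folds(co, k = 10, seed = 8)
mdr_search(co, orders = 1:3, folds)
#> MDR exhaustive search (k = 10 folds)
#> order  best model                       testing BA   CV consistency sign p
#> 1      ACE                              0.5650       9/10           0.01074
#> 2      ACE x BFG_T148C                  0.5917       10/10          0.01074
#> 3      ACE x BFG_T148C x BFG_A455G      0.5700       5/10           0.05469
#> overall best: ACE x BFG_T148C
```

The search recovers the planted pair with full cross-validation
consistency (10/10 folds) and a testing balanced accuracy of 0.59.
Labeling the full data and classifying individuals:

```r
lab <- label_cells(co, c("ACE", "BFG_T148C"))
lab
#> <cell labels> ACE x BFG_T148C, threshold T = 1.0000 (0 excluded)
#>   cell cases controls label
#>  DD:TT     4        2  high
#>  DD:CT    14        8  high
#>  DD:CC    22       15  high
#>  ID:TT     9       17   low
#>  ID:CT    43       54   low
#>  ID:CC    97       54  high
#>  II:TT     8        9   low
#>  II:CT    42       60   low
#>  II:CC    61       81   low
odds_ratio(classify_individuals(co, lab))
#> OR = 2.351 (95% CI 1.669-3.313), p = 1.029e-06
```

The planted cells DD:CC, DD:CT and ID:CC are labeled high risk (DD:TT
and its 6 individuals is a sparse-cell artifact typical of real MDR
grids).  The crude OR of the fitted recode is 2.35; adjusting for age,
sex, family history, hypertension and diabetes:

```r
rec <- risk_recode(co, lab)
fit_logistic(co$data$phenotype,
             cbind(data.frame(high_risk = rec$indicator),
                   co$data[, c("age", "sex", "family_history_IS",
                               "hypertension", "diabetes")]))
#> logistic fit: n = 600, logLik = -294.80, 5 IRLS iterations
#>               term estimate    se     or ci_lower ci_upper p_value
#>        (Intercept)   -5.641 0.541  0.004    0.001    0.010       0
#>          high_risk    1.076 0.218  2.932    1.914    4.492       0
#>          ...
```

The adjusted OR for the high-risk combination is 2.93 (95% CI
1.91–4.49); its interval covers the planted 2.5.  `run_pipeline()` +
`report_render()` execute all stages (Hardy–Weinberg, single-locus
screen, MDR with permutation test, risk recode, crude and adjusted ORs
per subtype stratum) and write a TSV report bundle;
`inst/cli/mdrpipe.R` exposes `simulate`, `hwe`, `assoc`, `mdr` and
`run` subcommands.

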