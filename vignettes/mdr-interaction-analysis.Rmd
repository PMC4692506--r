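---
title: "Detecting gene-gene interactions with MDR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-gene interactions with MDR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrpipe)
```

## The problem

Candidate-gene studies of complex diseases such as ischemic stroke often
find no single-locus association even when the candidate loci are well
supported: a locus may contribute to risk only through its interaction
with another locus, with main effects too small to detect.  `mdrpipe`
implements the standard analysis pipeline for this situation in a
case-control design: single-locus screening (Hardy-Weinberg and
genotype chi-square tests with Bonferroni correction), an exhaustive
multifactor dimensionality reduction (MDR) search for multi-locus risk
patterns, and crude plus covariate-adjusted logistic odds ratios for
the risk combination the search selects.

The default locus panel is the six-marker stroke panel — ACE I/D,
beta-fibrinogen T148C and A455G, MTHFR C677T, ApoE epsilon-2/3/4 (six
genotypes) and eNOS G894T — but every function takes arbitrary
`locus()` definitions with two or three alleles.

## The MDR procedure

MDR is nonparametric and model-free.  For a combination of $k$ loci
(a grid of $3^k$ cells for biallelic markers), each cell $c$ with
$a_c$ cases and $b_c$ controls is labeled **high risk** when

$$ a_c / b_c \;\ge\; T, \qquad T = n_{\text{cases}} / n_{\text{controls}} $$

computed on the labeling (training) data, and **low risk** otherwise.
The $k$-locus genotype is thereby collapsed to one binary attribute.
Its quality is measured by balanced accuracy,
$(\text{sensitivity} + \text{specificity})/2$, which is insensitive to
the case:control imbalance.

Numerical conventions, chosen once and applied everywhere:

* a cell exactly at the threshold is high risk (the rule is a closed
  half-line, and the integer comparison $a_c n_{\text{controls}} \ge
  b_c n_{\text{cases}}$ avoids floating-point ratios entirely);
* a cell with cases but no controls has infinite ratio and is high;
* a cell with no training individuals is labeled `empty` and scored
  low risk if an out-of-sample individual falls into it — conservative
  toward the null — with a counted warning;
* individuals missing a genotype at any locus of the combination are
  excluded from that combination only (complete-case per combination);
* if a phenotype class is absent from an evaluation set its rate is
  defined as 0.5.

## Cross-validation, consistency and significance

Evaluation uses stratified 10-fold cross-validation: within each
phenotype class a seeded permutation is dealt into folds differing by
at most one in size.  For each fold, labels are fit on the other nine
tenths and balanced accuracy is measured on the held-out tenth;
*prediction error* is one minus the mean testing balanced accuracy.

The exhaustive search evaluates every locus combination of each
requested order (orders 1-4 by default; six loci give at most
$\binom{6}{3}=20$ combinations per order, so exhaustive search is
cheap).  Within each fold, the combination with the highest *training*
balanced accuracy is the fold winner; ties break toward the
lexicographically first combination by locus index so the search is
deterministic.  A combination's **CV consistency** is the number of
folds it wins; the model reported for an order is the combination
winning the most folds, and the overall best model maximizes CV
consistency with ties broken by minimum prediction error, then by the
lower order.  The classical presentation describes selection by
consistency and prediction error but does not pin down the within-fold
winner rule; the definition above is explicit, deterministic and
configurable through the search interface.

Two significance measures accompany the best model:

* **Sign test**: an exact one-sided binomial test on the number of
  folds whose testing balanced accuracy exceeds 0.5 (folds at exactly
  0.5 count as failures).  The original MDR software prints a different
  (undocumented) statistic in its "sign test" column; this package
  provides the exact binomial version only.
* **Permutation test**: the phenotype labels are shuffled `n_perm`
  times (default 1000), the *entire* search is re-run on each shuffle
  — fold plans re-drawn from the same fold seed, since stratification
  depends on the labels — and the add-one estimator
  $p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(n_\text{perm}+1)$
  is reported, which cannot return 0.  Genotype-to-cell indices are
  computed once and reused across shuffles, which keeps 1000 full
  re-searches inexpensive.

## Odds ratios and covariate adjustment

The selected model's labels, fit on the full data, recode each
individual as high or low risk.  The crude odds ratio comes from the
2x2 risk-by-status table with a Woolf (log-normal) confidence interval,
applying the Haldane-Anscombe +0.5 correction only when a cell is zero
(and flagging it).  The adjusted odds ratio is the exponentiated
coefficient of the risk indicator in a logistic regression that also
enters age (linear, in years), sex, family history of ischemic stroke,
hypertension history and diabetes history; age in categories is a
configuration choice left to the caller, and Wald rather than
likelihood-ratio p-values are reported to match the OR + CI
presentation.  The fit itself is iteratively reweighted least squares
via `stats::glm`; the wrapper adds the OR-scale summary, a
quasi-separation check (a non-intercept coefficient beyond 15 on the
log-odds scale is reported as an error naming the predictor) and a
rank-deficiency error for aliased designs.  Subtype-stratified
analyses (e.g. large-artery and small-artery stroke) use the subtype's
cases against *all* controls; strata below a configurable minimum case
count (default 30) are skipped with a warning because cell counts
become too sparse for stable labeling.

## The synthetic cohort generator

Because per-individual data from published studies are rarely
redistributable, every stage is testable against `generate_cohort()`,
which emulates the study conditions:

* **Genotypes**: independent loci in Hardy-Weinberg proportions, with
  control-population allele frequencies obtained by gene counting from
  the published control genotype distribution (e.g. ACE D =
  $479/1548 \approx 0.309$; ApoE epsilon-2 $= 121/1548$).
* **Covariates**: age truncated-normal on [18, 100] (control mean 51.5,
  SD 16.9), sex, hypertension, diabetes and family history as
  Bernoulli draws, mutually independent given disease status.
* **Disease**: a logistic penetrance model
  $\operatorname{logit} P(\text{case}) = \beta_0 + \beta_{\text{int}}
  \mathbf{1}[\text{cell} \in \text{high set}] + X^\top\beta_{\text{cov}}$,
  with the planted high-risk set defaulting to ACE DD:CC, DD:CT and
  ID:CC on the (ACE, beta-FG T148C) pair at odds ratio 1.57, and
  optional per-locus additive main effects defaulting to zero (pure
  epistasis — the marginal structure of the real interaction is not
  published, and zero main effects is the hardest case for the
  single-locus screen, matching the observed pattern of no single-locus
  significance).
* **Sampling**: a population is simulated prospectively and exactly
  `n_cases` cases (default 712) and `n_controls` controls (default
  774) are drawn from it.  Case-control sampling shifts only the
  intercept of a logistic model, so the planted odds ratios remain the
  estimands of the downstream logistic fits.

Calibration deserves a note.  At the default 10% population case
fraction the disease is not rare, so the observed control group is
*not* the population, and closed-form "log odds ratio of the two
prevalences" coefficients would under-enrich the cases.  The generator
therefore solves for three parameter sets jointly on a fixed 50,000-row
calibration sample: the intercept (Newton, to the target case
fraction), the population covariate parameters (so control-conditional
marginals match the configured control column) and the enrichment
coefficients (so case-conditional marginals match the case column),
using case-/control-probability-weighted marginals and about twenty
fixed-point steps.  The calibration sample has its own fixed seed:
penetrance parameters are a function of the scientific configuration
alone, so replicate cohorts under different master seeds share the same
planted truth, and the calibration is cached per configuration.

A consequence worth knowing: the *crude* odds ratio of the planted
indicator is attenuated relative to $\exp(\beta_{\text{int}})$ because
odds ratios are non-collapsible over independent risk factors; the
covariate-*adjusted* logistic OR is the quantity that recovers the
planted value, and the recovery tests are written accordingly.

What the generator does **not** emulate: linkage disequilibrium between
loci (simulated in linkage equilibrium; none is published for this
panel), haplotype phase, population stratification, the smaller age SD
observed in cases (a single linear age term cannot match both moments),
genotype-covariate dependence, and missing data.  Passing tests
therefore demonstrate correctness of the machinery and calibration of
the tests under these idealized conditions, not robustness to LD or
structure in real cohorts.

`null_shuffle()` permutes the case/control labels (carrying subtype
labels with them) for null-calibration experiments.

## Seeds and determinism

Every random stage — generation chunks, subtype assignment, fold plans,
permutation shuffles — draws from a seed derived from one master seed
via a fixed affine map, and each function restores the caller's RNG
state.  Identical cohort + configuration + seed reproduce every number
in a pipeline report exactly.

## Verification strategy and problem sizes

The test suite checks the engine at three levels, with sizes chosen to
keep the default run within a few minutes:

* **Exact oracle equivalence**: on 100 random cohorts of up to 30
  individuals and 2-3 loci, the vectorized engine's labels,
  cross-validated accuracies, fold winners, CV consistencies and best
  models agree *exactly* with an independent brute-force implementation
  that enumerates cells, individuals and folds by literal loops.
* **Published-table recomputation**: the printed single-locus tables
  recompute to their printed p-values with the uncorrected Pearson test
  (which is how the choice of no continuity correction was verified),
  and the printed risk-combination 2x2 yields its odds ratio 1.580
  identically by cross-product and by logistic regression.  One
  printed case column contains a typo (its entries do not sum to the
  case total); the affected count is reconstructed from the column
  total, which reproduces the printed p-value.
* **Statistical calibration**: planted-pair recovery (50 seeds at
  2,000/2,000 and interaction OR 3.0: the pair must win order 2 in at
  least 80% of seeds, and the adjusted CI must cover the planted OR at
  the nominal rate), and null calibration (200 label-shuffled cohorts
  of 100/100: permutation rejection at the 5% level within binomial
  tolerance, fixed-pair testing accuracy at 0.5).

## Limitations

Beyond the generator's idealizations listed above: no generalized or
model-based MDR variants, no covariate adjustment inside the MDR search
itself (covariates enter only the logistic stage), no exact
Hardy-Weinberg test or Firth-corrected logistic regression, and no
imputation — missingness is handled by complete-case exclusion per
analysis.  Six categorical loci keep the exhaustive search trivial;
the engine is not designed for genome-wide marker sets.
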