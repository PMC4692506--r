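# Small cohort builders used across the test files.

# Build a cohort from explicit phenotype + genotype vectors; loci are the
# named genotype arguments (subset of the default panel).  Covariates are
# filled deterministically with enough variation for logistic fits.
mk_cohort <- function(phenotype, ..., subtype = NULL) {
  g <- list(...)
  stopifnot(length(g) >= 1, !is.null(names(g)))
  loci <- default_loci()[names(g)]
  n <- length(phenotype)
  d <- data.frame(
    id = sprintf("I%04d", seq_len(n)),
    phenotype = as.integer(phenotype),
    subtype = if (is.null(subtype))
      ifelse(phenotype == 1L, "LAA", "control") else subtype,
    age = 40 + (seq_len(n) %% 35),
    sex = rep_len(c("male", "female"), n),
    family_history_IS = rep_len(c(0L, 0L, 0L, 1L), n),
    hypertension = rep_len(c(0L, 1L, 1L), n),
    diabetes = rep_len(c(0L, 0L, 1L), n),
    stringsAsFactors = FALSE)
  for (nm in names(g)) d[[nm]] <- g[[nm]]
  cohort(d, loci)
}

# Expand per-cell case/control counts over a two-locus grid into a cohort.
# `cells` are "g1:g2" labels; counts are named by cell.
cohort_from_cells <- function(case_counts, control_counts,
                              loci = c("ACE", "BFG_T148C")) {
  split2 <- function(cells) do.call(rbind, strsplit(cells, ":", fixed = TRUE))
  gc <- split2(rep(names(case_counts), case_counts))
  gt <- split2(rep(names(control_counts), control_counts))
  phen <- c(rep(1L, sum(case_counts)), rep(0L, sum(control_counts)))
  args <- list(phenotype = phen)
  args[[loci[1]]] <- c(gc[, 1], gt[, 1])
  args[[loci[2]]] <- c(gc[, 2], gt[, 2])
  do.call(mk_cohort, args)
}

# Random small cohort for oracle-equivalence checks: 12-30 individuals,
# 2-3 loci, occasional missing genotypes, both classes >= k members.
random_tiny_cohort <- function(seed, k = 3L) {
  set.seed(seed)
  panel <- default_loci()
  n_loci <- sample(2:3, 1)
  loci <- panel[sample(names(panel), n_loci)]
  repeat {
    n <- sample(12:30, 1)
    phen <- sample(c(0L, 1L), n, replace = TRUE)
    if (min(sum(phen), n - sum(phen)) >= k) break
  }
  args <- list(phenotype = phen)
  for (nm in names(loci)) {
    g <- sample(loci[[nm]]$categories, n, replace = TRUE)
    g[runif(n) < 0.05] <- NA
    args[[nm]] <- g
  }
  do.call(mk_cohort, args)
}

# Table of observed single-locus genotype counts used as printed-data
# fixtures (controls and overall cases; ACE I/D and beta-FG T148C).
printed_ace <- function()
  matrix(c(74, 356, 282, 64, 351, 359), ncol = 2,
         dimnames = list(c("DD", "ID", "II"), c("case", "control")))

# overall-case TT reconstructed as 712 - 243 - 413 = 56 (the printed
# column does not sum to the case total; CT and CC do)
printed_bfg_t148c <- function()
  matrix(c(56, 243, 413, 77, 301, 396), ncol = 2,
         dimnames = list(c("TT", "CT", "CC"), c("case", "control")))

printed_risk_2x2 <- function()
  matrix(c(288, 424, 233, 542), 2,
         dimnames = list(c("high", "low"), c("case", "control")))
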