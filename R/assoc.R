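new_test_result <- function(statistic, df, n_used, warnings = character()) {
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 n_used = n_used, warnings = warnings),
            class = "mdr_test")
}

#' @export
print.mdr_test <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n_used))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Estimates allele frequencies by gene counting from the observed
#' genotype counts, forms the Hardy-Weinberg expected genotype counts,
#' and returns the goodness-of-fit chi-square.  Degrees of freedom are
#' the number of genotype categories minus the number of alleles: 1 for
#' a biallelic marker, 3 for a three-allele marker such as ApoE.
#'
#' @param counts Named (or locus-ordered) vector of genotype counts
#'   covering the locus categories.
#' @param loc The [locus()] the counts belong to.
#' @return An `mdr_test` with fields `statistic`, `df`, `p_value`,
#'   `n_used`, `warnings`.
#' @examples
#' hwe_chisq(c(DD = 64, ID = 351, II = 359), default_loci()$ACE)
#' @export
hwe_chisq <- function(counts, loc) {
  stopifnot(inherits(loc, "mdr_locus"))
  if (!is.null(names(counts))) {
    missing_cat <- setdiff(loc$categories, names(counts))
    counts[missing_cat] <- 0L
    counts <- counts[loc$categories]
  } else if (length(counts) != length(loc$categories)) {
    stop("counts must cover every genotype category", call. = FALSE)
  }
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n <= 0) stop("no observations", call. = FALSE)
  allele_n <- vapply(loc$alleles,
                     function(a) sum(allele_dosage(loc, a) * counts), 0)
  observed_alleles <- loc$alleles[allele_n > 0]
  if (length(observed_alleles) < 2L)
    stop(sprintf("locus %s is monomorphic in these counts; HWE test undefined",
                 loc$name), call. = FALSE)
  p <- allele_n / (2 * n)
  expected <- vapply(loc$genotypes, function(pair) {
    if (pair[1] == pair[2]) n * p[pair[1]]^2 else 2 * n * p[pair[1]] * p[pair[2]]
  }, 0)
  keep <- expected > 0
  stat <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep) - length(observed_alleles)
  warn <- if (any(expected[keep] < 5))
    "expected count < 5 in at least one genotype class" else character()
  new_test_result(stat, df, as.integer(n), warn)
}

#' Pearson chi-square test of genotype-status independence
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on an
#' r x 2 genotype-by-status table, the test used for single-locus
#' case-control comparison.  Rows with zero margin are an error; an
#' expected cell count below 5 raises a warning field.
#'
#' @param tab An [genotype_table()] result or a counts matrix with >= 2
#'   rows and 2 columns.
#' @return An `mdr_test`.
#' @export
chisq_independence <- function(tab) {
  m <- unclass(tab)
  attributes(m)[c("n_excluded", "loci", "stratum")] <- NULL
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) != 2L)
    stop("need a table with >= 2 rows and exactly 2 columns", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin; test undefined", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  warn <- if (any(ct$expected < 5))
    "expected count < 5 in at least one cell" else character()
  new_test_result(unname(ct$statistic), unname(ct$parameter),
                  as.integer(sum(m)), warn)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`, the per-test threshold; report significance as
#'   `p < bonferroni_threshold(alpha, m)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' Cross-product odds ratio of a 2x2 exposure-by-status table (rows:
#' exposed/unexposed, columns: case/control), with the Woolf log-normal
#' confidence interval, SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d).  If
#' any cell is zero the Haldane-Anscombe correction (+0.5 to every cell)
#' is applied and flagged; a zero row or column margin is an error.
#'
#' @param tab 2x2 counts matrix (or `mdr_table`).
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `mdr_or`: `or`, `ci` (length 2), `log_or`,
#'   `se_log_or`, `p_value` (Wald), `corrected` flag.
#' @examples
#' odds_ratio(matrix(c(288, 424, 233, 542), 2,
#'                   dimnames = list(c("high", "low"), c("case", "control"))))
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  m <- as.matrix(unclass(tab))[, , drop = FALSE]
  attributes(m)[c("n_excluded", "loci", "stratum")] <- NULL
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin; odds ratio undefined", call. = FALSE)
  corrected <- any(m == 0)
  mm <- if (corrected) m + 0.5 else m
  log_or <- log(mm[1, 1]) + log(mm[2, 2]) - log(mm[1, 2]) - log(mm[2, 1])
  se <- sqrt(sum(1 / mm))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = exp(log_or),
                 ci = exp(log_or + c(-1, 1) * z * se),
                 log_or = log_or, se_log_or = se,
                 p_value = 2 * stats::pnorm(-abs(log_or / se)),
                 corrected = corrected),
            class = "mdr_or")
}

#' @export
print.mdr_or <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f), p = %.4g%s\n",
              x$or, x$ci[1], x$ci[2], x$p_value,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}
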