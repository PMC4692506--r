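#' Pipeline configuration
#'
#' Settings for the end-to-end analysis: which loci and subtype strata
#' to analyze, the covariates entering the adjusted logistic model, MDR
#' search settings, and one master seed from which the fold and
#' permutation streams are derived.
#'
#' @param loci Locus names to analyze (default: all cohort loci).
#' @param strata Subtype strata analyzed beside the overall comparison.
#'   Strata with fewer than `min_stratum_cases` cases are skipped with a
#'   warning (small subtypes cannot support the analysis).
#' @param covariates Covariate columns for the adjusted model.
#' @param orders MDR interaction orders searched.
#' @param k Cross-validation folds.
#' @param n_perm Permutations for the MDR permutation test.
#' @param min_stratum_cases Minimum cases for a stratum to be analyzed.
#' @param alpha Family-wise level for the Bonferroni-corrected
#'   single-locus screen.
#' @param seed Master seed.
#' @return List of class `mdr_pipeline_config`.
#' @export
pipeline_config <- function(loci = NULL, strata = c("LAA", "SAO"),
                            covariates = COVARIATE_COLS,
                            orders = 1:4, k = 10L, n_perm = 1000L,
                            min_stratum_cases = 30L, alpha = 0.05,
                            seed = 20151228) {
  structure(list(loci = loci, strata = strata, covariates = covariates,
                 orders = orders, k = as.integer(k), n_perm = as.integer(n_perm),
                 min_stratum_cases = as.integer(min_stratum_cases),
                 alpha = alpha, seed = seed),
            class = "mdr_pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full interaction-analysis pipeline
#'
#' Executes, in order: Hardy-Weinberg tests on the controls per locus;
#' single-locus genotype chi-square per locus for the overall comparison
#' and each analyzable subtype stratum (with the Bonferroni-corrected
#' significance threshold); the exhaustive MDR search with
#' cross-validation and permutation test; full-data cell labeling of the
#' best model; per-individual high/low risk recoding; and crude plus
#' covariate-adjusted logistic odds ratios per stratum.  Every number in
#' the report is recomputable from the cohort, the configuration and the
#' master seed.
#'
#' @param x An `mdr_cohort`, or a path readable by [read_cohort()].
#' @param config A [pipeline_config()].
#' @return Object of class `mdr_report`.
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  if (is.character(x)) x <- stage("read_cohort", read_cohort(x))
  stopifnot(inherits(x, "mdr_cohort"), inherits(config, "mdr_pipeline_config"))
  loci <- if (is.null(config$loci)) names(x$loci) else config$loci
  d <- x$data

  strata <- character()
  for (s in config$strata) {
    n_s <- sum(d$phenotype == 1L & !is.na(d$subtype) & d$subtype == s)
    if (n_s >= config$min_stratum_cases) strata <- c(strata, s)
    else warning(sprintf("stratum %s skipped: only %d cases (< %d)",
                         s, n_s, config$min_stratum_cases))
  }

  hwe <- stage("hwe", {
    do.call(rbind, lapply(loci, function(nm) {
      cnt <- table(factor(d[[nm]][d$phenotype == 0L],
                          levels = x$loci[[nm]]$categories))
      r <- hwe_chisq(as.vector(cnt), x$loci[[nm]])
      data.frame(locus = nm, statistic = r$statistic, df = r$df,
                 p_value = r$p_value, n_controls = r$n_used,
                 stringsAsFactors = FALSE)
    }))
  })

  thr <- bonferroni_threshold(config$alpha, length(loci))
  single_locus <- stage("single_locus", {
    do.call(rbind, lapply(c("overall", strata), function(s)
      do.call(rbind, lapply(loci, function(nm) {
        tab <- genotype_table(x, nm, stratum = s)
        # genotype categories absent from this comparison carry no
        # information; drop them rather than fail the whole stage
        m <- unclass(tab)[rowSums(unclass(tab)) > 0, , drop = FALSE]
        r <- chisq_independence(m)
        data.frame(stratum = s, locus = nm, statistic = r$statistic,
                   df = r$df, p_value = r$p_value,
                   bonferroni_significant = r$p_value < thr,
                   n_used = r$n_used, stringsAsFactors = FALSE)
      }))))
  })

  perm <- stage("mdr", permutation_test(
    x, orders = config$orders, folds_seed = derive_seed(config$seed, 1L),
    n_perm = config$n_perm, seed = derive_seed(config$seed, 2L),
    k = config$k, loci = loci))
  search <- perm$observed
  best <- search$best

  labels <- stage("label_cells", label_cells(x, best$combo))

  rec_full <- stage("risk_recode", risk_recode(x, labels))
  risk <- stage("risk_tables", {
    lapply(stats::setNames(nm = c("overall", strata)), function(s) {
      tab <- classify_individuals(x, labels, stratum = s)
      crude <- odds_ratio(tab)
      keep <- !is.na(rec_full$indicator)
      if (!identical(s, "overall"))
        keep <- keep & (d$phenotype == 0L |
                          (!is.na(d$subtype) & d$subtype == s))
      adj <- fit_logistic(
        d$phenotype[keep],
        cbind(data.frame(high_risk = rec_full$indicator[keep]),
              d[keep, config$covariates, drop = FALSE]))
      list(stratum = s, table = tab, crude = crude, adjusted = adj)
    })
  })

  structure(list(hwe = hwe, single_locus = single_locus,
                 bonferroni_threshold = thr,
                 search = search, permutation_p = perm$p_value,
                 labels = labels, risk = risk,
                 provenance = list(seed = config$seed,
                                   folds_seed = derive_seed(config$seed, 1L),
                                   perm_seed = derive_seed(config$seed, 2L),
                                   orders = config$orders, k = config$k,
                                   n_perm = config$n_perm,
                                   n_cases = n_cases(x), n_controls = n_controls(x),
                                   strata = strata)),
            class = "mdr_report")
}

adjusted_or_row <- function(block) {
  co <- block$adjusted$coefficients
  i <- match("high_risk", co$term)
  data.frame(stratum = block$stratum,
             high_case = block$table["high", "case"],
             low_case = block$table["low", "case"],
             high_control = block$table["high", "control"],
             low_control = block$table["low", "control"],
             crude_or = block$crude$or,
             crude_ci_lower = block$crude$ci[1], crude_ci_upper = block$crude$ci[2],
             adjusted_or = co$or[i], adj_ci_lower = co$ci_lower[i],
             adj_ci_upper = co$ci_upper[i], adj_p = co$p_value[i],
             stringsAsFactors = FALSE)
}

#' @export
print.mdr_report <- function(x, ...) {
  cat("== Hardy-Weinberg (controls) ==\n")
  print(x$hwe, row.names = FALSE)
  cat(sprintf("\n== Single-locus chi-square (Bonferroni threshold %.4g) ==\n",
              x$bonferroni_threshold))
  print(x$single_locus, row.names = FALSE)
  cat("\n== MDR search ==\n")
  print(x$search)
  cat(sprintf("permutation p = %.4g (%d permutations)\n",
              x$permutation_p, x$provenance$n_perm))
  cat("\n== Best-model cell labels ==\n")
  print(x$labels)
  cat("\n== Risk-combination odds ratios ==\n")
  print(do.call(rbind, lapply(x$risk, adjusted_or_row)), row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Renders an [run_pipeline()] report as a TSV bundle (one file per
#' block: Hardy-Weinberg, single-locus, MDR models, cell labels, risk
#' tables) plus a human-readable `report.txt` and a `provenance.tsv`
#' key-value file with the seeds and settings.  Re-rendering is
#' idempotent.
#'
#' @param report An `mdr_report`.
#' @param dir Output directory (created if needed).
#' @param format Only `"tsv"` is defined.
#' @return Invisibly, the vector of files written.
#' @export
report_render <- function(report, dir, format = "tsv") {
  stopifnot(inherits(report, "mdr_report"))
  if (!identical(format, "tsv")) stop("unknown format: ", format, call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    file.path(dir, f)
  }
  models <- do.call(rbind, lapply(report$search$per_order, function(m)
    data.frame(order = length(m$combo),
               best_model = paste(m$combo, collapse = ":"),
               testing_balanced_accuracy = m$mean_test_ba,
               cv_consistency = sprintf("%d/%d", m$cv_consistency,
                                        length(m$test_ba)),
               sign_test_p = m$sign_p, stringsAsFactors = FALSE)))
  risk <- do.call(rbind, lapply(report$risk, adjusted_or_row))
  prov <- report$provenance
  prov_df <- data.frame(key = names(prov),
                        value = vapply(prov, function(v)
                          paste(format(v, scientific = FALSE), collapse = ","), ""))
  files <- c(w(report$hwe, "hwe.tsv"),
             w(report$single_locus, "single_locus.tsv"),
             w(models, "mdr_models.tsv"),
             w(report$labels$cells, "cell_labels.tsv"),
             w(risk, "risk_tables.tsv"),
             w(prov_df, "provenance.tsv"))
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink())
  print(report)
  sink(); on.exit()
  invisible(c(files, txt))
}
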