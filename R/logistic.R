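#' Logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic regression fitted by iteratively
#' reweighted least squares, reported on the odds-ratio scale: one OR,
#' Wald 95\% CI (`exp(b +/- 1.96 SE)`) and Wald p-value per coefficient.
#' Categorical predictors are dummy-coded against their first level.
#' Quasi-complete separation (a coefficient running away while the
#' deviance still falls) and rank-deficient designs are reported as
#' errors naming the offending predictor.
#'
#' @param response Binary 0/1 vector (both classes present).
#' @param predictors data.frame of predictors (numeric, or
#'   factor/character for dummy coding); row order matches `response`.
#' @param conf_level Confidence level for the Wald intervals.
#' @param epsilon Relative deviance-change convergence tolerance.
#' @param maxit Maximum IRLS iterations.
#' @return Object of class `mdr_logistic`: data.frame `coefficients`
#'   (term, estimate, se, or, ci_lower, ci_upper, p_value), plus
#'   `log_likelihood`, `iterations`, `converged`, `n_used`.
#' @export
fit_logistic <- function(response, predictors, conf_level = 0.95,
                         epsilon = 1e-10, maxit = 100L) {
  response <- as.numeric(response)
  stopifnot(all(response %in% c(0, 1)))
  if (length(unique(response)) < 2L)
    stop("response must contain both classes", call. = FALSE)
  predictors <- as.data.frame(predictors, stringsAsFactors = FALSE)
  stopifnot(nrow(predictors) == length(response))
  for (j in names(predictors))
    if (is.character(predictors[[j]])) predictors[[j]] <- factor(predictors[[j]])
  dat <- cbind(.y = response, predictors)
  complete <- stats::complete.cases(dat)
  dat <- dat[complete, , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("rank-deficient design; aliased term(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  if (nrow(dat) <= length(beta))
    stop("fewer observations than parameters", call. = FALSE)
  runaway <- abs(beta[-1]) > 15
  if (any(runaway))
    stop("apparent separation; coefficient diverging for: ",
         paste(names(beta[-1])[runaway], collapse = ", "), call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), or = exp(unname(beta)),
                      ci_lower = exp(unname(beta) - z * unname(se)),
                      ci_upper = exp(unname(beta) + z * unname(se)),
                      p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 iterations = fit$iter, converged = fit$converged,
                 n_used = nrow(dat), n_dropped = sum(!complete)),
            class = "mdr_logistic")
}

#' @export
print.mdr_logistic <- function(x, digits = 3, ...) {
  cat(sprintf("logistic fit: n = %d, logLik = %.2f, %d IRLS iterations%s\n",
              x$n_used, x$log_likelihood, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(cbind(x$coefficients[1], round(x$coefficients[-1], digits)),
        row.names = FALSE)
  invisible(x)
}

#' Single-locus logistic association
#'
#' Fits case-control status on one locus under a chosen genetic coding.
#' The default codominant coding dummy-codes each non-reference genotype
#' against the reference, yielding one OR + CI per genotype; dominant
#' and recessive collapse to carrier/non-carrier of the risk allele
#' (the allele of the last genotype category), and additive codes the
#' risk-allele dosage 0/1/2 as a linear term.
#'
#' @param x An `mdr_cohort`.
#' @param locus_name Name of the locus to test.
#' @param reference Reference genotype category (codominant coding);
#'   defaults to the first category of the locus.
#' @param coding `"codominant"`, `"dominant"`, `"recessive"` or
#'   `"additive"`.
#' @param covariates Optional character vector of covariate columns to
#'   adjust for.
#' @return An `mdr_logistic` fit.
#' @export
univariate_locus_logistic <- function(x, locus_name,
                                      reference = NULL,
                                      coding = c("codominant", "dominant",
                                                 "recessive", "additive"),
                                      covariates = NULL) {
  stopifnot(inherits(x, "mdr_cohort"))
  coding <- match.arg(coding)
  loc <- x$loci[[locus_name]]
  if (is.null(loc)) stop("unknown locus: ", locus_name, call. = FALSE)
  g <- x$data[[locus_name]]
  keep <- !is.na(g)
  g <- g[keep]
  y <- x$data$phenotype[keep]
  if (coding == "codominant") {
    if (is.null(reference)) reference <- loc$categories[1]
    if (!reference %in% loc$categories)
      stop("reference genotype not a category of ", locus_name, call. = FALSE)
    seen <- intersect(loc$categories, unique(g))
    dropped <- setdiff(setdiff(loc$categories, reference), seen)
    if (length(dropped))
      warning("unobserved genotype term(s) dropped: ",
              paste(dropped, collapse = ", "))
    pred <- data.frame(genotype = factor(
      g, levels = c(reference, setdiff(seen, reference))))
  } else {
    if (loc$allele_arity != 2L)
      stop(coding, " coding requires a biallelic locus", call. = FALSE)
    risk <- loc$genotypes[[length(loc$genotypes)]][1]
    dose <- allele_dosage(loc, risk)[g]
    pred <- switch(coding,
      dominant  = data.frame(carrier = as.integer(dose >= 1)),
      recessive = data.frame(homozygote = as.integer(dose == 2)),
      additive  = data.frame(dose = as.numeric(dose)))
  }
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(x$data))
    if (length(miss))
      stop("unknown covariate(s): ", paste(miss, collapse = ", "), call. = FALSE)
    pred <- cbind(pred, x$data[keep, covariates, drop = FALSE])
  }
  fit_logistic(y, pred)
}
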