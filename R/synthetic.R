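# Control-group genotype counts used to calibrate the generator's
# allele frequencies by gene counting (774 controls).
CONTROL_GENOTYPE_COUNTS <- list(
  ACE         = c(DD = 64, ID = 351, II = 359),
  BFG_T148C   = c(TT = 77, CT = 301, CC = 396),
  BFG_A455G   = c(AA = 62, GA = 302, GG = 410),
  MTHFR_C677T = c(TT = 52, CT = 299, CC = 423),
  APOE        = c(e2e2 = 3, e2e3 = 107, e2e4 = 8,
                  e3e3 = 535, e3e4 = 113, e4e4 = 8),
  ENOS_G894T  = c(TT = 12, GT = 143, GG = 619))

# Case/control subtype mix of the study population (712 cases)
SUBTYPE_COUNTS <- c(LAA = 327, SAO = 221, CE = 54, SOE = 52, SUE = 58)

allele_freqs_from_counts <- function(loc, counts) {
  counts <- counts[loc$categories]
  n2 <- 2 * sum(counts)
  p <- vapply(loc$alleles, function(a) sum(allele_dosage(loc, a) * counts) / n2, 0)
  names(p) <- loc$alleles
  p
}

hwe_genotype_probs <- function(loc, p) {
  vapply(loc$genotypes, function(pair) {
    if (pair[1] == pair[2]) p[pair[1]]^2 else 2 * p[pair[1]] * p[pair[2]]
  }, 0)
}

#' Default synthetic-cohort generator configuration
#'
#' The defaults emulate the study conditions: 712 cases and 774
#' controls; control-population allele frequencies obtained by gene
#' counting from the observed control genotype distribution (e.g. ACE D
#' = 479/1548); covariate marginals (age, sex, hypertension, diabetes,
#' family history) matching the observed control and case groups; and a
#' planted two-locus interaction on the (ACE I/D, beta-FG T148C) pair
#' whose high-risk cells are DD:CC, DD:CT and ID:CC with odds ratio 1.57.
#' Disease is assigned by a logistic penetrance model; its intercept is
#' calibrated to a population case fraction of 10\% and its covariate
#' terms are calibrated so the simulated control and case groups
#' reproduce the configured marginals (see [generate_cohort()]).
#'
#' @param n_cases,n_controls Sample sizes to draw (defaults 712 / 774).
#' @param interaction_or Odds ratio of the planted high-risk-combination
#'   indicator (default 1.57); 1 plants no effect.
#' @param planted_loci Length-2 locus-name vector carrying the
#'   interaction.
#' @param high_cells Cell labels (`"g1:g2"`) forming the high-risk set.
#' @param main_effect_or Named per-locus odds ratio per copy of the
#'   locus's first-listed allele; default none (pure epistasis).
#' @param target_case_fraction Population case fraction the intercept is
#'   calibrated to (default 0.10).
#' @param seed Master seed; every random stream derives from it.
#' @param loci Locus definitions (default six-locus panel).
#' @return Object of class `mdr_gen_config`.
#' @export
default_config <- function(n_cases = 712L, n_controls = 774L,
                           interaction_or = 1.57,
                           planted_loci = c("ACE", "BFG_T148C"),
                           high_cells = c("DD:CC", "DD:CT", "ID:CC"),
                           main_effect_or = NULL,
                           target_case_fraction = 0.10,
                           seed = 20151228, loci = default_loci()) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, interaction_or > 0,
            length(planted_loci) == 2L, all(planted_loci %in% names(loci)),
            target_case_fraction > 0, target_case_fraction < 1)
  freqs <- lapply(names(loci), function(nm)
    allele_freqs_from_counts(loci[[nm]], CONTROL_GENOTYPE_COUNTS[[nm]]))
  names(freqs) <- names(loci)
  for (p in freqs) stopifnot(all(p > 0), all(p < 1), abs(sum(p) - 1) < 1e-12)
  main <- stats::setNames(numeric(length(loci)), names(loci))
  if (!is.null(main_effect_or)) {
    stopifnot(all(names(main_effect_or) %in% names(loci)), all(main_effect_or > 0))
    main[names(main_effect_or)] <- log(main_effect_or)
  }
  # covariates: the population follows the control marginals; the
  # case-enrichment coefficients are calibrated at generation time so
  # the case-conditional marginals match the observed case group
  cov <- list(
    age = list(mean = 51.5, sd = 16.9, case_mean = 65.2, range = c(18, 100)),
    male = list(p = 0.54, case_p = 0.653),
    hypertension = list(p = 0.19, case_p = 0.573),
    diabetes = list(p = 0.071, case_p = 0.202),
    family_history_IS = list(p = 0.006, case_p = 0.056))
  cfg <- structure(list(n_cases = as.integer(n_cases),
                        n_controls = as.integer(n_controls),
                        loci = loci, allele_freqs = freqs,
                        planted = list(loci = planted_loci,
                                       high_cells = high_cells,
                                       log_or = log(interaction_or)),
                        main_effects = main, covariates = cov,
                        target_case_fraction = target_case_fraction,
                        subtype_probs = SUBTYPE_COUNTS / sum(SUBTYPE_COUNTS),
                        seed = seed),
                   class = "mdr_gen_config")
  cfg
}

#' @export
print.mdr_gen_config <- function(x, ...) {
  cat(sprintf(paste0("<generator config> %d cases / %d controls; planted %s ",
                     "interaction OR %.3f on {%s}; seed %d\n"),
              x$n_cases, x$n_controls, paste(x$planted$loci, collapse = " x "),
              exp(x$planted$log_or), paste(x$planted$high_cells, collapse = ", "),
              x$seed))
  invisible(x)
}

BINARY_COVS <- c("male", "hypertension", "diabetes", "family_history_IS")

# per-session cache of calibrated penetrance parameters, keyed by the
# scientific configuration (not the master seed)
calibration_cache <- new.env(parent = emptyenv())

logit <- function(p) log(p / (1 - p))

# raw material for a population chunk: uniform draws for the covariates
# (so the covariate parameters can be re-applied without re-drawing),
# genotypes, and the genetic part of the linear predictor (main effects
# + planted interaction); assumes a seeded RNG
draw_raw <- function(cfg, n) {
  raw <- list(n = n,
              u = matrix(stats::runif(n * 5L), n, 5L,
                         dimnames = list(NULL, c("age", BINARY_COVS))))
  g <- list()
  gen_eta <- numeric(n)
  for (nm in names(cfg$loci)) {
    loc <- cfg$loci[[nm]]
    pr <- hwe_genotype_probs(loc, cfg$allele_freqs[[nm]])
    g[[nm]] <- loc$categories[sample.int(length(pr), n, replace = TRUE,
                                         prob = pr)]
    b <- cfg$main_effects[[nm]]
    if (b != 0) gen_eta <- gen_eta + b * allele_dosage(loc, loc$alleles[1])[g[[nm]]]
  }
  cell <- paste(g[[cfg$planted$loci[1]]], g[[cfg$planted$loci[2]]], sep = ":")
  raw$genotypes <- g
  raw$gen_eta <- gen_eta + cfg$planted$log_or * (cell %in% cfg$planted$high_cells)
  raw
}

# turn uniform draws into the covariate design matrix under population
# parameters `pop` (age mean + binary prevalences); truncated-normal age
# by inverse CDF
cov_design <- function(cfg, raw, pop) {
  rng <- cfg$covariates$age$range
  sd <- cfg$covariates$age$sd
  u_age <- stats::pnorm(rng[1], pop["age"], sd) +
    raw$u[, "age"] * (stats::pnorm(rng[2], pop["age"], sd) -
                        stats::pnorm(rng[1], pop["age"], sd))
  X <- cbind(age = stats::qnorm(u_age, pop["age"], sd),
             male = as.numeric(raw$u[, "male"] < pop["male"]),
             hypertension = as.numeric(raw$u[, "hypertension"] < pop["hypertension"]),
             diabetes = as.numeric(raw$u[, "diabetes"] < pop["diabetes"]),
             family_history_IS = as.numeric(raw$u[, "family_history_IS"] <
                                              pop["family_history_IS"]))
  X
}

# solve mean(plogis(b0 + eta)) = target for b0 (monotone; Newton with a
# bisection fallback for safety)
solve_intercept <- function(eta, target) {
  b0 <- logit(target) - mean(eta)
  for (i in 1:100) {
    p <- stats::plogis(b0 + eta)
    f <- mean(p) - target
    if (abs(f) < 1e-12) break
    step <- f / mean(p * (1 - p))
    b0 <- max(min(b0 - step, 30), -60)
  }
  b0
}

# Calibrate the penetrance model on a fixed calibration sample.  Three
# sets of parameters are solved jointly by fixed-point iteration: the
# intercept (to the target population case fraction), the population
# covariate parameters (so the CONTROL-conditional marginals match the
# observed control group — controls are not the population once
# covariates carry risk), and the covariate enrichment coefficients (so
# the CASE-conditional marginals match the observed case group).
# Conditional marginals are case-/control-probability-weighted means on
# the calibration sample.  The calibration sample uses its own fixed
# seed, so the penetrance parameters are a function of the scientific
# configuration alone: replicate cohorts drawn under different master
# seeds share the same planted truth (results are cached per
# configuration).
calibrate_penetrance <- function(cfg, n_cal = 50000L) {
  key <- paste(utils::capture.output(utils::str(
    cfg[c("allele_freqs", "planted", "main_effects", "covariates",
          "target_case_fraction")], digits.d = 15)), collapse = "\n")
  hit <- calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  cv <- cfg$covariates
  raw <- with_seed(881221L, draw_raw(cfg, n_cal))
  ctrl_target <- c(age = cv$age$mean, male = cv$male$p,
                   hypertension = cv$hypertension$p, diabetes = cv$diabetes$p,
                   family_history_IS = cv$family_history_IS$p)
  case_target <- c(age = cv$age$case_mean, male = cv$male$case_p,
                   hypertension = cv$hypertension$case_p,
                   diabetes = cv$diabetes$case_p,
                   family_history_IS = cv$family_history_IS$case_p)
  pop <- ctrl_target                       # start: population = controls
  betas <- c(age = (case_target["age"] - ctrl_target["age"]) / cv$age$sd^2,
             logit(case_target[BINARY_COVS]) - logit(ctrl_target[BINARY_COVS]))
  names(betas) <- c("age", BINARY_COVS)
  b0 <- 0
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  for (it in 1:20) {
    X <- cov_design(cfg, raw, pop)
    eta <- as.vector(X %*% betas) + raw$gen_eta
    b0 <- solve_intercept(eta, cfg$target_case_fraction)
    pi <- stats::plogis(b0 + eta)
    case_mean <- colSums(X * pi) / sum(pi)
    ctrl_mean <- colSums(X * (1 - pi)) / sum(1 - pi)
    age_var <- stats::var(X[, "age"])
    pop["age"] <- pop["age"] + (ctrl_target["age"] - ctrl_mean["age"])
    betas["age"] <- betas["age"] + (case_target["age"] - case_mean["age"]) / age_var
    for (j in BINARY_COVS) {
      pop[j] <- clamp(stats::plogis(logit(pop[j]) + logit(ctrl_target[j]) -
                                      logit(clamp(ctrl_mean[j]))))
      betas[j] <- betas[j] + logit(case_target[j]) - logit(clamp(case_mean[j]))
    }
  }
  out <- list(b0 = b0, betas = betas, pop = pop)
  calibration_cache[[key]] <- out
  out
}

#' Generate a synthetic case-control cohort
#'
#' Prospectively simulates a population — Hardy-Weinberg genotypes at
#' the configured control-population allele frequencies, independent
#' loci, covariates from the control marginals — assigns disease from
#' the logistic penetrance model, and then samples exactly `n_cases`
#' cases and `n_controls` controls (case-control sampling leaves all
#' odds ratios of the penetrance model intact up to the intercept).
#' Cases receive an etiologic subtype label drawn from the study's
#' subtype mix.  Deterministic given `config$seed`.
#'
#' @param config A [default_config()] object.
#' @return An `mdr_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mdr_gen_config"))
  pen <- calibrate_penetrance(config)
  tf <- config$target_case_fraction
  chunk_n <- as.integer(ceiling(1.5 * max(config$n_cases / tf,
                                          config$n_controls / (1 - tf))))
  cases <- controls <- NULL
  for (i in 1:50) {
    d <- with_seed(derive_seed(config$seed, i), {
      raw <- draw_raw(config, chunk_n)
      X <- cov_design(config, raw, pen$pop)
      eta <- as.vector(X %*% pen$betas) + raw$gen_eta
      ch <- data.frame(age = X[, "age"],
                       sex = ifelse(X[, "male"] == 1, "male", "female"),
                       family_history_IS = as.integer(X[, "family_history_IS"]),
                       hypertension = as.integer(X[, "hypertension"]),
                       diabetes = as.integer(X[, "diabetes"]),
                       stringsAsFactors = FALSE)
      for (nm in names(config$loci)) ch[[nm]] <- raw$genotypes[[nm]]
      ch$phenotype <- as.integer(stats::runif(chunk_n) <
                                   stats::plogis(pen$b0 + eta))
      ch
    })
    cases <- rbind(cases, d[d$phenotype == 1L, ])
    controls <- rbind(controls, d[d$phenotype == 0L, ])
    if (nrow(cases) >= config$n_cases && nrow(controls) >= config$n_controls)
      break
  }
  if (nrow(cases) < config$n_cases || nrow(controls) < config$n_controls)
    stop("resampling limit: simulated population yielded too few ",
         if (nrow(cases) < config$n_cases) "cases" else "controls",
         call. = FALSE)
  d <- rbind(cases[seq_len(config$n_cases), ],
             controls[seq_len(config$n_controls), ])
  d$subtype <- "control"
  d$subtype[d$phenotype == 1L] <- with_seed(
    derive_seed(config$seed, 8888L),
    sample(names(config$subtype_probs), config$n_cases, replace = TRUE,
           prob = config$subtype_probs))
  d$id <- sprintf("S%05d", seq_len(nrow(d)))
  rownames(d) <- NULL
  cohort(d[, c("id", "phenotype", "subtype", COVARIATE_COLS,
               names(config$loci))], config$loci)
}

#' Permute phenotype labels (null cohort)
#'
#' Uniformly permutes the case/control labels (carrying the subtype
#' label with them, since subtypes only attach to cases) while leaving
#' genotypes and covariates untouched; class totals are preserved.
#'
#' @param x An `mdr_cohort`.
#' @param seed Integer seed.
#' @return An `mdr_cohort` with shuffled outcome labels.
#' @export
null_shuffle <- function(x, seed = 1L) {
  stopifnot(inherits(x, "mdr_cohort"))
  perm <- with_seed(seed, sample.int(nrow(x$data)))
  x$data$phenotype <- x$data$phenotype[perm]
  x$data$subtype <- x$data$subtype[perm]
  x
}
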