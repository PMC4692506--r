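test_that("default config computes allele frequencies by gene counting", {
  cfg <- default_config()
  # allele counting from the control genotype distribution, done here by
  # direct arithmetic on the counts
  expect_equal(cfg$allele_freqs$ACE[["D"]], (2 * 64 + 351) / 1548)
  expect_equal(cfg$allele_freqs$BFG_T148C[["C"]], (2 * 396 + 301) / 1548)
  expect_equal(cfg$allele_freqs$BFG_A455G[["G"]], (2 * 410 + 302) / 1548)
  expect_equal(cfg$allele_freqs$MTHFR_C677T[["T"]], (2 * 52 + 299) / 1548)
  expect_equal(cfg$allele_freqs$ENOS_G894T[["T"]], (2 * 12 + 143) / 1548)
  expect_equal(cfg$allele_freqs$APOE[["e2"]], (2 * 3 + 107 + 8) / 1548)
  expect_equal(cfg$allele_freqs$APOE[["e4"]], (2 * 8 + 8 + 113) / 1548)
  expect_equal(sum(cfg$allele_freqs$APOE), 1)
  expect_identical(cfg$planted$high_cells, c("DD:CC", "DD:CT", "ID:CC"))
  expect_equal(exp(cfg$planted$log_or), 1.57)
  expect_equal(cfg$n_cases, 712L)
  expect_equal(cfg$n_controls, 774L)
  # Hardy-Weinberg genotype probabilities sum to 1 at every locus
  for (nm in names(cfg$loci))
    expect_equal(sum(mdrpipe:::hwe_genotype_probs(cfg$loci[[nm]],
                                                  cfg$allele_freqs[[nm]])), 1)
})

test_that("generation is deterministic given the seed", {
  cfg <- default_config(n_cases = 80, n_controls = 90, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- default_config(n_cases = 80, n_controls = 90, seed = 124)
  expect_false(identical(generate_cohort(cfg)$data, generate_cohort(cfg2)$data))
})

test_that("generated control genotype frequencies match the configuration", {
  cfg <- default_config(n_cases = 200, n_controls = 4000, seed = 5)
  co <- generate_cohort(cfg)
  ctrl <- co$data[co$data$phenotype == 0L, ]
  for (nm in c("ACE", "APOE")) {
    pr <- mdrpipe:::hwe_genotype_probs(cfg$loci[[nm]], cfg$allele_freqs[[nm]])
    obs <- table(factor(ctrl[[nm]], levels = cfg$loci[[nm]]$categories)) / nrow(ctrl)
    se <- sqrt(pr * (1 - pr) / nrow(ctrl))
    expect_true(all(abs(as.vector(obs) - pr) < 4 * se + 1e-3))
  }
  # covariate marginals near the configured control distribution
  expect_lt(abs(mean(ctrl$age) - 51.5), 1.5)
  expect_lt(abs(mean(ctrl$sex == "male") - 0.54), 0.03)
  expect_lt(abs(mean(ctrl$hypertension) - 0.19), 0.03)
})

test_that("a planted interaction is recovered and a null one is absent", {
  high <- c("DD:CC", "DD:CT", "ID:CC")
  crude_log_or <- function(co) {
    cell <- paste(co$data$ACE, co$data$BFG_T148C, sep = ":")
    h <- cell %in% high
    y <- co$data$phenotype
    log((sum(h & y == 1) * sum(!h & y == 0)) /
          (sum(!h & y == 1) * sum(h & y == 0)))
  }
  adjusted_log_or <- function(co) {
    cell <- paste(co$data$ACE, co$data$BFG_T148C, sep = ":")
    f <- fit_logistic(co$data$phenotype,
                      cbind(data.frame(high_risk = as.integer(cell %in% high)),
                            co$data[, c("age", "sex", "family_history_IS",
                                        "hypertension", "diabetes")]))
    f$coefficients$estimate[f$coefficients$term == "high_risk"]
  }
  # three seeds at n = 5000/5000: the covariate-adjusted log-OR (the
  # estimand the penetrance model plants) is recovered within
  # Monte-Carlo tolerance on the average; the crude log-OR sits between
  # zero and the planted value (odds-ratio non-collapsibility)
  fits <- vapply(1:3, function(s) {
    cfg <- default_config(n_cases = 5000, n_controls = 5000,
                          interaction_or = 1.57, seed = 100 + s)
    co <- generate_cohort(cfg)
    c(adjusted = adjusted_log_or(co), crude = crude_log_or(co))
  }, c(0, 0))
  expect_lt(abs(mean(fits["adjusted", ]) - log(1.57)), 0.08)
  expect_true(all(fits["crude", ] > 0 & fits["crude", ] < log(1.57) + 0.08))
  # null config: no association either way
  cfg0 <- default_config(n_cases = 5000, n_controls = 5000,
                         interaction_or = 1, seed = 77)
  expect_lt(abs(crude_log_or(generate_cohort(cfg0))), 0.12)
})

test_that("cases are enriched in covariates as configured", {
  cfg <- default_config(n_cases = 3000, n_controls = 3000, seed = 9)
  co <- generate_cohort(cfg)
  cas <- co$data[co$data$phenotype == 1L, ]
  expect_lt(abs(mean(cas$age) - 65.2), 2.5)
  expect_lt(abs(mean(cas$hypertension) - 0.573), 0.05)
  expect_lt(abs(mean(cas$diabetes) - 0.202), 0.04)
  # every case has a stroke subtype, every control the control label
  expect_true(all(cas$subtype %in% c("LAA", "SAO", "CE", "SOE", "SUE")))
  expect_true(all(co$data$subtype[co$data$phenotype == 0L] == "control"))
})

test_that("null_shuffle permutes labels, preserving totals and pairing", {
  cfg <- default_config(n_cases = 50, n_controls = 60, seed = 2)
  co <- generate_cohort(cfg)
  sh <- null_shuffle(co, seed = 3)
  expect_equal(n_cases(sh), n_cases(co))
  expect_equal(n_controls(sh), n_controls(co))
  expect_identical(sh$data$ACE, co$data$ACE)
  expect_identical(sh$data$age, co$data$age)
  # subtype travels with phenotype, so the shuffled cohort stays valid
  expect_silent(mdrpipe:::validate_cohort(sh))
  sh2 <- null_shuffle(co, seed = 4)
  expect_false(identical(sh$data$phenotype, sh2$data$phenotype))
})
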