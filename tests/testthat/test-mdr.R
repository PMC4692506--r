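test_that("fold plans are stratified, balanced, exhaustive and seeded", {
  co <- mk_cohort(rep(c(1, 0), each = 20),
                  ACE = rep(c("DD", "ID", "II", "DD"), 10))
  f <- make_folds(co, k = 10, seed = 5)
  expect_equal(sort(unique(f$fold)), 1:10)
  for (k in 1:10) {
    expect_equal(sum(f$fold == k & co$data$phenotype == 1L), 2)
    expect_equal(sum(f$fold == k & co$data$phenotype == 0L), 2)
  }
  expect_identical(f, make_folds(co, k = 10, seed = 5))
  expect_false(identical(f$fold, make_folds(co, k = 10, seed = 6)$fold))
  expect_error(make_folds(mk_cohort(c(1, rep(0, 20)), ACE = rep("DD", 21)),
                          k = 5), "at least k")
})

test_that("cell labeling follows the closed threshold rule", {
  # 2x2 toy with cell ratios 2.0, 0.5, 1.0 and one empty cell at T = 1
  co <- cohort_from_cells(
    case_counts = c("DD:TT" = 4, "DD:CT" = 2, "ID:TT" = 3),
    control_counts = c("DD:TT" = 2, "DD:CT" = 4, "ID:TT" = 3),
    loci = c("ACE", "BFG_T148C"))
  lab <- label_cells(co, c("ACE", "BFG_T148C"))
  expect_equal(lab$threshold, 1)
  got <- setNames(lab$cells$label, lab$cells$cell)
  expect_equal(got[["DD:TT"]], "high")   # 4:2 above T
  expect_equal(got[["DD:CT"]], "low")    # 2:4 below T
  expect_equal(got[["ID:TT"]], "high")   # 3:3 ties are high
  expect_equal(got[["ID:CC"]], "empty")

  # cases with zero controls: infinite ratio is high
  co2 <- cohort_from_cells(c("DD:TT" = 10, "ID:TT" = 1),
                           c("ID:TT" = 20),
                           loci = c("ACE", "BFG_T148C"))
  lab2 <- label_cells(co2, c("ACE", "BFG_T148C"))
  expect_equal(lab2$cells$label[lab2$cells$cell == "DD:TT"], "high")

  # on full data every high cell's ratio meets the threshold
  for (s in 1:5) {
    co3 <- random_tiny_cohort(400 + s)
    lab3 <- label_cells(co3, names(co3$loci))
    hi <- lab3$cells[lab3$cells$label == "high", ]
    expect_true(all(hi$cases / pmax(hi$controls, 1e-12) >= lab3$threshold
                    | hi$controls == 0))
  }
})

test_that("risk recoding applies labels and handles empty cells and NAs", {
  co <- cohort_from_cells(
    case_counts = c("DD:CC" = 5, "ID:CT" = 2),
    control_counts = c("DD:CC" = 2, "ID:CT" = 6),
    loci = c("ACE", "BFG_T148C"))
  lab <- label_cells(co, c("ACE", "BFG_T148C"))
  rec <- risk_recode(co, lab)
  # high-risk cell DD:CC -> 1, low-risk ID:CT -> 0
  expect_equal(unique(rec$indicator[co$data$ACE == "DD"]), 1L)
  expect_equal(unique(rec$indicator[co$data$ACE == "ID"]), 0L)
  # recode tabulated against phenotype reproduces the class sizes
  expect_equal(sum(co$data$phenotype == 1L), 7)
  expect_equal(table(rec$indicator, co$data$phenotype)["1", "1"],
               sum(co$data$phenotype == 1L & co$data$ACE == "DD"),
               ignore_attr = TRUE)

  # out-of-training individuals in empty cells score low, with a warning
  co_new <- mk_cohort(c(1, 0), ACE = c("II", "ID"),
                      BFG_T148C = c("TT", "CC"))
  expect_warning(rec2 <- risk_recode(co_new, lab), "empty")
  expect_equal(rec2$indicator, c(0L, 0L))
  expect_equal(rec2$n_empty_cell, 2L)

  # missing genotype at a model locus: excluded, counted
  co_na <- mk_cohort(c(1, 0, 0), ACE = c("DD", NA, "ID"),
                     BFG_T148C = c("CC", "CT", "CT"))
  rec3 <- risk_recode(co_na, lab)
  expect_true(is.na(rec3$indicator[2]))
  expect_equal(rec3$n_excluded, 1L)
})

test_that("balanced accuracy is (sensitivity + specificity) / 2", {
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(balanced_accuracy(rep(1, 10), rep(c(1, 0), 5)), 0.5)
  # TP=3, FN=1, TN=2, FP=2 -> (0.75 + 0.5)/2
  pred <- c(1, 1, 1, 0, 0, 0, 1, 1)
  y    <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(balanced_accuracy(pred, y), 0.625)
  expect_warning(balanced_accuracy(c(1, 0), c(1, 1)), "absent")
  expect_error(balanced_accuracy(c(1, 0), c(1, 0, 1)), "length")
})

test_that("sign test is the exact binomial upper tail", {
  expect_equal(sign_test(rep(0.6, 10)), 0.5^10)
  expect_equal(sign_test(c(rep(0.6, 5), rep(0.4, 5))), 638 / 1024)
  expect_equal(sign_test(rep(0.3, 10)), 1)
  # folds at exactly 0.5 count as failures
  expect_equal(sign_test(c(rep(0.6, 5), rep(0.5, 5))), 638 / 1024)
})

test_that("cross-validated evaluation matches the brute-force oracle", {
  for (s in 1:10) {
    co <- random_tiny_cohort(1000 + s)
    folds <- make_folds(co, k = 3, seed = s)
    combo <- names(co$loci)[1:2]
    got <- cv_evaluate(co, combo, folds)
    want <- oracle_cv(co, combo, folds$fold, folds$k)
    expect_identical(got$train_ba, want$train_ba)
    expect_identical(got$test_ba, want$test_ba)
    expect_equal(got$mean_test_ba, mean(want$test_ba))
    expect_equal(got$prediction_error + got$mean_test_ba, 1)
  }
})

test_that("search is deterministic and recovers planted structure", {
  cfg <- default_config(n_cases = 400, n_controls = 400,
                        interaction_or = 3, seed = 60)
  co <- generate_cohort(cfg)
  folds <- make_folds(co, k = 10, seed = 61)
  s1 <- mdr_search(co, 1:3, folds)
  s2 <- mdr_search(co, 1:3, folds)
  expect_identical(s1, s2)
  expect_setequal(s1$per_order[["2"]]$combo, c("ACE", "BFG_T148C"))
  expect_gt(s1$per_order[["2"]]$mean_test_ba, 0.55)
  # consistency bounded by k; accuracies in [0, 1]
  for (m in s1$per_order) {
    expect_true(m$cv_consistency >= 0 && m$cv_consistency <= 10)
    expect_true(all(m$test_ba >= 0 & m$test_ba <= 1))
  }
})

test_that("a label-shuffled cohort evaluates near chance", {
  cfg <- default_config(n_cases = 500, n_controls = 500,
                        interaction_or = 3, seed = 70)
  co <- null_shuffle(generate_cohort(cfg), seed = 71)
  bas <- vapply(1:6, function(s) {
    folds <- make_folds(co, k = 10, seed = 100 + s)
    cv_evaluate(co, c("ACE", "BFG_T148C"), folds)$mean_test_ba
  }, 0)
  expect_lt(abs(mean(bas) - 0.5), 0.04)
})

test_that("testing accuracy does not degrade as the planted effect grows", {
  grid <- c(1, 1.5, 2, 3)
  mean_ba <- vapply(grid, function(or) {
    bas <- vapply(1:6, function(s) {
      cfg <- default_config(n_cases = 600, n_controls = 600,
                            interaction_or = or, seed = 200 + s)
      co <- generate_cohort(cfg)
      folds <- make_folds(co, k = 10, seed = 300 + s)
      cv_evaluate(co, c("ACE", "BFG_T148C"), folds)$mean_test_ba
    }, 0)
    mean(bas)
  }, 0)
  expect_true(all(diff(mean_ba) > -0.015))
  expect_gt(mean_ba[4], mean_ba[1])
})

test_that("permutation p-values use the add-one estimator", {
  cfg <- default_config(n_cases = 150, n_controls = 150,
                        interaction_or = 4, seed = 90)
  co <- generate_cohort(cfg)
  pt <- permutation_test(co, orders = 2, folds_seed = 91, n_perm = 19,
                         seed = 92, loci = c("ACE", "BFG_T148C", "BFG_A455G"))
  expect_equal(pt$p_value, (1 + sum(pt$perm_stats >=
                                      pt$observed$best$mean_test_ba)) / 20)
  # a strong effect should beat all 19 shuffles: the floor is 1/20
  expect_equal(pt$p_value, 1 / 20)
  expect_length(pt$perm_stats, 19)
})

test_that("classification tables feed the odds-ratio machinery", {
  co <- cohort_from_cells(
    case_counts = c("DD:CC" = 30, "ID:CT" = 20),
    control_counts = c("DD:CC" = 10, "ID:CT" = 40),
    loci = c("ACE", "BFG_T148C"))
  lab <- label_cells(co, c("ACE", "BFG_T148C"))
  tab <- classify_individuals(co, lab)
  expect_equal(unclass(tab)["high", "case"], 30, ignore_attr = TRUE)
  expect_equal(sum(tab), nrow(co$data))
  expect_equal(odds_ratio(tab)$or, (30 * 40) / (20 * 10))
  # stratified: subtype cases + all controls
  laa <- classify_individuals(co, lab, stratum = "LAA")
  expect_equal(sum(laa[, "control"]), 50)
})
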