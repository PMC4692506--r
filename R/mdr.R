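# ---- internal engine -------------------------------------------------
#
# Genotype combinations are flattened to integer cell indices once per
# cohort; every labeling / cross-validation step is then a handful of
# tabulate() calls.  The permutation test reuses the same indices across
# all phenotype shuffles, which is what makes 1000 full re-searches cheap.

# integer cell index per individual for a locus combination (NA = missing)
cell_index <- function(x, combo) {
  dims <- vapply(combo, function(nm) length(x$loci[[nm]]$categories), 1L)
  idx <- rep.int(1L, nrow(x$data))
  mult <- 1L
  # last locus varies fastest, so the first locus varies slowest and the
  # cell sequence reads in input-locus order
  for (j in rev(seq_along(combo))) {
    g <- match(x$data[[combo[j]]], x$loci[[combo[j]]]$categories)
    idx <- idx + (g - 1L) * mult
    mult <- mult * dims[j]
  }
  cn <- expand.grid(rev(lapply(combo, function(nm) x$loci[[nm]]$categories)),
                    stringsAsFactors = FALSE)
  cell_names <- apply(as.matrix(cn[, rev(seq_along(combo)), drop = FALSE]),
                      1L, paste, collapse = ":")
  list(idx = idx, n_cells = prod(dims), cell_names = cell_names)
}

# balanced accuracy from a logical prediction and 0/1 truth; an absent
# class contributes rate 0.5 (callers that must warn do so themselves)
ba_rate <- function(pred, y) {
  ncase <- sum(y == 1L)
  nctrl <- length(y) - ncase
  sens <- if (ncase == 0L) 0.5 else sum(pred & y == 1L) / ncase
  spec <- if (nctrl == 0L) 0.5 else sum(!pred & y == 0L) / nctrl
  (sens + spec) / 2
}

# high/low labels for one training split; returns logical per cell
# (TRUE = high); empty cells are FALSE here and reported separately
cell_high <- function(cidx, n_cells, y) {
  ncase <- sum(y == 1L)
  nctrl <- length(y) - ncase
  case_c <- tabulate(cidx[y == 1L], n_cells)
  ctrl_c <- tabulate(cidx[y == 0L], n_cells)
  list(high = (case_c * nctrl >= ctrl_c * ncase) & (case_c + ctrl_c > 0L),
       empty = case_c + ctrl_c == 0L, cases = case_c, controls = ctrl_c,
       threshold = ncase / nctrl)
}

# per-fold training / testing balanced accuracy for one combination
combo_cv <- function(cidx, n_cells, phen, fold, k) {
  train_ba <- numeric(k)
  test_ba <- numeric(k)
  ok <- !is.na(cidx)
  for (f in seq_len(k)) {
    tr <- ok & fold != f
    te <- ok & fold == f
    ytr <- phen[tr]
    lab <- cell_high(cidx[tr], n_cells, ytr)
    train_ba[f] <- ba_rate(lab$high[cidx[tr]], ytr)
    test_ba[f] <- ba_rate(lab$high[cidx[te]], phen[te])
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

new_mdr_model <- function(combo, train_ba, test_ba, cv_consistency = NA_integer_) {
  m <- structure(list(combo = combo, train_ba = train_ba, test_ba = test_ba,
                      mean_test_ba = mean(test_ba),
                      prediction_error = 1 - mean(test_ba),
                      cv_consistency = cv_consistency,
                      sign_p = NA_real_, permutation_p = NA_real_),
                 class = "mdr_model")
  m$sign_p <- sign_test(test_ba)
  m
}

#' @export
print.mdr_model <- function(x, ...) {
  cat(sprintf("<MDR model> %s: testing BA %.4f, CV consistency %s/%d, sign p %.4g%s\n",
              paste(x$combo, collapse = " x "), x$mean_test_ba,
              ifelse(is.na(x$cv_consistency), "?", x$cv_consistency),
              length(x$test_ba), x$sign_p,
              if (is.na(x$permutation_p)) ""
              else sprintf(", permutation p %.4g", x$permutation_p)))
  invisible(x)
}

# ---- fold construction ------------------------------------------------

#' Stratified cross-validation fold plan
#'
#' Assigns each individual to one of `k` folds, stratified by phenotype:
#' within each class a seeded random permutation is dealt into blocks,
#' so fold sizes within a class differ by at most one.  Deterministic
#' given the seed.
#'
#' @param x An `mdr_cohort` (or a 0/1 phenotype vector).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold permutation.
#' @return Object of class `mdr_folds`: integer `fold` per individual,
#'   plus `k` and `seed`.
#' @export
make_folds <- function(x, k = 10L, seed = 1L) {
  phen <- if (inherits(x, "mdr_cohort")) x$data$phenotype else as.integer(x)
  stopifnot(k >= 2L)
  if (min(sum(phen == 1L), sum(phen == 0L)) < k)
    stop("each phenotype class needs at least k individuals", call. = FALSE)
  fold <- integer(length(phen))
  with_seed(seed, {
    for (cls in c(1L, 0L)) {
      ids <- which(phen == cls)
      fold[ids[sample.int(length(ids))]] <- rep_len(seq_len(k), length(ids))
    }
  })
  structure(list(fold = fold, k = as.integer(k), seed = seed),
            class = "mdr_folds")
}

# ---- labeling and reduction ------------------------------------------

#' Label genotype-combination cells high or low risk
#'
#' The heart of MDR: each cell of the k-locus genotype grid is labeled
#' high risk when its case:control ratio meets or exceeds the threshold
#' T = (cases:controls of the labeling data); cells with cases but no
#' controls are high (infinite ratio), cells with no individuals are
#' `empty`.  Ties at exactly T are high, making the rule a closed
#' half-line.
#'
#' @param x An `mdr_cohort` (the training data).
#' @param combo Character vector of locus names (order fixes the grid).
#' @return Object of class `mdr_cell_labels`: `cells` data.frame with
#'   columns cell, cases, controls, label (high/low/empty); `threshold`;
#'   `combo`; `n_excluded` (individuals missing a combo genotype).
#' @export
label_cells <- function(x, combo) {
  stopifnot(inherits(x, "mdr_cohort"), length(combo) >= 1L)
  unknown <- setdiff(combo, names(x$loci))
  if (length(unknown))
    stop("unknown locus: ", paste(unknown, collapse = ", "), call. = FALSE)
  ci <- cell_index(x, combo)
  ok <- !is.na(ci$idx)
  y <- x$data$phenotype[ok]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("training data must contain both cases and controls", call. = FALSE)
  lab <- cell_high(ci$idx[ok], ci$n_cells, y)
  label <- ifelse(lab$empty, "empty", ifelse(lab$high, "high", "low"))
  structure(list(cells = data.frame(cell = ci$cell_names, cases = lab$cases,
                                    controls = lab$controls, label = label,
                                    stringsAsFactors = FALSE),
                 threshold = lab$threshold, combo = combo,
                 n_excluded = sum(!ok)),
            class = "mdr_cell_labels")
}

#' @export
print.mdr_cell_labels <- function(x, ...) {
  cat(sprintf("<cell labels> %s, threshold T = %.4f (%d excluded)\n",
              paste(x$combo, collapse = " x "), x$threshold, x$n_excluded))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Collapse a multi-locus genotype to the binary MDR risk attribute
#'
#' Applies a fitted cell labeling to a cohort, reducing each
#' individual's k-locus genotype to 1 (high-risk combination) or 0
#' (low-risk).  Individuals falling into cells that were empty in the
#' labeling data are conservatively scored 0 and counted; individuals
#' missing a genotype at any model locus are excluded and counted.
#'
#' @param x An `mdr_cohort`.
#' @param labels An [label_cells()] result.
#' @return List of class `mdr_recode`: `indicator` (0/1, `NA` for
#'   excluded individuals), `n_excluded`, `n_empty_cell`.
#' @export
risk_recode <- function(x, labels) {
  stopifnot(inherits(x, "mdr_cohort"), inherits(labels, "mdr_cell_labels"))
  ci <- cell_index(x, labels$combo)
  stopifnot(identical(ci$cell_names, labels$cells$cell))
  high <- labels$cells$label == "high"
  empty <- labels$cells$label == "empty"
  ind <- ifelse(is.na(ci$idx), NA_integer_, as.integer(high[ci$idx]))
  n_empty <- sum(empty[ci$idx], na.rm = TRUE)
  if (n_empty > 0L)
    warning(n_empty, " individual(s) fell into cells empty at labeling; scored low risk")
  structure(list(indicator = ind, n_excluded = sum(is.na(ci$idx)),
                 n_empty_cell = n_empty, combo = labels$combo),
            class = "mdr_recode")
}

#' Balanced accuracy of a binary risk prediction
#'
#' (sensitivity + specificity) / 2.  If a phenotype class is absent its
#' rate is defined as 0.5 and a warning is raised.
#'
#' @param pred 0/1 (or logical) predictions.
#' @param phenotype 0/1 truth of the same length.
#' @return A single number in [0, 1].
#' @export
balanced_accuracy <- function(pred, phenotype) {
  if (length(pred) != length(phenotype)) stop("length mismatch", call. = FALSE)
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  y <- as.integer(phenotype)
  if (!any(y == 1L) || !any(y == 0L))
    warning("a phenotype class is absent; its rate is taken as 0.5")
  ba_rate(as.logical(pred), y)
}

# ---- cross-validated evaluation and search ---------------------------

#' Cross-validated evaluation of one locus combination
#'
#' For each fold, cell labels are fit on the training nine tenths and
#' balanced accuracy is measured on the held-out tenth; the prediction
#' error is one minus the mean testing balanced accuracy.  The CV
#' consistency field is only defined relative to a search over
#' competing combinations and is filled by [mdr_search()].
#'
#' @param x An `mdr_cohort`.
#' @param combo Character vector of locus names.
#' @param folds An [make_folds()] plan for `x`.
#' @return An `mdr_model`.
#' @export
cv_evaluate <- function(x, combo, folds) {
  stopifnot(inherits(x, "mdr_cohort"), inherits(folds, "mdr_folds"))
  ci <- cell_index(x, combo)
  cv <- combo_cv(ci$idx, ci$n_cells, x$data$phenotype, folds$fold, folds$k)
  new_mdr_model(combo, cv$train_ba, cv$test_ba)
}

# all locus-name combinations of one order, in lexicographic index order
order_combos <- function(loci_names, order) {
  if (order > length(loci_names)) return(list())
  m <- utils::combn(seq_along(loci_names), order)
  lapply(seq_len(ncol(m)), function(j) loci_names[m[, j]])
}

# core search over a fixed set of pre-indexed combinations; returns the
# per-order winners and overall best using: fold winner = highest
# training BA (ties -> lexicographically first combination), CV
# consistency = folds won, per-order model = most folds won, overall
# best = max CV consistency then min prediction error then lowest order
search_engine <- function(indexed, orders, phen, fold, k) {
  per_order <- vector("list", length(orders))
  names(per_order) <- as.character(orders)
  for (oi in seq_along(orders)) {
    combos <- indexed[[oi]]
    ncomb <- length(combos)
    train_ba <- matrix(0, ncomb, k)
    test_ba <- matrix(0, ncomb, k)
    for (ci in seq_len(ncomb)) {
      cv <- combo_cv(combos[[ci]]$idx, combos[[ci]]$n_cells, phen, fold, k)
      train_ba[ci, ] <- cv$train_ba
      test_ba[ci, ] <- cv$test_ba
    }
    winners <- apply(train_ba, 2L, which.max)   # ties -> first = lexicographic
    wins <- tabulate(winners, ncomb)
    best_i <- which.max(wins)
    per_order[[oi]] <- new_mdr_model(combos[[best_i]]$combo,
                                     train_ba[best_i, ], test_ba[best_i, ],
                                     cv_consistency = wins[best_i])
  }
  pe <- vapply(per_order, `[[`, 0, "prediction_error")
  cons <- vapply(per_order, `[[`, 0L, "cv_consistency")
  cand <- which(cons == max(cons))
  best <- cand[which.min(pe[cand])]   # ties -> lowest order (first)
  list(per_order = per_order, best = per_order[[best]])
}

index_combos <- function(x, orders, loci_names) {
  lapply(orders, function(o)
    lapply(order_combos(loci_names, o), function(cmb) {
      ci <- cell_index(x, cmb)
      list(combo = cmb, idx = ci$idx, n_cells = ci$n_cells)
    }))
}

#' Exhaustive MDR search across interaction orders
#'
#' Evaluates every locus combination of each requested order by
#' cross-validation.  Within each fold the combination with the highest
#' training balanced accuracy is the fold winner (ties broken toward the
#' lexicographically first combination by locus index); a combination's
#' CV consistency is the number of folds it wins.  The reported model
#' per order is the combination winning the most folds, and the overall
#' best model maximizes CV consistency with ties broken by minimum
#' prediction error.
#'
#' @param x An `mdr_cohort`.
#' @param orders Integer vector of interaction orders (default 1:4).
#' @param folds An [make_folds()] plan.
#' @param loci Locus names to search over (default: all loci of `x`).
#' @return Object of class `mdr_search`: `per_order` (list of
#'   `mdr_model`, one per order) and `best`.
#' @export
mdr_search <- function(x, orders = 1:4, folds, loci = names(x$loci)) {
  stopifnot(inherits(x, "mdr_cohort"), inherits(folds, "mdr_folds"),
            all(orders >= 1L), all(orders <= length(loci)))
  indexed <- index_combos(x, orders, loci)
  res <- search_engine(indexed, orders, x$data$phenotype, folds$fold, folds$k)
  structure(c(res, list(orders = orders, k = folds$k)), class = "mdr_search")
}

#' @export
print.mdr_search <- function(x, ...) {
  cat("MDR exhaustive search (k =", x$k, "folds)\n")
  cat(sprintf("%-6s %-32s %-12s %-14s %s\n",
              "order", "best model", "testing BA", "CV consistency", "sign p"))
  for (m in x$per_order)
    cat(sprintf("%-6d %-32s %-12.4f %d/%-12d %.4g\n", length(m$combo),
                paste(m$combo, collapse = " x "), m$mean_test_ba,
                m$cv_consistency, length(m$test_ba), m$sign_p))
  cat("overall best:", paste(x$best$combo, collapse = " x "), "\n")
  invisible(x)
}

#' Cross-validation sign test
#'
#' One-sided exact binomial test that the number of folds with testing
#' balanced accuracy above 0.5 exceeds chance (success probability 1/2);
#' folds at exactly 0.5 count as failures.
#'
#' @param x An `mdr_model` or a numeric vector of per-fold testing
#'   balanced accuracies.
#' @return The one-sided binomial p-value.
#' @export
sign_test <- function(x) {
  acc <- if (inherits(x, "mdr_model")) x$test_ba else as.numeric(x)
  k <- length(acc)
  s <- sum(acc > 0.5)
  stats::pbinom(s - 1, k, 0.5, lower.tail = FALSE)
}

#' Permutation test for the best MDR model
#'
#' Re-runs the full exhaustive search on `n_perm` phenotype-shuffled
#' copies of the cohort and compares the observed best model's mean
#' testing balanced accuracy with the permutation distribution, using
#' the add-one estimator p = (1 + #\{permuted >= observed\}) /
#' (n_perm + 1).  Fold plans are re-drawn per permutation from the same
#' fold seed (stratification depends on the shuffled labels).
#'
#' @param x An `mdr_cohort`.
#' @param orders Interaction orders searched (default 1:4).
#' @param folds_seed Seed for every fold plan.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the label shuffles.
#' @param k Folds per plan (default 10).
#' @param loci Locus names to search over.
#' @return List of class `mdr_permutation`: `p_value`, `observed` (the
#'   observed `mdr_search`), `perm_stats`.
#' @export
permutation_test <- function(x, orders = 1:4, folds_seed = 1L,
                             n_perm = 1000L, seed = 1L, k = 10L,
                             loci = names(x$loci)) {
  stopifnot(inherits(x, "mdr_cohort"), n_perm >= 1L)
  indexed <- index_combos(x, orders, loci)
  phen <- x$data$phenotype
  folds <- make_folds(phen, k = k, seed = folds_seed)
  obs_res <- search_engine(indexed, orders, phen, folds$fold, folds$k)
  obs <- obs_res$best$mean_test_ba
  perm_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- with_seed(derive_seed(seed, b), sample(phen))
    fp <- make_folds(yp, k = k, seed = folds_seed)
    perm_stats[b] <- search_engine(indexed, orders, yp, fp$fold, fp$k)$best$mean_test_ba
  }
  p <- (1 + sum(perm_stats >= obs)) / (n_perm + 1)
  obs_res$best$permutation_p <- p
  structure(list(p_value = p,
                 observed = structure(c(obs_res, list(orders = orders, k = k)),
                                      class = "mdr_search"),
                 perm_stats = perm_stats, n_perm = n_perm),
            class = "mdr_permutation")
}

#' @export
print.mdr_permutation <- function(x, ...) {
  cat(sprintf("permutation test: p = %.4g (%d permutations; observed testing BA %.4f)\n",
              x$p_value, x$n_perm, x$observed$best$mean_test_ba))
  invisible(x)
}

#' Tabulate high/low risk classification against phenotype
#'
#' Applies a full-cohort cell labeling to every individual and returns
#' the 2x2 table of risk indicator (high/low) by status, the table
#' consumed by crude and covariate-adjusted odds-ratio estimation.  With
#' a subtype stratum, cases are restricted to the subtype while all
#' controls are kept.
#'
#' @param x An `mdr_cohort`.
#' @param labels An [label_cells()] result.
#' @param stratum `"overall"` or a subtype label.
#' @return An `mdr_table` with rows `high`, `low` and columns `case`,
#'   `control`.
#' @export
classify_individuals <- function(x, labels, stratum = "overall") {
  rec <- risk_recode(x, labels)
  d <- x$data
  keep <- !is.na(rec$indicator)
  if (!identical(stratum, "overall")) {
    if (!stratum %in% IS_SUBTYPES) stop("unknown stratum: ", stratum, call. = FALSE)
    keep <- keep & (d$phenotype == 0L |
                      (!is.na(d$subtype) & d$subtype == stratum))
  }
  ind <- factor(rec$indicator[keep], levels = c(1L, 0L), labels = c("high", "low"))
  ph <- factor(d$phenotype[keep], levels = c(1L, 0L), labels = c("case", "control"))
  m <- table(ind, ph)
  m <- matrix(as.integer(m), 2L, 2L,
              dimnames = list(c("high", "low"), c("case", "control")))
  structure(m, class = c("mdr_table", "matrix"),
            n_excluded = rec$n_excluded,
            loci = labels$combo, stratum = stratum)
}
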