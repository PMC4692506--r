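# Brute-force MDR oracle: everything done by literal enumeration over
# cells, individuals and folds.  Deliberately slow and independent of the
# package's vectorized engine; used on tiny cohorts only.

oracle_cells <- function(loci_defs, combo) {
  cells <- list(character(0))
  for (nm in combo) {
    out <- list()
    for (prefix in cells)
      for (cat in loci_defs[[nm]]$categories)
        out[[length(out) + 1L]] <- c(prefix, cat)
    cells <- out
  }
  cells
}

oracle_individual_cell <- function(d, combo, i) {
  cell <- character(0)
  for (nm in combo) {
    if (is.na(d[[nm]][i])) return(NULL)
    cell <- c(cell, d[[nm]][i])
  }
  cell
}

# high/low/empty label per cell, threshold = cases:controls of the rows
# in `use` (a logical vector over individuals)
oracle_label <- function(co, combo, use = rep(TRUE, nrow(co$data))) {
  d <- co$data
  cells <- oracle_cells(co$loci, combo)
  ncase <- 0; nctrl <- 0
  for (i in seq_len(nrow(d))) {
    if (!use[i] || is.null(oracle_individual_cell(d, combo, i))) next
    if (d$phenotype[i] == 1L) ncase <- ncase + 1 else nctrl <- nctrl + 1
  }
  thr <- ncase / nctrl
  lab <- character(length(cells))
  cas <- integer(length(cells)); ctr <- integer(length(cells))
  for (ci in seq_along(cells)) {
    a <- 0L; b <- 0L
    for (i in seq_len(nrow(d))) {
      if (!use[i]) next
      cell <- oracle_individual_cell(d, combo, i)
      if (is.null(cell) || !identical(cell, cells[[ci]])) next
      if (d$phenotype[i] == 1L) a <- a + 1L else b <- b + 1L
    }
    cas[ci] <- a; ctr[ci] <- b
    lab[ci] <- if (a + b == 0) "empty"
      else if (b == 0) "high"
      else if (a / b >= thr) "high" else "low"
  }
  list(cells = sapply(cells, paste, collapse = ":"), cases = cas,
       controls = ctr, label = lab, threshold = thr)
}

oracle_ba <- function(pred, y) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1L) { if (pred[i]) tp <- tp + 1 else fn <- fn + 1 }
    else            { if (pred[i]) fp <- fp + 1 else tn <- tn + 1 }
  }
  sens <- if (tp + fn == 0) 0.5 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0.5 else tn / (tn + fp)
  (sens + spec) / 2
}

# per-fold training/testing balanced accuracy for one combination
oracle_cv <- function(co, combo, fold, k) {
  d <- co$data
  train_ba <- test_ba <- numeric(k)
  for (f in seq_len(k)) {
    lab <- oracle_label(co, combo, use = fold != f)
    predict_one <- function(i) {
      cell <- oracle_individual_cell(d, combo, i)
      if (is.null(cell)) return(NA)
      lab$label[match(paste(cell, collapse = ":"), lab$cells)] == "high"
    }
    for (part in c("train", "test")) {
      ids <- which(if (part == "train") fold != f else fold == f)
      preds <- c(); ys <- c()
      for (i in ids) {
        p <- predict_one(i)
        if (is.na(p)) next
        preds <- c(preds, p); ys <- c(ys, d$phenotype[i])
      }
      ba <- oracle_ba(preds, ys)
      if (part == "train") train_ba[f] <- ba else test_ba[f] <- ba
    }
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

# exhaustive search: fold winner by training BA (tie -> first combo in
# lexicographic order), CV consistency = folds won, per-order best =
# most folds won, overall best = max consistency then min prediction error
oracle_search <- function(co, orders, fold, k) {
  per_order <- list()
  for (o in orders) {
    idx <- utils::combn(seq_along(co$loci), o)
    combos <- list()
    for (j in seq_len(ncol(idx))) combos[[j]] <- names(co$loci)[idx[, j]]
    cvs <- lapply(combos, function(cmb) oracle_cv(co, cmb, fold, k))
    wins <- integer(length(combos))
    for (f in seq_len(k)) {
      best_j <- 1
      for (j in seq_along(combos))
        if (cvs[[j]]$train_ba[f] > cvs[[best_j]]$train_ba[f]) best_j <- j
      wins[best_j] <- wins[best_j] + 1L
    }
    bj <- 1
    for (j in seq_along(combos)) if (wins[j] > wins[bj]) bj <- j
    per_order[[as.character(o)]] <-
      list(combo = combos[[bj]], train_ba = cvs[[bj]]$train_ba,
           test_ba = cvs[[bj]]$test_ba,
           mean_test_ba = mean(cvs[[bj]]$test_ba),
           cv_consistency = wins[bj])
  }
  best <- per_order[[1]]
  for (m in per_order)
    if (m$cv_consistency > best$cv_consistency ||
        (m$cv_consistency == best$cv_consistency &&
         (1 - m$mean_test_ba) < (1 - best$mean_test_ba) - 1e-15))
      best <- m
  list(per_order = per_order, best = best)
}
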