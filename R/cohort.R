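IS_SUBTYPES <- c("LAA", "SAO", "CE", "SOE", "SUE")
COVARIATE_COLS <- c("age", "sex", "family_history_IS", "hypertension", "diabetes")

#' Assemble a case-control cohort
#'
#' Bundles a per-individual table with the locus definitions that govern
#' its genotype columns and validates every field.  The table is
#' wide-format: one row per individual with columns `id`, `phenotype`
#' (0 = control, 1 = case), `subtype` (etiologic stroke subtype for
#' cases, `"control"` or `NA` otherwise), covariates `age` (years),
#' `sex` (`"male"`/`"female"`), `family_history_IS`, `hypertension`,
#' `diabetes` (each 0/1), and one character column per locus holding a
#' genotype category or `NA`.
#'
#' @param data A data.frame in the layout above.
#' @param loci Named list of [locus()] definitions; defaults to the
#'   six-locus stroke panel of [default_loci()].
#' @return An object of class `mdr_cohort` with elements `data` and `loci`.
#' @seealso [read_cohort()], [generate_cohort()]
#' @export
cohort <- function(data, loci = default_loci()) {
  x <- structure(list(data = as.data.frame(data, stringsAsFactors = FALSE),
                      loci = loci),
                 class = "mdr_cohort")
  validate_cohort(x)
  x
}

validate_cohort <- function(x) {
  d <- x$data
  if (nrow(d) == 0L) stop("cohort is empty", call. = FALSE)
  needed <- c("id", "phenotype", "subtype", COVARIATE_COLS,
              vapply(x$loci, `[[`, "", "name"))
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_row <- function(what, i)
    stop(sprintf("invalid %s at row(s) %s", what,
                 paste(utils::head(i, 5L), collapse = ", ")), call. = FALSE)
  if (!all(d$phenotype %in% c(0L, 1L)))
    bad_row("phenotype (must be 0/1)", which(!d$phenotype %in% c(0L, 1L)))
  ok_sub <- is.na(d$subtype) | d$subtype %in% c(IS_SUBTYPES, "control")
  if (!all(ok_sub)) bad_row("subtype label", which(!ok_sub))
  clash <- d$phenotype == 0L & !is.na(d$subtype) & d$subtype %in% IS_SUBTYPES
  if (any(clash)) bad_row("subtype (stroke subtype on a control)", which(clash))
  ok_age <- is.na(d$age) | (d$age >= 0 & d$age <= 120)
  if (!all(ok_age)) bad_row("age (outside [0, 120])", which(!ok_age))
  ok_sex <- is.na(d$sex) | d$sex %in% c("male", "female")
  if (!all(ok_sex)) bad_row("sex", which(!ok_sex))
  for (cc in c("family_history_IS", "hypertension", "diabetes")) {
    ok <- is.na(d[[cc]]) | d[[cc]] %in% c(0L, 1L)
    if (!all(ok)) bad_row(paste0(cc, " (must be 0/1)"), which(!ok))
  }
  for (loc in x$loci) {
    g <- d[[loc$name]]
    ok <- is.na(g) | g %in% loc$categories
    if (!all(ok))
      stop(sprintf("invalid genotype for locus %s at row(s) %s: %s",
                   loc$name, paste(utils::head(which(!ok), 5L), collapse = ", "),
                   paste(unique(utils::head(g[!ok], 3L)), collapse = ", ")),
           call. = FALSE)
  }
  invisible(x)
}

#' @export
print.mdr_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals: %d cases / %d controls; %d loci (%s)\n",
              nrow(x$data), n_cases(x), n_controls(x), length(x$loci),
              paste(names(x$loci), collapse = ", ")))
  invisible(x)
}

#' @rdname cohort
#' @param x An `mdr_cohort`.
#' @export
n_cases <- function(x) sum(x$data$phenotype == 1L)

#' @rdname cohort
#' @export
n_controls <- function(x) sum(x$data$phenotype == 0L)

#' @export
as.data.frame.mdr_cohort <- function(x, ...) x$data

#' Read a cohort from its CSV dialect
#'
#' The on-disk dialect is wide-format, comma-separated, UTF-8, with a
#' header row, one column per locus and missing code `NA` — written by
#' [write_cohort()] and round-trip lossless.  Columns named differently
#' in the source file can be remapped via `column_map`.
#'
#' @param path Path to a CSV file.
#' @param loci Locus definitions validating the genotype columns.
#' @param column_map Optional named character vector mapping canonical
#'   column names (names) to the file's column names (values).
#' @return A validated [cohort()].
#' @export
read_cohort <- function(path, loci = default_loci(), column_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                       fileEncoding = "UTF-8")
  if (nrow(d) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(d))
    if (length(miss))
      stop("mapped column(s) absent from file: ", paste(miss, collapse = ", "),
           call. = FALSE)
    names(d)[match(column_map, names(d))] <- names(column_map)
  }
  for (cc in c("subtype", "sex", vapply(loci, `[[`, "", "name")))
    if (cc %in% names(d)) d[[cc]] <- as.character(d[[cc]])
  cohort(d, loci)
}

#' Write a cohort in the CSV dialect read by [read_cohort()]
#'
#' @param x An `mdr_cohort`.
#' @param path Output file path.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "mdr_cohort"))
  utils::write.csv(x$data, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Genotype-by-status contingency table
#'
#' Cross-tabulates genotypes (one locus) or genotype combinations (the
#' Cartesian product of several loci, in the given order) against
#' case-control status.  A subtype stratum restricts the cases to that
#' etiologic subtype while keeping all controls, matching the standard
#' per-subtype presentation.  Individuals missing any required genotype
#' are excluded and counted in `n_excluded`.
#'
#' @param x An `mdr_cohort`.
#' @param loci Character vector of locus names (1 or more).
#' @param stratum `"overall"` or a subtype label (e.g. `"LAA"`).
#' @return An object of class `mdr_table`: a counts matrix with one row
#'   per genotype (combination) and columns `case`, `control`, plus
#'   attributes `n_excluded` and `loci`.
#' @export
genotype_table <- function(x, loci, stratum = "overall") {
  stopifnot(inherits(x, "mdr_cohort"))
  unknown <- setdiff(loci, names(x$loci))
  if (length(unknown))
    stop("unknown locus: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!identical(stratum, "overall") && !stratum %in% IS_SUBTYPES)
    stop("unknown stratum: ", stratum, call. = FALSE)
  d <- x$data
  if (!identical(stratum, "overall"))
    d <- d[d$phenotype == 0L | (!is.na(d$subtype) & d$subtype == stratum), ]
  g <- lapply(loci, function(nm)
    factor(d[[nm]], levels = x$loci[[nm]]$categories))
  complete <- !Reduce(`|`, lapply(g, is.na))
  cell <- interaction(g, sep = ":", lex.order = FALSE)[complete]
  # interaction() varies the first factor fastest; reorder so the first
  # locus varies slowest, i.e. rows follow the input locus order
  lv <- levels(cell)
  if (length(loci) > 1L) {
    dims <- vapply(loci, function(nm) length(x$loci[[nm]]$categories), 1L)
    idx <- array(seq_along(lv), dim = dims)
    lv <- lv[as.vector(aperm(idx, rev(seq_along(dims))))]
    cell <- factor(as.character(cell), levels = lv)
  }
  ph <- factor(d$phenotype[complete], levels = c(1L, 0L),
               labels = c("case", "control"))
  counts <- table(cell, ph)
  m <- matrix(as.integer(counts), nrow = nlevels(cell),
              dimnames = list(levels(cell), c("case", "control")))
  structure(m, class = c("mdr_table", "matrix"),
            n_excluded = sum(!complete), loci = loci, stratum = stratum)
}

#' @export
print.mdr_table <- function(x, ...) {
  cat(sprintf("<contingency table> %s%s; %d excluded for missing genotypes\n",
              paste(attr(x, "loci"), collapse = " x "),
              if (identical(attr(x, "stratum"), "overall")) ""
              else paste0(" [", attr(x, "stratum"), " cases vs all controls]"),
              attr(x, "n_excluded")))
  m <- unclass(x)
  attributes(m)[c("n_excluded", "loci", "stratum")] <- NULL
  print(stats::addmargins(as.table(m)))
  invisible(x)
}

#' Export a contingency table as TSV with labeled margins
#'
#' @param x An `mdr_table`.
#' @param path Output file path.
#' @export
write_table_tsv <- function(x, path) {
  stopifnot(inherits(x, "mdr_table"))
  m <- stats::addmargins(as.table(unclass(x)[, , drop = FALSE]))
  d <- data.frame(cell = rownames(m), as.data.frame.matrix(m),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
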