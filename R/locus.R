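#' Define a genotyped locus
#'
#' A locus is a named polymorphism with an ordered set of genotype
#' categories and the allele composition of each category.  Biallelic
#' markers (SNPs and insertion/deletion variants) have three genotype
#' categories; a three-allele marker such as ApoE epsilon-2/3/4 has six.
#'
#' @param name Short identifier, used as the cohort column name.
#' @param alleles Character vector of allele labels (length 2 or 3).
#' @param genotypes Named list mapping each genotype category to the
#'   length-2 character vector of its alleles.  Category order is the
#'   order of this list and is preserved everywhere (tables, cell grids).
#' @return An object of class `mdr_locus`.
#' @examples
#' locus("ACE", alleles = c("D", "I"),
#'       genotypes = list(DD = c("D", "D"), ID = c("I", "D"), II = c("I", "I")))
#' @export
locus <- function(name, alleles, genotypes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  alleles <- as.character(alleles)
  if (anyDuplicated(alleles) || !length(alleles) %in% c(2L, 3L))
    stop("'alleles' must be 2 or 3 unique labels", call. = FALSE)
  categories <- names(genotypes)
  if (is.null(categories) || anyDuplicated(categories) || any(!nzchar(categories)))
    stop("'genotypes' must be a uniquely named list", call. = FALSE)
  n_expected <- length(alleles) * (length(alleles) + 1L) / 2L
  if (length(genotypes) != n_expected)
    stop(sprintf("locus '%s': %d alleles require %d genotype categories, got %d",
                 name, length(alleles), n_expected, length(genotypes)), call. = FALSE)
  for (g in categories) {
    pair <- genotypes[[g]]
    if (length(pair) != 2L || !all(pair %in% alleles))
      stop(sprintf("locus '%s': genotype '%s' must list exactly 2 known alleles",
                   name, g), call. = FALSE)
  }
  structure(
    list(name = name, categories = categories, alleles = alleles,
         genotypes = lapply(genotypes, as.character),
         allele_arity = length(alleles)),
    class = "mdr_locus")
}

#' @export
print.mdr_locus <- function(x, ...) {
  cat(sprintf("<locus> %s: %s (alleles %s)\n", x$name,
              paste(x$categories, collapse = "/"),
              paste(x$alleles, collapse = "/")))
  invisible(x)
}

#' The six candidate loci of the ischemic-stroke panel
#'
#' Returns the default locus set: ACE I/D, beta-fibrinogen T148C and
#' A455G, MTHFR C677T, ApoE epsilon-2/3/4 (six genotypes) and eNOS
#' G894T, in the conventional reporting order (locus 1..6).
#'
#' @return Named list of `mdr_locus` objects.
#' @export
default_loci <- function() {
  l <- list(
    locus("ACE", c("D", "I"),
          list(DD = c("D", "D"), ID = c("I", "D"), II = c("I", "I"))),
    locus("BFG_T148C", c("T", "C"),
          list(TT = c("T", "T"), CT = c("C", "T"), CC = c("C", "C"))),
    locus("BFG_A455G", c("A", "G"),
          list(AA = c("A", "A"), GA = c("G", "A"), GG = c("G", "G"))),
    locus("MTHFR_C677T", c("T", "C"),
          list(TT = c("T", "T"), CT = c("C", "T"), CC = c("C", "C"))),
    locus("APOE", c("e2", "e3", "e4"),
          list(e2e2 = c("e2", "e2"), e2e3 = c("e2", "e3"),
               e2e4 = c("e2", "e4"), e3e3 = c("e3", "e3"),
               e3e4 = c("e3", "e4"), e4e4 = c("e4", "e4"))),
    locus("ENOS_G894T", c("T", "G"),
          list(TT = c("T", "T"), GT = c("G", "T"), GG = c("G", "G"))))
  names(l) <- vapply(l, `[[`, "", "name")
  l
}

# copies of allele `a` carried by each genotype category of a locus
allele_dosage <- function(loc, a) {
  vapply(loc$genotypes, function(p) sum(p == a), integer(1))
}
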