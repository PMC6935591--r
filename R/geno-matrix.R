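#' Genotype matrix container
#'
#' A `geno_matrix` stores biallelic genotypes as an integer matrix of allele
#' counts (individuals in rows, loci in columns) with codes `0`, `1`, `2` and
#' `NA` for missing. Codes count copies of the locus's *counted* allele (the
#' ALT allele when read from VCF); allele labels are kept in the locus
#' metadata so polarity can be flipped downstream without re-reading. Two
#' metadata tibbles ride along as attributes:
#'
#' * `loci`: one row per locus — `locus`, `contig`, `class`
#'   (`"control"` or `"candidate"`), `ref`, `alt`.
#' * `individuals`: one row per individual — `individual`, `population`.
#'
#' @param codes Integer matrix of 0/1/2/NA allele counts with individual ids
#'   as rownames and locus ids as colnames.
#' @param loci Tibble of locus metadata (see above). Missing columns are
#'   filled with defaults (`contig` = locus id, `class` = `"candidate"`,
#'   `ref` = `"A"`, `alt` = `"B"`).
#' @param individuals Tibble mapping `individual` to `population`. Defaults to
#'   one population for all individuals.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(codes, loci = NULL, individuals = NULL) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) rownames(codes) <- paste0("ind_", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("locus_", seq_len(ncol(codes)))
  bad <- codes[!is.na(codes)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    abort("Genotype codes must be 0, 1, 2 or NA.")
  }
  storage.mode(codes) <- "integer"

  if (is.null(loci)) loci <- tibble(locus = colnames(codes))
  loci <- as_tibble(loci)
  if (!"locus" %in% names(loci)) abort("`loci` must have a `locus` column.")
  loci$locus <- as.character(loci$locus)
  if (!"contig" %in% names(loci)) loci$contig <- loci$locus
  if (!"class" %in% names(loci)) loci$class <- "candidate"
  if (!"ref" %in% names(loci)) loci$ref <- "A"
  if (!"alt" %in% names(loci)) loci$alt <- "B"
  if (!setequal(loci$locus, colnames(codes)) || nrow(loci) != ncol(codes)) {
    abort("`loci` must have exactly one row per genotype column.")
  }
  loci <- loci[match(colnames(codes), loci$locus), ]

  if (is.null(individuals)) {
    individuals <- tibble(individual = rownames(codes), population = "pop_1")
  }
  individuals <- as_tibble(individuals)
  if (!all(c("individual", "population") %in% names(individuals))) {
    abort("`individuals` must have `individual` and `population` columns.")
  }
  individuals$individual <- as.character(individuals$individual)
  if (!setequal(individuals$individual, rownames(codes)) ||
      nrow(individuals) != nrow(codes)) {
    abort("`individuals` must have exactly one row per genotype row.")
  }
  individuals <- individuals[match(rownames(codes), individuals$individual), ]

  structure(codes, loci = loci, individuals = individuals,
            class = c("geno_matrix", "matrix", "array"))
}

#' @export
print.geno_matrix <- function(x, ...) {
  li <- geno_loci(x)
  cat(sprintf("<geno_matrix> %d individuals x %d loci (%d control, %d candidate)\n",
              nrow(x), ncol(x), sum(li$class == "control"),
              sum(li$class == "candidate")))
  miss <- mean(is.na(unclass(x)))
  cat(sprintf("  missing: %.2f%%; populations: %d\n", 100 * miss,
              length(unique(geno_individuals(x)$population))))
  invisible(x)
}

#' Locus metadata of a genotype matrix
#' @param g A [geno_matrix()].
#' @return A tibble with one row per locus.
#' @export
geno_loci <- function(g) attr(g, "loci")

#' Individual metadata of a genotype matrix
#' @param g A [geno_matrix()].
#' @return A tibble with one row per individual.
#' @export
geno_individuals <- function(g) attr(g, "individuals")

#' Subset a genotype matrix keeping metadata in sync
#'
#' @param x A [geno_matrix()].
#' @param i,j Individual / locus indices (numeric, logical or ids).
#' @param drop Ignored; subsetting always returns a `geno_matrix`.
#' @param ... Unused.
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  attr(m, "loci") <- NULL
  attr(m, "individuals") <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  sub <- m[i, j, drop = FALSE]
  li <- attr(x, "loci")[match(colnames(sub), attr(x, "loci")$locus), ]
  ind <- attr(x, "individuals")[match(rownames(sub), attr(x, "individuals")$individual), ]
  geno_matrix(sub, loci = li, individuals = ind)
}

# Internal: raw integer matrix without the class baggage.
geno_codes <- function(g) {
  m <- unclass(g)
  attr(m, "loci") <- NULL
  attr(m, "individuals") <- NULL
  m
}
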