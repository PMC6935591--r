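#' Read a genotype matrix
#'
#' Reads genotypes either from a 0/1/2 TSV matrix (individuals in rows, a
#' header row of locus ids, first column `individual`) with an optional locus
#' metadata sidecar, or from a VCF (v4.x) of biallelic SNPs. VCF genotype
#' codes count copies of the ALT allele; `./.` becomes missing.
#' Multi-allelic VCF records are skipped with a warning.
#'
#' @param path File path.
#' @param format `"matrix"` or `"vcf"`.
#' @param loci_path Optional path to a locus metadata TSV with columns
#'   `locus`, `contig`, `class` (and optionally `ref`, `alt`).
#' @param individuals Optional tibble mapping `individual` to `population`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf"),
                           loci_path = NULL, individuals = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  loci <- if (!is.null(loci_path)) {
    readr::read_tsv(loci_path, show_col_types = FALSE)
  } else {
    NULL
  }
  if (format == "matrix") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    ids <- as.character(tab[[1]])
    codes <- as.matrix(tab[, -1, drop = FALSE])
    rownames(codes) <- ids
    return(geno_matrix(codes, loci = loci, individuals = individuals))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    warn(sprintf("Skipping %d non-biallelic-SNP record(s).", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!nrow(fix)) abort("No biallelic SNP records in VCF.")
  alt_count <- function(s) {
    s <- sub(":.*", "", s)
    out <- rep(NA_integer_, length(s))
    known <- !is.na(s) & grepl("^[01]([/|][01])?$", s)
    if (any(!known & !is.na(s) & !grepl("\\.", s))) {
      abort("Malformed genotype field in VCF.")
    }
    out[known] <- vapply(strsplit(s[known], "[/|]"),
                         function(a) sum(as.integer(a)), integer(1))
    out
  }
  codes <- t(apply(gt, 1L, alt_count))
  if (ncol(gt) == 1L) codes <- matrix(codes, ncol = 1L)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  rownames(codes) <- NULL
  codes <- t(codes)
  colnames(codes) <- ids
  rownames(codes) <- colnames(gt)
  cls <- rep("candidate", nrow(fix))
  info_cls <- regmatches(fix$INFO, regexpr("CLASS=[^;]+", fix$INFO))
  if (length(info_cls) == nrow(fix)) cls <- sub("CLASS=", "", info_cls)
  meta <- tibble(locus = ids, contig = fix$CHROM, class = cls,
                 ref = fix$REF, alt = fix$ALT)
  if (!is.null(loci)) {
    meta <- meta[, c("locus", "ref", "alt")]
    meta <- dplyr::left_join(meta, as_tibble(loci), by = "locus")
    if (!"contig" %in% names(meta)) meta$contig <- meta$locus
    if (!"class" %in% names(meta)) meta$class <- "candidate"
  }
  geno_matrix(codes, loci = meta, individuals = individuals)
}

#' Write a genotype matrix
#'
#' `format = "matrix"` writes the 0/1/2 TSV (plus a locus metadata sidecar
#' when `loci_path` is given); `format = "vcf"` writes a minimal plain-text
#' VCF v4.2 with one sample column per individual and the class recorded in
#' INFO.
#'
#' @param g A [geno_matrix()].
#' @param path Output file.
#' @param format `"matrix"` or `"vcf"`.
#' @param loci_path Optional sidecar TSV path for locus metadata.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("matrix", "vcf"),
                            loci_path = NULL) {
  format <- match.arg(format)
  codes <- geno_codes(g)
  li <- geno_loci(g)
  if (!is.null(loci_path)) readr::write_tsv(li, loci_path)
  if (format == "matrix") {
    tab <- dplyr::bind_cols(tibble(individual = rownames(codes)),
                            as_tibble(as.data.frame(codes)))
    readr::write_tsv(tab, path)
    return(invisible(path))
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[codes + 1L], nrow = nrow(codes))
  gt_str[is.na(codes)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Locus class\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(codes)), collapse = "\t"))
  body <- vapply(seq_len(ncol(codes)), function(j) {
    paste(c(li$contig[j], j, li$locus[j], li$ref[j], li$alt[j], ".", ".",
            paste0("CLASS=", li$class[j]), "GT", gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter loci by minor allele frequency
#'
#' Removes loci whose overall minor-allele frequency, computed over
#' non-missing alleles across all individuals, is below `threshold`
#' (the comparison is inclusive: MAF equal to the threshold is retained).
#'
#' @param g A [geno_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return A filtered [geno_matrix()].
#' @export
filter_maf <- function(g, threshold = 0.01) {
  assert_scalar_in(threshold, 0, 0.5, "threshold")
  codes <- geno_codes(g)
  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- which(maf >= threshold)
  g[, keep]
}

#' Cross-validate a dataset's tables
#'
#' Checks id consistency between genotypes, panel, climate and phenotypes;
#' reports orphan individuals/populations, genotype missingness, locus class
#' counts and absent bioclimatic variables. Id mismatch between genotypes
#' and phenotypes is fatal.
#'
#' @param genotypes A [geno_matrix()].
#' @param panel Population panel tibble (`population`, coordinates, `n`).
#' @param climate Climate tibble (`population` + variables).
#' @param phenotypes Phenotype tibble (`individual`, `population`, `block`,
#'   `location`, traits).
#' @param climate_vars Variable names expected in `climate`.
#' @return A list of class `validation_report` with `errors` (character),
#'   `warnings` (character) and `summary` (list); `errors` is empty for a
#'   consistent dataset.
#' @export
validate_dataset <- function(genotypes, panel, climate = NULL,
                             phenotypes = NULL, climate_vars = bioclim_names) {
  errors <- character()
  warnings <- character()
  ind <- geno_individuals(genotypes)
  li <- geno_loci(genotypes)

  orphan_pops <- setdiff(ind$population, panel$population)
  if (length(orphan_pops)) {
    errors <- c(errors, sprintf(
      "%d genotyped population(s) absent from panel: %s", length(orphan_pops),
      paste(utils::head(orphan_pops, 5), collapse = ", ")))
  }
  if (!is.null(phenotypes)) {
    bad_ind <- setdiff(phenotypes$individual, ind$individual)
    if (length(bad_ind)) {
      errors <- c(errors, sprintf(
        "%d phenotyped individual(s) absent from genotypes: %s",
        length(bad_ind), paste(utils::head(bad_ind, 5), collapse = ", ")))
    }
    bad_pop <- setdiff(phenotypes$population, panel$population)
    if (length(bad_pop)) {
      errors <- c(errors, sprintf(
        "%d phenotype row population(s) absent from panel: %s",
        length(bad_pop), paste(utils::head(bad_pop, 5), collapse = ", ")))
    }
  }
  if (!is.null(climate)) {
    missing_vars <- setdiff(climate_vars, names(climate))
    if (length(missing_vars)) {
      warnings <- c(warnings, sprintf("climate table missing variable(s): %s",
                                      paste(missing_vars, collapse = ", ")))
    }
    no_clim <- setdiff(ind$population, climate$population)
    if (length(no_clim)) {
      warnings <- c(warnings, sprintf(
        "%d population(s) lack climate rows", length(no_clim)))
    }
  }
  summary <- list(
    n_individuals = nrow(ind),
    n_populations = length(unique(ind$population)),
    n_loci = ncol(genotypes),
    class_counts = table(li$class),
    missingness = mean(is.na(geno_codes(genotypes)))
  )
  structure(list(errors = errors, warnings = warnings, summary = summary),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  ERROR:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  s <- x$summary
  cat(sprintf("  %d individuals / %d populations / %d loci; missing %.2f%%\n",
              s$n_individuals, s$n_populations, s$n_loci,
              100 * s$missingness))
  invisible(x)
}
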