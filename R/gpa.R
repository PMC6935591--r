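#' Structure-corrected genotype-phenotype association scan
#'
#' Mixed-linear-model association of per-locus allele counts against an
#' adjusted phenotype: `y = mu + x beta + g + e`, with polygenic effect
#' `g ~ N(0, sigma2_g * GRM)`. The two variance components are estimated
#' once on the null model by REML via eigendecomposition of the GRM and then
#' held fixed while each locus is tested by generalized least squares with a
#' Wald p-value — the standard MLMA convention. Missing genotypes are
#' mean-imputed per locus; monomorphic loci get `beta = 0`, `p = 1` and a
#' flag.
#'
#' @param genotypes A [geno_matrix()]; loci to scan selected by `loci`
#'   (default: candidate-class loci).
#' @param phenotype Tibble `individual`, `residual` (one adjusted trait, as
#'   from [adjusted_phenotypes()]), or a named numeric vector.
#' @param grm GRM from [compute_grm()] (control loci).
#' @param loci Locus ids to scan.
#' @param trait Trait label for the output.
#' @param lambda Optional fixed variance ratio `sigma2_g / sigma2_e`
#'   (bypasses the null REML); `lambda = 0` reduces every test to ordinary
#'   least squares.
#' @return A tibble of class `mlma_result`: `locus`, `contig`, `trait`,
#'   `beta` (per copy of the counted allele), `se`, `p_value`,
#'   `counted_allele`, `other_allele`, `monomorphic`; attributes `sigma2_g`,
#'   `sigma2_e` carry the null-model variance components.
#' @export
mlma_scan <- function(genotypes, phenotype, grm, loci = NULL, trait = "trait",
                      lambda = NULL) {
  li <- geno_loci(genotypes)
  loci <- loci %||% li$locus[li$class == "candidate"]
  if (is.data.frame(phenotype)) {
    y <- setNames(phenotype$residual, phenotype$individual)
    if ("trait" %in% names(phenotype) && length(unique(phenotype$trait)) == 1) {
      trait <- phenotype$trait[1]
    }
  } else {
    y <- phenotype
  }
  ids <- intersect(names(y), rownames(grm))
  ids <- ids[!is.na(y[ids])]
  if (length(ids) < 10) abort("Too few phenotyped individuals in the GRM.")
  y <- y[ids]
  K <- grm[ids, ids]
  X <- geno_codes(genotypes)[ids, loci, drop = FALSE]

  ek <- eigen(K, symmetric = TRUE)
  U <- ek$vectors
  d <- pmax(ek$values, 0)
  yr <- drop(crossprod(U, y))
  one_r <- drop(crossprod(U, rep(1, length(y))))

  # Null-model REML over lambda = sigma2_g / sigma2_e
  reml_nll <- function(log_lambda) {
    lam <- exp(log_lambda)
    v <- lam * d + 1
    w <- 1 / v
    xwx <- sum(one_r^2 * w)
    bhat <- sum(one_r * yr * w) / xwx
    r <- yr - one_r * bhat
    n <- length(yr)
    s2 <- sum(r^2 * w) / (n - 1)
    0.5 * (sum(log(v)) + (n - 1) * log(s2) + log(xwx))
  }
  lam <- if (!is.null(lambda)) {
    stopifnot(lambda >= 0)
    lambda
  } else {
    exp(optimize(reml_nll, c(-10, 10))$minimum)
  }
  v <- lam * d + 1
  w <- 1 / v
  xwx <- sum(one_r^2 * w)
  bhat <- sum(one_r * yr * w) / xwx
  sigma2_e <- sum((yr - one_r * bhat)^2 * w) / (length(yr) - 1)
  sigma2_g <- lam * sigma2_e

  # Per-locus GLS with components fixed: weights w / sigma2_e
  p_loc <- colMeans(X, na.rm = TRUE) / 2
  mono <- !is.finite(p_loc) | p_loc <= 0 | p_loc >= 1
  Ximp <- X
  for (j in which(colSums(is.na(X)) > 0)) {
    Ximp[is.na(X[, j]), j] <- 2 * p_loc[j]
  }
  Ximp[, mono] <- 0
  Xr <- crossprod(U, Ximp)

  sw <- w / sigma2_e
  a11 <- sum(one_r^2 * sw)
  a1y <- sum(one_r * yr * sw)
  a1x <- drop(crossprod(Xr, one_r * sw))
  axx <- drop(crossprod(Xr^2, sw))
  axy <- drop(crossprod(Xr, yr * sw))
  det_ <- a11 * axx - a1x^2
  beta <- (a11 * axy - a1x * a1y) / det_
  se <- sqrt(a11 / det_)
  chi2 <- (beta / se)^2
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  beta[mono] <- 0
  se[mono] <- NA_real_
  p[mono] <- 1

  meta <- li[match(loci, li$locus), ]
  out <- tibble(locus = loci, contig = meta$contig, trait = trait,
                beta = unname(beta), se = unname(se), p_value = unname(p),
                counted_allele = meta$alt, other_allele = meta$ref,
                monomorphic = unname(mono))
  class(out) <- c("mlma_result", class(out))
  attr(out, "sigma2_g") <- sigma2_g
  attr(out, "sigma2_e") <- sigma2_e
  attr(out, "n") <- length(y)
  out
}

#' Keep the strongest association per contig
#'
#' Retains, for each contig, the locus with the smallest p-value (ties
#' broken by locus id) to reduce redundancy from physical linkage.
#'
#' @param results An association tibble with `locus`, `contig`, `p_value`.
#' @return The filtered tibble (one row per contig).
#' @export
reduce_one_per_contig <- function(results) {
  ord <- order(results$contig, results$p_value, results$locus)
  r <- results[ord, ]
  r[!duplicated(r$contig), ]
}

#' Bottom-fraction candidate selection
#'
#' Selects the `ceiling(fraction * pool size)` loci with the smallest
#' p-values; boundary ties broken by descending `|beta|`, then locus id.
#' With a one-per-contig pool of 18,525 loci the default 1% fraction yields
#' 186 candidates.
#'
#' @param results Deduplicated association tibble.
#' @param fraction Selection fraction in (0, 1); default 0.01.
#' @return The selected rows (a tibble of class `candidate_set`), ordered by
#'   increasing p-value, with attribute `rule` describing the selection.
#' @export
select_candidates <- function(results, fraction = 0.01) {
  assert_scalar_in(fraction, 0, 1, "fraction", open_lo = TRUE, open_hi = TRUE)
  n_sel <- as.integer(ceiling(fraction * nrow(results)))
  ord <- order(results$p_value, -abs(results$beta), results$locus)
  out <- results[ord[seq_len(n_sel)], ]
  class(out) <- c("candidate_set", class(out))
  attr(out, "rule") <- sprintf("bottom %.3g%% of %d p-values (n = %d)",
                               100 * fraction, nrow(results), n_sel)
  out
}

#' Polarize to the positive effect allele
#'
#' Identifies, per locus, the allele whose count increases the trait — the
#' positive effect allele (PEA) — from the sign of the regression slope, and
#' reports `beta` per PEA copy (non-negative). Loci with exactly zero slope
#' keep the counted allele as PEA and are flagged.
#'
#' @param results Association tibble with `beta`, `counted_allele`,
#'   `other_allele`.
#' @return The tibble with added `pea_allele`, `pea_is_counted`,
#'   `zero_beta`, and `beta` replaced by its magnitude.
#' @export
polarize_pea <- function(results) {
  pos <- results$beta >= 0
  results$pea_allele <- ifelse(pos, results$counted_allele,
                               results$other_allele)
  results$pea_is_counted <- pos
  results$zero_beta <- results$beta == 0
  results$beta <- abs(results$beta)
  results
}
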