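#' Genomic relationship matrix from control loci
#'
#' VanRaden-form GRM: each locus is centered at `2p` and scaled to variance
#' `2p(1-p)` (with `p` the overall counted-allele frequency over non-missing
#' genotypes), missing genotypes are mean-imputed per locus, and
#' `GRM = Z Z' / L`. Loci fixed in the sample (`p` of 0 or 1) are excluded.
#'
#' @param g A [geno_matrix()].
#' @param loci Locus ids to use; defaults to the control-class loci.
#' @return A symmetric individuals x individuals matrix with a `loci`
#'   attribute naming the loci used.
#' @export
compute_grm <- function(g, loci = NULL) {
  li <- geno_loci(g)
  loci <- loci %||% li$locus[li$class == "control"]
  if (length(loci) < 2) abort("Need at least 2 loci to build a GRM.")
  X <- geno_codes(g)[, loci, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(X, 2L, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centering
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(X), rownames(X))
  attr(K, "loci") <- colnames(X)
  K
}

#' Population allele-frequency table
#'
#' Per-population frequency of a designated allele at each locus:
#' allele count / (2 x non-missing individuals). `allele = "counted"` uses
#' the stored counted allele; `"minor"` flips loci whose overall frequency
#' exceeds 0.5 so the rarer allele is tracked; `"pea"` flips according to a
#' polarization table (see [polarize_pea()]).
#'
#' @param g A [geno_matrix()].
#' @param loci Locus ids (default all).
#' @param allele `"counted"`, `"minor"` or `"pea"`.
#' @param pea Tibble `locus`, `pea_is_counted` (logical), required for
#'   `allele = "pea"`.
#' @return A populations x loci frequency matrix with attribute `n_alleles`
#'   (matrix of non-missing allele counts `2n`) and `flipped` (logical per
#'   locus). Populations with an all-missing locus get `NA`.
#' @export
pop_allele_frequencies <- function(g, loci = NULL,
                                   allele = c("counted", "minor", "pea"),
                                   pea = NULL) {
  allele <- match.arg(allele)
  li <- geno_loci(g)
  loci <- loci %||% li$locus
  X <- geno_codes(g)[, loci, drop = FALSE]
  pop <- geno_individuals(g)$population
  pops <- unique(pop)
  cnt <- rowsum(ifelse(is.na(X), 0L, X), pop, reorder = FALSE)
  nn <- rowsum((!is.na(X)) * 2L, pop, reorder = FALSE)
  freq <- cnt / nn
  freq[nn == 0] <- NA_real_
  freq <- freq[match(pops, rownames(cnt)), , drop = FALSE]
  nn <- nn[match(pops, rownames(cnt)), , drop = FALSE]
  flipped <- rep(FALSE, length(loci))
  if (allele == "minor") {
    overall <- colSums(ifelse(is.na(X), 0L, X)) / colSums((!is.na(X)) * 2L)
    flipped <- overall > 0.5
  } else if (allele == "pea") {
    if (is.null(pea)) abort("`pea` table required for allele = \"pea\".")
    m <- match(loci, pea$locus)
    if (anyNA(m)) abort("`pea` table lacks some requested loci.")
    flipped <- !pea$pea_is_counted[m]
  }
  if (any(flipped)) {
    freq[, flipped] <- 1 - freq[, flipped]
  }
  attr(freq, "n_alleles") <- nn
  attr(freq, "flipped") <- setNames(flipped, loci)
  freq
}

#' Covariance of standardized population allele frequencies
#'
#' Estimates the populations x populations covariance `Omega` that captures
#' shared drift, from control-locus frequencies. Each locus is standardized
#' as `x_k = (p_k - pbar) / sqrt(pbar (1 - pbar))` with `pbar` the
#' across-population mean. Each run computes the sample covariance over a
#' bootstrap resample of loci, augments the diagonal with the mean binomial
#' sampling variance `1/(2 n_k)` and a small ridge for positive
#' semi-definiteness; `Omega` is the average over `n_runs` runs. The
#' individual runs serve as independent "chains" for consensus filtering in
#' the environment-association scan.
#'
#' @param freq Populations x loci frequency matrix (from
#'   [pop_allele_frequencies()] on control loci), with its `n_alleles`
#'   attribute or `n_alleles` supplied.
#' @param n_runs Number of bootstrap runs (default 3).
#' @param seed Integer seed.
#' @param ridge Ridge added to the diagonal; default `1e-6 * trace / P`.
#' @param n_alleles Optional matrix of per-population, per-locus allele
#'   counts `2n`; defaults to the attribute on `freq`.
#' @param bootstrap Resample loci per run (TRUE, default). With FALSE all
#'   runs use the full locus set and are identical.
#' @return A list of class `pop_cov`: `omega` (average), `runs` (list of
#'   per-run matrices), `loci` used, `ridge`.
#' @export
estimate_pop_covariance <- function(freq, n_runs = 3, seed = NULL,
                                    ridge = NULL, n_alleles = NULL,
                                    bootstrap = TRUE) {
  n_alleles <- n_alleles %||% attr(freq, "n_alleles")
  P <- nrow(freq)
  L <- ncol(freq)
  if (L < P) warn("Fewer control loci than populations; ridge may need raising.")
  pbar <- colMeans(freq, na.rm = TRUE)
  ok <- is.finite(pbar) & pbar > 0 & pbar < 1
  Xs <- sweep(freq[, ok, drop = FALSE], 2L, pbar[ok]) |>
    sweep(2L, sqrt(pbar[ok] * (1 - pbar[ok])), `/`)
  Xs[is.na(Xs)] <- 0
  L <- ncol(Xs)
  if (L < 2) abort("Need at least 2 polymorphic control loci.")
  diag_aug <- if (!is.null(n_alleles)) {
    rowMeans(1 / pmax(n_alleles[, ok, drop = FALSE], 2), na.rm = TRUE)
  } else {
    rep(0, P)
  }
  runs <- with_seed(seed, {
    lapply(seq_len(n_runs), function(r) {
      idx <- if (bootstrap) sample.int(L, L, replace = TRUE) else seq_len(L)
      S <- tcrossprod(Xs[, idx, drop = FALSE]) / length(idx)
      S <- S + diag(diag_aug, P)
      eps <- ridge %||% (1e-6 * sum(diag(S)) / P)
      S + diag(eps, P)
    })
  })
  omega <- Reduce(`+`, runs) / n_runs
  dimnames(omega) <- list(rownames(freq), rownames(freq))
  runs <- lapply(runs, `dimnames<-`, dimnames(omega))
  structure(list(omega = omega, runs = runs, loci = colnames(Xs),
                 ridge = ridge %||% "1e-6*trace/P"),
            class = "pop_cov")
}

#' @export
print.pop_cov <- function(x, ...) {
  cat(sprintf("<pop_cov> %d populations, %d runs, %d control loci\n",
              nrow(x$omega), length(x$runs), length(x$loci)))
  invisible(x)
}

#' Principal components of a predictor table
#'
#' Column-centered (and optionally unit-scaled) PCA via singular value
#' decomposition, with mean imputation of missing cells, removal of
#' zero-variance columns (warning), and a deterministic sign convention
#' (each component's largest-magnitude loading is positive).
#'
#' @param table Observations x variables matrix or data frame (numeric).
#' @param standardize Scale columns to unit variance (default TRUE).
#' @param m Number of components to keep (default all).
#' @return A list of class `pc_result`: `scores` (obs x m), `loadings`,
#'   `var_explained` (fractions), `center`, `scale`.
#' @export
principal_components <- function(table, standardize = TRUE, m = NULL) {
  X <- as.matrix(as.data.frame(table))
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  v <- apply(X, 2L, var)
  if (any(v == 0)) {
    warn(sprintf("Dropping %d zero-variance column(s).", sum(v == 0)))
    X <- X[, v > 0, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = standardize)
  m <- min(m %||% ncol(pc$x), ncol(pc$x))
  scores <- pc$x[, seq_len(m), drop = FALSE]
  loadings <- pc$rotation[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center, scale = pc$scale),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  ve <- utils::head(x$var_explained, 5)
  cat(sprintf("<pc_result> %d x %d scores; var explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * ve), collapse = " ")))
  invisible(x)
}
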