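# Internal CV engine: regress `y` on the columns of `Z` with `folds`-fold
# cross-validation over observations; R2 pooled over held-out folds,
# 1 - sum(SSE)/sum(SST), with SST around each fold's training mean.
# folds = 1 is training mode (ordinary in-sample R2).
cv_r2 <- function(y, Z, folds = 5, seed = NULL) {
  Z <- as.matrix(Z)
  ok <- is.finite(y) & stats::complete.cases(Z)
  y <- y[ok]
  Z <- Z[ok, , drop = FALSE]
  n <- length(y)
  if (folds == 1) {
    fit <- stats::lm.fit(cbind(1, Z), y)
    return(1 - sum(fit$residuals^2) / sum((y - mean(y))^2))
  }
  if (n < folds) {
    warn(sprintf("Only %d observations; reducing folds from %d.", n, folds))
    folds <- n
  }
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  sse <- sst <- 0
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    fit <- stats::lm.fit(cbind(1, Z[tr, , drop = FALSE]), y[tr])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    pred <- drop(cbind(1, Z[!tr, , drop = FALSE]) %*% cf)
    sse <- sse + sum((y[!tr] - pred)^2)
    sst <- sst + sum((y[!tr] - mean(y[tr]))^2)
  }
  1 - sse / sst
}

#' Cumulative-PC cross-validated R-squared curve
#'
#' The comparison engine for predictor sets: principal components are
#' extracted once from the full predictor table, then for each `m` in
#' `1..m_max` the response is regressed on the first `m` PCs with
#' `folds`-fold cross-validation over populations. R-squared is pooled over
#' held-out folds (`1 - sum(SSE)/sum(SST)`); it may be negative for
#' uninformative predictors. `folds = 1` gives in-sample (training) R².
#'
#' @param response Named numeric vector of population-mean phenotype (names
#'   are populations) or tibble `population`, `value`.
#' @param predictors Populations x variables table (rows aligned to
#'   `response` by name when both are named).
#' @param m_max Largest number of PCs (default: full rank).
#' @param folds CV folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param standardize Unit-scale predictor columns before PCA.
#' @param set Label of the predictor set (e.g. "climate").
#' @param trait Optional trait label.
#' @return A tibble of class `ev_curve`: `set`, `trait`, `m`, `r2_cv`.
#' @export
cv_r2_curve <- function(response, predictors, m_max = NULL, folds = 5,
                        seed = NULL, standardize = TRUE, set = "predictors",
                        trait = NA_character_) {
  if (is.data.frame(response)) {
    response <- setNames(response$value, response$population)
  }
  P <- as.matrix(as.data.frame(predictors))
  if (!is.null(names(response)) && !is.null(rownames(P))) {
    common <- intersect(names(response), rownames(P))
    response <- response[common]
    P <- P[common, , drop = FALSE]
  }
  pc <- principal_components(P, standardize = standardize)
  m_max <- min(m_max %||% ncol(pc$scores), ncol(pc$scores))
  # same fold assignment for every m so the curve varies only through m
  r2 <- vapply(seq_len(m_max), function(m) {
    cv_r2(response, pc$scores[, seq_len(m), drop = FALSE], folds = folds,
          seed = seed)
  }, numeric(1))
  out <- tibble(set = set, trait = trait, m = seq_len(m_max), r2_cv = r2)
  class(out) <- c("ev_curve", class(out))
  out
}

#' Mutually exclusive control-set subsamples
#'
#' Draws `floor(pool / size)` disjoint subsets of `size` loci from the
#' control pool without replacement, for rarefaction of the control set to
#' the size of a candidate set.
#'
#' @param control_loci Character vector of control locus ids.
#' @param size Subsample size (default 186).
#' @param seed Integer seed.
#' @return A list of character vectors (pairwise disjoint).
#' @export
rarefy_control <- function(control_loci, size = 186, seed = NULL) {
  if (size > length(control_loci)) abort("`size` exceeds the control pool.")
  n_sub <- length(control_loci) %/% size
  with_seed(seed, {
    perm <- sample(control_loci)
    lapply(seq_len(n_sub), function(i) perm[((i - 1) * size + 1):(i * size)])
  })
}

#' Rarefaction curves over control subsamples
#'
#' Computes a [cv_r2_curve()] per disjoint control subsample and summarizes
#' the spread (min / median / max of `r2_cv`) per number of PCs.
#'
#' @param response Population-mean phenotype (see [cv_r2_curve()]).
#' @param freq Populations x loci frequency matrix covering the control
#'   pool.
#' @param subsets List of locus-id vectors from [rarefy_control()].
#' @inheritParams cv_r2_curve
#' @return A list: `curves` (stacked `ev_curve` with a `subset` column) and
#'   `summary` (tibble `m`, `r2_min`, `r2_median`, `r2_max`).
#' @export
rarefaction_curves <- function(response, freq, subsets, m_max = NULL,
                               folds = 5, seed = NULL, trait = NA_character_) {
  curves <- purrr::imap(subsets, function(loci, i) {
    cv <- cv_r2_curve(response, freq[, loci, drop = FALSE], m_max = m_max,
                      folds = folds, seed = child_seed(seed, i) %||% seed,
                      set = "control_rarefied", trait = trait)
    cv$subset <- i
    cv
  })
  curves <- dplyr::bind_rows(curves)
  summary <- curves |>
    dplyr::group_by(.data$m) |>
    dplyr::summarise(r2_min = min(.data$r2_cv),
                     r2_median = median(.data$r2_cv),
                     r2_max = max(.data$r2_cv), .groups = "drop")
  list(curves = curves, summary = summary)
}

#' Calibrate the climate-association threshold on the control set
#'
#' For each control locus, computes the in-sample R-squared of a multiple
#' linear regression of its population-mean allele frequency on the first
#' `n_pcs` principal components of the climate variables, and takes the
#' stated percentile of that null distribution as the threshold for calling
#' a locus climate-associated.
#'
#' @param control_freq Populations x control-loci frequency matrix.
#' @param climate Climate tibble (`population` + variables).
#' @param percentile Percentile of the control R² distribution (default
#'   99.7).
#' @param n_pcs Climate PCs used (default 5).
#' @param climate_vars Variables to use (default: all numeric columns).
#' @return A list of class `assoc_threshold`: `threshold`, `percentile`,
#'   `r2` (per-locus vector), `n_pcs`.
#' @export
calibrate_threshold <- function(control_freq, climate, percentile = 99.7,
                                n_pcs = 5, climate_vars = NULL) {
  assert_scalar_in(percentile, 0, 100, "percentile")
  cpc <- climate_pcs(climate, n_pcs, climate_vars,
                     populations = rownames(control_freq))
  r2 <- locus_climate_r2(control_freq, cpc)
  structure(list(threshold = unname(quantile(r2, percentile / 100)),
                 percentile = percentile, r2 = r2, n_pcs = ncol(cpc)),
            class = "assoc_threshold")
}

#' @export
print.assoc_threshold <- function(x, ...) {
  cat(sprintf("<assoc_threshold> R2 > %.3f (%.1fth percentile of %d control loci, %d climate PCs)\n",
              x$threshold, x$percentile, length(x$r2), x$n_pcs))
  invisible(x)
}

# Climate PC scores aligned to a population ordering.
climate_pcs <- function(climate, n_pcs = 5, climate_vars = NULL,
                        populations = NULL) {
  climate_vars <- climate_vars %||%
    setdiff(names(climate)[vapply(climate, is.numeric, logical(1))],
            "population")
  M <- as.matrix(climate[, climate_vars, drop = FALSE])
  rownames(M) <- climate$population
  if (!is.null(populations)) M <- M[populations, , drop = FALSE]
  principal_components(M, standardize = TRUE, m = n_pcs)$scores
}

# In-sample R2 of freq ~ design, per locus (vectorized over loci).
locus_climate_r2 <- function(freq, design) {
  X <- cbind(1, design)
  Y <- as.matrix(freq)
  Y[is.na(Y)] <- matrix(colMeans(Y, na.rm = TRUE), nrow(Y), ncol(Y),
                        byrow = TRUE)[is.na(Y)]
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  sst <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  r2 <- 1 - colSums(res^2) / sst
  r2[sst == 0] <- 0
  setNames(r2, colnames(freq))
}

#' Select climate-associated candidate loci
#'
#' Retains the candidate loci whose population-frequency regression on the
#' first `n_pcs` climate PCs exceeds the threshold (strictly).
#'
#' @param candidate_freq Populations x candidate-loci frequency matrix.
#' @param climate Climate tibble.
#' @param threshold Numeric cutoff or an [calibrate_threshold()] result
#'   (default 0.35).
#' @param n_pcs Climate PCs (default 5).
#' @param climate_vars Optional variable subset.
#' @return A tibble `locus`, `r2`, `selected`; attribute `threshold`.
#' @export
select_climate_associated <- function(candidate_freq, climate,
                                      threshold = 0.35, n_pcs = 5,
                                      climate_vars = NULL) {
  if (inherits(threshold, "assoc_threshold")) threshold <- threshold$threshold
  cpc <- climate_pcs(climate, n_pcs, climate_vars,
                     populations = rownames(candidate_freq))
  r2 <- locus_climate_r2(candidate_freq, cpc)
  out <- tibble(locus = names(r2), r2 = unname(r2),
                selected = unname(r2 > threshold))
  attr(out, "threshold") <- threshold
  out
}
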