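#' Variance of one climate variable explained by a predictor set
#'
#' Regression with the climate variable as the *response*: in genomic mode
#' the predictors are the first `n_pcs` principal components of the supplied
#' table (population-mean minor-allele frequencies of the variable's top GEA
#' loci); in direct mode the table's columns are used as-is (e.g. the four
#' population-mean standardized traits, or per-site provenance-trial
#' heights). Reports the pooled fivefold cross-validated R-squared.
#'
#' @param climate Climate tibble (`population` + variables).
#' @param variable Climate variable name (the response).
#' @param predictors Populations x variables table.
#' @param mode `"pcs"` (PCA first) or `"direct"`.
#' @param n_pcs Number of PCs in `"pcs"` mode (default 4); if fewer are
#'   available the available ones are used with a warning.
#' @param folds CV folds (default 5). `folds = 1` gives training R².
#' @param seed Integer seed for folds.
#' @return A single numeric `r2_cv`.
#' @export
driver_r2 <- function(climate, variable, predictors, mode = c("pcs", "direct"),
                      n_pcs = 4, folds = 5, seed = NULL) {
  mode <- match.arg(mode)
  y <- setNames(climate[[variable]], climate$population)
  P <- as.matrix(as.data.frame(predictors))
  if (!is.null(rownames(P))) {
    common <- intersect(names(y), rownames(P))
    y <- y[common]
    P <- P[common, , drop = FALSE]
  }
  Z <- if (mode == "pcs") {
    pc <- principal_components(P, standardize = FALSE)
    if (ncol(pc$scores) < n_pcs) {
      warn(sprintf("Only %d PCs available (requested %d).",
                   ncol(pc$scores), n_pcs))
      n_pcs <- ncol(pc$scores)
    }
    pc$scores[, seq_len(n_pcs), drop = FALSE]
  } else {
    P
  }
  cv_r2(y, Z, folds = folds, seed = seed)
}

#' Rank climate variables as drivers of local adaptation
#'
#' Applies [driver_r2()] to every climate variable for each data source and
#' ranks variables by explained variance within source. For the genomic
#' source, per-variable predictor tables (top GEA loci frequencies) are
#' produced by `predictor_fun(variable)`.
#'
#' @param climate Climate tibble.
#' @param sources Named list; each element is either a fixed predictor table
#'   (used for every variable, `mode = "direct"`) or a function
#'   `function(variable)` returning the per-variable table
#'   (`mode = "pcs"`).
#' @param variables Variables to rank (default: all numeric columns).
#' @param n_pcs,folds,seed Passed to [driver_r2()].
#' @return A tibble of class `driver_ranking`: `variable`, `source`,
#'   `r2_cv`, `rank` (1 = most explained within source).
#' @export
rank_climate_drivers <- function(climate, sources, variables = NULL,
                                 n_pcs = 4, folds = 5, seed = NULL) {
  variables <- variables %||%
    setdiff(names(climate)[vapply(climate, is.numeric, logical(1))],
            "population")
  out <- purrr::imap(sources, function(src, nm) {
    per_var <- is.function(src)
    r2 <- vapply(variables, function(v) {
      pred <- if (per_var) src(v) else src
      driver_r2(climate, v, pred, mode = if (per_var) "pcs" else "direct",
                n_pcs = n_pcs, folds = folds, seed = seed)
    }, numeric(1))
    tibble(variable = variables, source = nm, r2_cv = unname(r2))
  })
  out <- dplyr::bind_rows(out) |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(rank = rank_with_id(.data$r2_cv, .data$variable)) |>
    dplyr::ungroup()
  class(out) <- c("driver_ranking", class(out))
  out
}

#' Quadratic climate-height fit across provenance-trial sites
#'
#' For each trial site, fits population-mean height as a quadratic function
#' of one provenance climate variable by OLS and computes the adjusted
#' R-squared `1 - (1 - R2)(n - 1)/(n - 3)`; returns the mean over sites.
#'
#' @param heights Tibble `site`, `population`, `height` (population-mean
#'   height per site).
#' @param climate_values Named numeric vector of the climate variable per
#'   population.
#' @return A list: `mean_adj_r2`, `by_site` (tibble `site`, `n`, `adj_r2`).
#' @export
quadratic_height_r2 <- function(heights, climate_values) {
  by_site <- heights |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(function(d, key) {
      x <- climate_values[d$population]
      ok <- is.finite(x) & is.finite(d$height)
      n <- sum(ok)
      if (n <= 3) abort(sprintf(
        "Site %s has %d populations; adjusted R2 needs > 3.", key$site, n))
      fit <- lm(d$height[ok] ~ x[ok] + I(x[ok]^2))
      r2 <- summary(fit)$r.squared
      tibble(n = n, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 3))
    }) |>
    dplyr::ungroup()
  list(mean_adj_r2 = mean(by_site$adj_r2), by_site = by_site)
}

#' Congruence of driver rankings between data sources
#'
#' Pearson correlation (with Spearman alongside) between two sources'
#' explained-variance vectors across climate variables.
#'
#' @param ranking_a,ranking_b Tibbles `variable`, `r2_cv` (e.g. rows of a
#'   [rank_climate_drivers()] result), or named numeric vectors.
#' @return A tibble: `n_variables`, `pearson`, `spearman`.
#' @export
congruence <- function(ranking_a, ranking_b) {
  to_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$r2_cv, x$variable) else x
  }
  a <- to_vec(ranking_a)
  b <- to_vec(ranking_b)
  common <- intersect(names(a), names(b))
  if (length(common) < 3) abort("Need at least 3 common variables.")
  tibble(n_variables = length(common),
         pearson = cor(a[common], b[common]),
         spearman = cor(a[common], b[common], method = "spearman"))
}
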