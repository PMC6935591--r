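#' Fit the common-garden design model for one trait
#'
#' Removes experimental design effects with the nested random-intercept
#' mixed model `Y_ijk = mu + B_j + L(B)_jk + e_ijk`, where block `B` and
#' location-within-block `L(B)` are random effects. Variance components are
#' estimated by REML (via lme4) and constrained non-negative; block and
#' location effects are predicted as BLUPs. With a single block the design
#' is singular and the fit falls back to a residual-only model with a
#' warning.
#'
#' @param phenotypes Tibble with `individual`, `block`, `location` and one
#'   column per trait; rows with a missing trait value are dropped for that
#'   trait.
#' @param trait Name of the trait column to fit.
#' @return A list of class `block_model`: `trait`, `mu`, `varcomp`
#'   (tibble `sigma2_B`, `sigma2_LB`, `sigma2_e`), `blup_block`,
#'   `blup_location` (named vectors), `data` (rows used) and `fit`
#'   (the lme4 fit, or NULL for the fallback).
#' @export
fit_block_model <- function(phenotypes, trait) {
  if (!trait %in% names(phenotypes)) {
    abort(sprintf("Trait `%s` not found in phenotypes.", trait))
  }
  d <- phenotypes[!is.na(phenotypes[[trait]]),
                  c("individual", "block", "location", trait)]
  names(d)[4] <- "y"
  # qualify location ids by block so reused labels still nest correctly
  d$location <- paste(d$block, d$location, sep = "::")
  n_blocks <- length(unique(d$block))
  if (n_blocks < 2) {
    warn("Fewer than 2 blocks: falling back to residual-only model.")
    mu <- mean(d$y)
    return(structure(list(
      trait = trait, mu = mu,
      varcomp = tibble(sigma2_B = 0, sigma2_LB = 0,
                       sigma2_e = var(d$y) * (nrow(d) - 1) / nrow(d)),
      blup_block = setNames(rep(0, n_blocks), unique(d$block)),
      blup_location = setNames(rep(0, length(unique(d$location))),
                               unique(d$location)),
      data = d, fit = NULL), class = "block_model"))
  }
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    y ~ 1 + (1 | block) + (1 | location), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.conv.grad = "ignore",
                                check.conv.hess = "ignore",
                                calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  re <- lme4::ranef(fit)
  blup_b <- setNames(re$block[, 1], rownames(re$block))
  blup_l <- setNames(re$location[, 1], rownames(re$location))
  structure(list(
    trait = trait, mu = unname(lme4::fixef(fit)[1]),
    varcomp = tibble(sigma2_B = getv("block"), sigma2_LB = getv("location"),
                     sigma2_e = getv("Residual")),
    blup_block = blup_b, blup_location = blup_l,
    data = d, fit = fit), class = "block_model")
}

#' @export
print.block_model <- function(x, ...) {
  cat(sprintf("<block_model> trait %s: mu=%.3f sigma2_B=%.4f sigma2_LB=%.4f sigma2_e=%.4f (n=%d)\n",
              x$trait, x$mu, x$varcomp$sigma2_B, x$varcomp$sigma2_LB,
              x$varcomp$sigma2_e, nrow(x$data)))
  invisible(x)
}

#' Design-adjusted, z-standardized phenotypes
#'
#' Subtracts the experimental mean and the block and location BLUPs from
#' each observation, then z-standardizes the residuals across all
#' individuals of the trait.
#'
#' @param phenotypes Phenotype tibble (as in [fit_block_model()]).
#' @param model A [fit_block_model()] result for one trait.
#' @return A tibble `individual`, `population` (if present), `trait`,
#'   `residual` (z-score; mean 0, SD 1).
#' @export
adjusted_phenotypes <- function(phenotypes, model) {
  d <- model$data
  res <- d$y - model$mu -
    ifelse(d$block %in% names(model$blup_block),
           model$blup_block[d$block], 0) -
    ifelse(d$location %in% names(model$blup_location),
           model$blup_location[d$location], 0)
  z <- as.numeric(scale(res))
  out <- tibble(individual = d$individual, trait = model$trait, residual = z)
  if ("population" %in% names(phenotypes)) {
    out <- dplyr::left_join(
      out, dplyr::distinct(phenotypes[, c("individual", "population")]),
      by = "individual")
    out <- out[, c("individual", "population", "trait", "residual")]
  }
  out
}

#' Adjust several traits at once
#'
#' Convenience wrapper: fits [fit_block_model()] per trait and stacks the
#' [adjusted_phenotypes()] results.
#'
#' @param phenotypes Phenotype tibble.
#' @param traits Character vector of trait column names; defaults to all
#'   non-design columns.
#' @return A long tibble of adjusted phenotypes with an attribute `models`
#'   (named list of `block_model`s).
#' @export
adjust_phenotypes <- function(phenotypes, traits = NULL) {
  design_cols <- c("individual", "population", "block", "location")
  traits <- traits %||% setdiff(names(phenotypes), design_cols)
  models <- lapply(traits, function(tr) fit_block_model(phenotypes, tr))
  names(models) <- traits
  out <- dplyr::bind_rows(lapply(models, function(m)
    adjusted_phenotypes(phenotypes, m)))
  attr(out, "models") <- models
  out
}

#' Population means of adjusted phenotypes
#'
#' Arithmetic mean of the z-standardized residuals per population per trait.
#' Panel populations with no phenotyped individuals appear with `NA` (absent,
#' not zero).
#'
#' @param adjusted Output of [adjusted_phenotypes()] or [adjust_phenotypes()]
#'   (must carry `population`).
#' @param panel Optional population panel; when given, all panel populations
#'   are present in the output.
#' @return A tibble `population`, `trait`, `mean_residual`, `n`.
#' @export
population_means <- function(adjusted, panel = NULL) {
  if (!"population" %in% names(adjusted)) {
    abort("`adjusted` must carry a `population` column.")
  }
  out <- adjusted |>
    dplyr::group_by(.data$population, .data$trait) |>
    dplyr::summarise(mean_residual = mean(.data$residual),
                     n = dplyr::n(), .groups = "drop")
  if (!is.null(panel)) {
    grid <- tidyr::expand_grid(population = panel$population,
                               trait = unique(adjusted$trait))
    out <- dplyr::left_join(grid, out, by = c("population", "trait"))
    out$n[is.na(out$n)] <- 0L
  }
  out
}
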