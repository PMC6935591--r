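#' Genotype-environment association scores
#'
#' Scores each locus against one centered-and-standardized environmental
#' variable under the allele-frequency covariance model. For standardized
#' frequency vector `x` (as in [estimate_pop_covariance()]) the Bayes factor
#' compares an environment-effect model against drift alone:
#' `BF = N(x; 0, Omega + tau^2 e e') / N(x; 0, Omega)`, i.e. the marginal
#' likelihood ratio after integrating the linear environmental effect over a
#' `N(0, tau^2)` prior, averaged over a grid of prior scales `tau`. The
#' nonparametric statistic `rho` is the Spearman rank correlation between
#' the whitened frequencies `L^-1 x` and the whitened environment `L^-1 e`
#' (`L` the lower Cholesky factor of `Omega`). Each "chain" is one
#' bootstrap-estimated `Omega` run, preserving consensus-across-chains
#' filtering.
#'
#' @param freq Populations x loci frequency matrix (candidate loci).
#' @param pop_cov A [estimate_pop_covariance()] result; its `runs` provide
#'   the chains.
#' @param env Named numeric vector of the environmental variable per
#'   population (must be non-constant), or a climate tibble plus `variable`.
#' @param variable Variable name when `env` is a climate tibble.
#' @param tau_grid Prior scales for the environmental effect (standardized
#'   scale).
#' @param contigs Optional named contig vector per locus; defaults to locus
#'   ids.
#' @return A tibble of class `gea_scores`: `locus`, `contig`, `variable`,
#'   `chain`, `bf`, `rho`.
#' @export
score_env_associations <- function(freq, pop_cov, env, variable = NULL,
                                   tau_grid = c(0.01, 0.1, 1),
                                   contigs = NULL) {
  if (is.data.frame(env)) {
    if (is.null(variable)) abort("Supply `variable` with a climate tibble.")
    e <- setNames(env[[variable]], env$population)
  } else {
    e <- env
    variable <- variable %||% "env"
  }
  pops <- rownames(freq)
  if (!is.null(names(e))) e <- e[pops]
  if (anyNA(e)) abort("Environmental values missing for some populations.")
  if (sd(e) == 0) abort("Environmental variable is constant; cannot standardize.")
  e <- (e - mean(e)) / sd(e)

  pbar <- colMeans(freq, na.rm = TRUE)
  ok <- is.finite(pbar) & pbar > 0 & pbar < 1
  if (!all(ok)) warn(sprintf("Dropping %d fixed locus(i) from GEA.", sum(!ok)))
  X <- sweep(freq[, ok, drop = FALSE], 2L, pbar[ok]) |>
    sweep(2L, sqrt(pbar[ok] * (1 - pbar[ok])), `/`)
  X[is.na(X)] <- 0
  loci <- colnames(X) %||% sprintf("locus_%05d", seq_len(ncol(X)))
  contigs <- contigs %||% setNames(loci, loci)

  out <- lapply(seq_along(pop_cov$runs), function(ch) {
    Om <- pop_cov$runs[[ch]]
    Lc <- tryCatch(t(chol(Om)), error = function(err)
      abort("Omega is not positive definite; raise the ridge."))
    Zx <- forwardsolve(Lc, X)     # L^-1 x per locus
    ze <- forwardsolve(Lc, e)     # L^-1 e
    u <- drop(forwardsolve(t(Lc), ze, upper.tri = TRUE))  # Omega^-1 e
    q <- sum(ze^2)                                        # e' Omega^-1 e
    ux <- drop(crossprod(X, u))                           # e' Omega^-1 x
    bf_tau <- vapply(tau_grid, function(tau) {
      t2 <- tau^2
      exp(-0.5 * log1p(t2 * q) + 0.5 * t2 * ux^2 / (1 + t2 * q))
    }, numeric(length(loci)))
    if (is.null(dim(bf_tau))) bf_tau <- matrix(bf_tau, nrow = length(loci))
    bf <- rowMeans(bf_tau)
    rho <- suppressWarnings(drop(cor(Zx, ze, method = "spearman")))
    tibble(locus = loci, contig = unname(contigs[loci]), variable = variable,
           chain = ch, bf = unname(bf), rho = unname(rho))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("gea_scores", class(out))
  out
}

# 6-way rank table: per chain, rank by BF (descending) and by |rho|
# (descending), ties broken by locus id; ranks are 1..n permutations.
gea_rank_table <- function(scores) {
  scores |>
    dplyr::group_by(.data$variable, .data$chain) |>
    dplyr::mutate(rank_bf = rank_with_id(.data$bf, .data$locus),
                  rank_rho = rank_with_id(abs(.data$rho), .data$locus)) |>
    dplyr::ungroup()
}

#' Dual-rank consensus candidate filter
#'
#' A locus is a candidate for a variable only if it is in the top `K` by
#' Bayes factor in *each* chain and in the top `K` by `|rho|` in *each*
#' chain (the intersection of six top-K lists per variable).
#'
#' @param scores A [score_env_associations()] tibble (all chains present).
#' @param K Rank cutoff (default 300).
#' @return A tibble of class `gea_candidates`: `variable`, `locus`,
#'   `mean_rank` (mean of the six ranks), ordered by `mean_rank`; the full
#'   rank table is attached as attribute `ranks`.
#' @export
dual_rank_filter <- function(scores, K = 300) {
  rk <- gea_rank_table(scores)
  out <- rk |>
    dplyr::group_by(.data$variable, .data$locus) |>
    dplyr::summarise(pass = all(.data$rank_bf <= K) & all(.data$rank_rho <= K),
                     mean_rank = mean(c(.data$rank_bf, .data$rank_rho)),
                     .groups = "drop") |>
    dplyr::filter(.data$pass) |>
    dplyr::select(-"pass") |>
    dplyr::arrange(.data$variable, .data$mean_rank, .data$locus)
  class(out) <- c("gea_candidates", class(out))
  attr(out, "K") <- K
  attr(out, "ranks") <- rk
  out
}

#' Keep the strongest environmental response per contig
#'
#' For each contig (within each variable), retains the locus with the best
#' (smallest) mean of its six ranks — BF and `|rho|` across the chains —
#' with ties broken by locus id.
#'
#' @param scores A [score_env_associations()] tibble.
#' @return The filtered scores tibble (all chains of the kept loci).
#' @export
reduce_one_per_contig_gea <- function(scores) {
  mr <- gea_rank_table(scores) |>
    dplyr::group_by(.data$variable, .data$contig, .data$locus) |>
    dplyr::summarise(mean_rank = mean(c(.data$rank_bf, .data$rank_rho)),
                     .groups = "drop")
  keep <- mr |>
    dplyr::group_by(.data$variable, .data$contig) |>
    dplyr::arrange(.data$mean_rank, .data$locus, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  dplyr::semi_join(scores, keep, by = c("variable", "locus"))
}

#' Top-N loci by consensus rank
#'
#' Orders (deduplicated) loci by the mean of their six ranks for one
#' variable and returns the first `N` locus ids.
#'
#' @param scores A [score_env_associations()] tibble for one variable.
#' @param N Number of loci (default 300). If `N` exceeds the pool, the whole
#'   pool is returned with a warning.
#' @return Character vector of locus ids, best first.
#' @export
top_n_by_rank <- function(scores, N = 300) {
  if (length(unique(scores$variable)) != 1) {
    abort("`top_n_by_rank()` expects scores for a single variable.")
  }
  mr <- gea_rank_table(scores) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(mean_rank = mean(c(.data$rank_bf, .data$rank_rho)),
                     .groups = "drop") |>
    dplyr::arrange(.data$mean_rank, .data$locus)
  if (N > nrow(mr)) {
    warn(sprintf("N = %d exceeds pool of %d loci; returning all.", N, nrow(mr)))
    N <- nrow(mr)
  }
  mr$locus[seq_len(N)]
}
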