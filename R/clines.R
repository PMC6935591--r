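#' Cluster SNPs by their allele-frequency profiles
#'
#' Euclidean k-means on absolute population positive-effect-allele
#' frequencies, with SNPs as observations and populations as variables.
#' Frequencies are deliberately *not* centered per locus: SNPs with similar
#' aggregate frequency cluster together, which is distinct from
#' correlation-based (LD) clustering. The best of `n_init` seeded restarts
#' by within-cluster sum of squares is kept, and cluster ids are relabeled
#' by ascending grand-mean frequency so labels are deterministic. An empty
#' cluster triggers a restart with a fresh seed (up to `max_retries`).
#'
#' @param freq Populations x loci frequency matrix (typically restricted to
#'   climate-associated trait candidates).
#' @param k Number of clusters (default 6; choose by inspecting cline
#'   homogeneity — a silhouette-style spread is reported in `member_sd`).
#' @param seed Integer seed.
#' @param n_init Random restarts (default 50).
#' @param max_retries Restart attempts on empty clusters.
#' @return A list of class `cline_clusters`: `k`, `assignment` (tibble
#'   `locus`, `cluster`), `cluster_mean_cline` (k x populations),
#'   `member_sd` (per cluster, mean across-population SD of member SNPs),
#'   `sizes`, `tot_withinss`.
#' @export
cluster_snps <- function(freq, k = 6, seed = NULL, n_init = 50,
                         max_retries = 5) {
  M <- t(as.matrix(freq))  # loci x populations
  if (anyNA(M)) {
    # impute a locus's missing population values at its own mean
    for (i in seq_len(nrow(M))) {
      nas <- is.na(M[i, ])
      if (all(nas)) abort("Locus with all-missing frequencies.")
      M[i, nas] <- mean(M[i, ], na.rm = TRUE)
    }
  }
  if (nrow(M) < k) abort("Need at least `k` loci to form `k` clusters.")
  if (nrow(M) == k) {
    # degenerate case: each locus is its own cluster
    km <- list(cluster = setNames(seq_len(k), rownames(M)), centers = M,
               size = rep(1L, k), tot.withinss = 0)
    rownames(km$centers) <- seq_len(k)
  } else {
  km <- NULL
  for (try in seq_len(max_retries)) {
    km <- with_seed(child_seed(seed, try) %||% NULL, {
      tryCatch(kmeans(M, centers = k, nstart = n_init, iter.max = 100),
               error = function(e) NULL)
    })
    if (!is.null(km) && length(km$size) == k && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) abort("k-means failed to produce k non-empty clusters.")
  }
  # relabel by ascending grand-mean center frequency
  ord <- order(rowMeans(km$centers), as.numeric(rownames(km$centers)))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  cl <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  member_sd <- vapply(seq_len(k), function(c_) {
    mean(apply(M[cl == c_, , drop = FALSE], 1L, sd))
  }, numeric(1))
  structure(list(k = k,
                 assignment = tibble(locus = rownames(M), cluster = cl),
                 cluster_mean_cline = centers,
                 member_sd = member_sd,
                 sizes = as.integer(table(factor(cl, levels = seq_len(k)))),
                 tot_withinss = km$tot.withinss),
            class = "cline_clusters")
}

#' @export
print.cline_clusters <- function(x, ...) {
  cat(sprintf("<cline_clusters> k=%d over %d loci x %d populations; sizes: %s\n",
              x$k, nrow(x$assignment), ncol(x$cluster_mean_cline),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Restore the variance of cluster-mean clines
#'
#' Averaging SNPs within a cluster shrinks the across-population spread of
#' the cluster-mean cline. The default `"deviation"` method rescales
#' deviations from the cline's own mean so its across-population SD equals
#' the mean SD of the member SNPs:
#' `restored = gbar + (m - gbar) * s_mem / sd(m)`, clipped to `[0, 1]`.
#' The `"literal"` method multiplies the cluster-mean frequency itself by
#' the mean member SD (which collapses the frequency scale; provided for
#' comparability).
#'
#' @param model A [cluster_snps()] result.
#' @param method `"deviation"` (default) or `"literal"`.
#' @return The model with added `restored_cline` (k x populations, clipped
#'   to `[0, 1]`) and `restored_unclipped`.
#' @export
restore_variance <- function(model, method = c("deviation", "literal")) {
  method <- match.arg(method)
  M <- model$cluster_mean_cline
  out <- M
  for (c_ in seq_len(model$k)) {
    m <- M[c_, ]
    if (method == "literal") {
      out[c_, ] <- m * model$member_sd[c_]
      next
    }
    s <- sd(m)
    if (s == 0) {
      out[c_, ] <- m
    } else {
      out[c_, ] <- mean(m) + (m - mean(m)) * model$member_sd[c_] / s
    }
  }
  model$restored_unclipped <- out
  model$restored_cline <- pmin(pmax(out, 0), 1)
  model$restore_method <- method
  model
}

#' Expected heterozygosity
#'
#' `He = 2 p (1 - p)` per frequency; zero exactly when the locus is fixed.
#' Missing frequencies give missing He.
#'
#' @param freq Frequency matrix (or vector) in `[0, 1]`.
#' @return Same shape as `freq`.
#' @export
expected_heterozygosity <- function(freq) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) {
    abort("frequencies must be in [0, 1].")
  }
  2 * freq * (1 - freq)
}

#' Proportional polymorphism per population per cluster
#'
#' The fraction of a cluster's member SNPs with `He > 0` in each population
#' — a summary of where standing variation for that cluster exists. Missing
#' He values are excluded from the denominator; a population where all
#' member loci are missing gets `NA`.
#'
#' @param he Populations x loci He matrix (from
#'   [expected_heterozygosity()]).
#' @param model A [cluster_snps()] result.
#' @return A tibble `population`, `cluster`, `prop_poly`.
#' @export
proportional_polymorphism <- function(he, model) {
  he <- as.matrix(he)
  out <- purrr::map_dfr(seq_len(model$k), function(c_) {
    loci <- model$assignment$locus[model$assignment$cluster == c_]
    sub <- he[, loci, drop = FALSE]
    pp <- rowMeans(sub > 0, na.rm = TRUE)
    pp[rowSums(!is.na(sub)) == 0] <- NA_real_
    tibble(population = rownames(he), cluster = c_, prop_poly = unname(pp))
  })
  out
}

# 4-parameter logistic fit of a cline; returns coefficients or NULL.
fit_logistic_cline <- function(env, p) {
  ord <- order(env)
  env <- env[ord]
  p <- p[ord]
  fit <- tryCatch(
    nls(p ~ SSfpl(env, A, B, xmid, scal),
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    n3 <- max(3L, length(p) %/% 10L)
    start <- list(A = mean(utils::head(p, n3)), B = mean(utils::tail(p, n3)),
                  xmid = stats::median(env), scal = diff(range(env)) / 8)
    fit <- tryCatch(
      minpack.lm::nlsLM(p ~ A + (B - A) * plogis((env - xmid) / scal),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(NULL)
  coef(fit)
}

#' Classify cline extent: rangewide, localized or flat
#'
#' Fits a 4-parameter logistic to each cluster's (restored) cline over the
#' environmental gradient and computes the active range — the env interval
#' covering the 10% to 90% points of the total frequency change,
#' `[center - width log 9, center + width log 9]`, intersected with the
#' observed gradient span. A cluster is *flat* if its total fitted change is
#' at most 0.1 (or the fit fails, with a warning), *localized* if the active
#' range is narrower than `span_fraction` of the gradient span, and
#' *rangewide* otherwise.
#'
#' @param model A [cluster_snps()] result with [restore_variance()] applied
#'   (falls back to cluster means), or a clusters x populations matrix.
#' @param env Named numeric vector of the gradient per population.
#' @param span_fraction Localized cutoff as a fraction of the gradient span
#'   (default 0.5).
#' @return A tibble of class `cline_extent`: `cluster`, `p0`, `p1`,
#'   `center`, `width`, `active_lo`, `active_hi`, `label`.
#' @export
classify_extent <- function(model, env, span_fraction = 0.5) {
  M <- if (inherits(model, "cline_clusters")) {
    model$restored_cline %||% model$cluster_mean_cline
  } else {
    as.matrix(model)
  }
  pops <- colnames(M)
  if (!is.null(names(env)) && !is.null(pops)) env <- env[pops]
  if (length(env) < 4) abort("Need at least 4 populations.")
  span <- diff(range(env))
  out <- purrr::map_dfr(seq_len(nrow(M)), function(c_) {
    p <- M[c_, ]
    cf <- fit_logistic_cline(env, p)
    if (is.null(cf)) {
      warn(sprintf("Cluster %s: logistic fit did not converge; labeled flat.",
                   rownames(M)[c_] %||% c_))
      return(tibble(cluster = c_, p0 = NA_real_, p1 = NA_real_,
                    center = NA_real_, width = NA_real_,
                    active_lo = NA_real_, active_hi = NA_real_,
                    label = "flat"))
    }
    p0 <- unname(cf["A"])
    p1 <- unname(cf["B"])
    ctr <- unname(cf["xmid"])
    w <- abs(unname(cf["scal"]))
    act <- c(max(ctr - w * log(9), min(env)), min(ctr + w * log(9), max(env)))
    total_change <- abs(p1 - p0)
    label <- if (total_change <= 0.1) {
      "flat"
    } else if (diff(act) < span_fraction * span) {
      "localized"
    } else {
      "rangewide"
    }
    tibble(cluster = c_, p0 = p0, p1 = p1, center = ctr, width = w,
           active_lo = act[1], active_hi = act[2], label = label)
  })
  class(out) <- c("cline_extent", class(out))
  out
}
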