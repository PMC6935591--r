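#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy block_model
#' @export
tidy.block_model <- function(x, ...) {
  tibble(term = c("mu", "sigma2_B", "sigma2_LB", "sigma2_e"),
         estimate = c(x$mu, x$varcomp$sigma2_B, x$varcomp$sigma2_LB,
                      x$varcomp$sigma2_e))
}

#' @method glance block_model
#' @export
glance.block_model <- function(x, ...) {
  tibble(trait = x$trait, n = nrow(x$data),
         n_blocks = length(x$blup_block),
         n_locations = length(x$blup_location),
         logLik = if (!is.null(x$fit)) as.numeric(stats::logLik(x$fit))
                  else NA_real_)
}

#' @method glance mlma_result
#' @export
glance.mlma_result <- function(x, ...) {
  tibble(trait = x$trait[1], n_loci = nrow(x), n = attr(x, "n"),
         sigma2_g = attr(x, "sigma2_g"), sigma2_e = attr(x, "sigma2_e"),
         h2 = attr(x, "sigma2_g") / (attr(x, "sigma2_g") + attr(x, "sigma2_e")))
}

#' @method tidy cline_clusters
#' @export
tidy.cline_clusters <- function(x, ...) x$assignment

#' @method glance cline_clusters
#' @export
glance.cline_clusters <- function(x, ...) {
  tibble(k = x$k, n_loci = nrow(x$assignment),
         tot_withinss = x$tot_withinss,
         min_size = min(x$sizes), max_size = max(x$sizes))
}

#' @method tidy pc_result
#' @export
tidy.pc_result <- function(x, ...) {
  as_tibble(x$scores, rownames = "observation")
}

#' @method glance pc_result
#' @export
glance.pc_result <- function(x, ...) {
  tibble(n_components = ncol(x$scores),
         var_explained_1 = x$var_explained[1],
         var_explained_m = sum(x$var_explained[seq_len(ncol(x$scores))]))
}

#' Long-format allele-frequency table
#'
#' Converts a populations x loci frequency matrix (from
#' [pop_allele_frequencies()]) to a tidy tibble.
#'
#' @param freq Frequency matrix with dimnames.
#' @return A tibble `population`, `locus`, `frequency`.
#' @export
freq_tidy <- function(freq) {
  as_tibble(as.data.frame(as.matrix(freq)), rownames = "population") |>
    tidyr::pivot_longer(-"population", names_to = "locus",
                        values_to = "frequency")
}
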