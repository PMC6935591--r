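# Shared fixtures, built in code.

# Tiny hand-checkable genotype matrix: 3 individuals x 2 loci.
toy_geno <- function() {
  codes <- matrix(c(0L, 1L, 2L,
                    2L, 2L, 2L), nrow = 3,
                  dimnames = list(c("i1", "i2", "i3"), c("L1", "L2")))
  geno_matrix(codes,
              loci = tibble::tibble(locus = c("L1", "L2"),
                                    contig = c("c1", "c1"),
                                    class = c("candidate", "candidate"),
                                    ref = c("A", "C"), alt = c("T", "G")),
              individuals = tibble::tibble(individual = c("i1", "i2", "i3"),
                                           population = c("p1", "p1", "p2")))
}

# Small but realistic synthetic dataset for module tests.
small_config <- function(seed = 1, n_pops = 60, n_per_pop = 6,
                         n_control = 400, n_neutral = 360,
                         groups = NULL, fst = 0.016, ...) {
  span <- 12
  groups <- groups %||% list(
    cline_group(20, "rangewide", center = 2,
                width = cline_width_for_span(0.6, span)),
    cline_group(20, "localized", center = 5,
                width = cline_width_for_span(0.08, span)))
  truth_config(n_pops = n_pops, n_per_pop = n_per_pop,
               n_control_loci = n_control, n_neutral_candidate_loci = n_neutral,
               cline_groups = groups, fst_neutral = fst, seed = seed, ...)
}

# Adjusted Rand index between two labelings (independent of genecol's own
# clustering code; closed-form from the contingency table).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Nei-style FST estimate across loci from a populations x loci frequency
# matrix: ratio of mean among-population variance to mean p(1-p).
realized_fst <- function(freq) {
  pbar <- colMeans(freq)
  num <- apply(freq, 2L, function(col) mean((col - mean(col))^2))
  mean(num) / mean(pbar * (1 - pbar))
}
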