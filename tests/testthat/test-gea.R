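# Toy Omega and standardized-frequency fixture for Bayes-factor oracles.
gea_toy <- function(seed = 1, n_pops = 4, n_loci = 6) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n_pops^2, 0, 0.3), n_pops)
    Om <- crossprod(A) + diag(0.5, n_pops)
    freq <- matrix(runif(n_pops * n_loci, 0.2, 0.8), n_pops, n_loci,
                   dimnames = list(paste0("p", seq_len(n_pops)),
                                   paste0("l", seq_len(n_loci))))
    e <- rnorm(n_pops)
  })
  names(e) <- rownames(freq)
  pc <- structure(list(omega = Om, runs = list(Om), loci = character()),
                  class = "pop_cov")
  list(freq = freq, pop_cov = pc, env = e, omega = Om)
}

# Brute-force BF by numerical quadrature of the environmental-effect model:
# integral over beta of N(x; beta*e, Omega) * N(beta; 0, tau^2), divided by
# N(x; 0, Omega).
bf_quadrature <- function(x, e, Om, tau_grid) {
  ldmvn <- function(z, S) {
    ch <- chol(S)
    -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(backsolve(ch, z, transpose = TRUE)^2))
  }
  null <- exp(ldmvn(x, Om))
  bfs <- vapply(tau_grid, function(tau) {
    f <- function(b) {
      vapply(b, function(bi) exp(ldmvn(x - bi * e, Om)) *
               dnorm(bi, 0, tau), numeric(1))
    }
    integrate(f, -8 * tau, 8 * tau, rel.tol = 1e-10)$value / null
  }, numeric(1))
  mean(bfs)
}

test_that("closed-form Bayes factors match numerical quadrature", {
  toy <- gea_toy(seed = 3)
  sc <- score_env_associations(toy$freq, toy$pop_cov, toy$env,
                               tau_grid = c(0.01, 0.1, 1))
  # reproduce the internal standardization to feed the oracle
  pbar <- colMeans(toy$freq)
  X <- sweep(sweep(toy$freq, 2, pbar), 2, sqrt(pbar * (1 - pbar)), `/`)
  es <- (toy$env - mean(toy$env)) / sd(toy$env)
  for (l in colnames(toy$freq)) {
    oracle <- bf_quadrature(X[, l], es, toy$omega, c(0.01, 0.1, 1))
    got <- sc$bf[sc$locus == l]
    expect_lt(abs(got - oracle) / oracle, 1e-6)
  }
})

test_that("the Bayes factor degenerates to one as the prior scale vanishes", {
  toy <- gea_toy(seed = 4)
  sc <- score_env_associations(toy$freq, toy$pop_cov, toy$env,
                               tau_grid = 1e-8)
  expect_equal(sc$bf, rep(1, nrow(sc)), tolerance = 1e-6)
})

test_that("scores are invariant to which allele is counted", {
  toy <- gea_toy(seed = 5)
  sc1 <- score_env_associations(toy$freq, toy$pop_cov, toy$env)
  sc2 <- score_env_associations(1 - toy$freq, toy$pop_cov, toy$env)
  expect_equal(sc1$bf, sc2$bf, tolerance = 1e-10)
  expect_equal(abs(sc1$rho), abs(sc2$rho), tolerance = 1e-10)
})

test_that("a constant environmental variable is rejected", {
  toy <- gea_toy(seed = 6)
  expect_error(
    score_env_associations(toy$freq, toy$pop_cov,
                           setNames(rep(1, 4), rownames(toy$freq))),
    "constant")
})

test_that("neutral loci have Bayes factors calibrated near one", {
  # null calibration holds at prior scales with tau^2 * e' Omega^-1 e <~ 1;
  # at larger scales every null BF shrinks below one by the Occam factor
  # (1 + tau^2 q)^(-1/2), so the weak-prior component carries the check
  n_pops <- 60
  f <- simulate_neutral_frequencies(2000, n_pops, fst = 0.05, seed = 7)
  rownames(f) <- sprintf("pop_%03d", seq_len(n_pops))
  om <- estimate_pop_covariance(f, n_runs = 3, seed = 8)
  env <- setNames(seq(-1, 1, length.out = n_pops), rownames(f))
  sc <- score_env_associations(f, om, env, tau_grid = 0.01)
  expect_lt(abs(median(log10(sc$bf))), 0.2)
  # with the default grid the null median is below one but bounded, and the
  # Occam penalty of the largest scale bounds it from below
  sc_def <- score_env_associations(f, om, env)
  expect_lt(median(sc_def$bf), 1.2)
  expect_gt(median(sc_def$bf), 1 / (3 * sqrt(1 + sum(env^2) * n_pops)))
})

test_that("the dual-rank filter is the six-list intersection", {
  withr::with_seed(9, {
    sc <- tidyr::expand_grid(locus = sprintf("l%02d", 1:10), chain = 1:3)
    sc$contig <- sc$locus
    sc$variable <- "MAT"
    sc$bf <- runif(nrow(sc), 0.5, 20)
    sc$rho <- runif(nrow(sc), -1, 1)
  })
  K <- 3
  cand <- dual_rank_filter(sc, K = K)
  # brute-force: per chain top-K sets by bf and |rho|
  sets <- list()
  for (ch in 1:3) {
    d <- sc[sc$chain == ch, ]
    sets <- c(sets,
              list(d$locus[order(-d$bf, d$locus)][1:K]),
              list(d$locus[order(-abs(d$rho), d$locus)][1:K]))
  }
  oracle <- Reduce(intersect, sets)
  expect_setequal(cand$locus, oracle)
  # K covering the pool passes everything
  expect_equal(nrow(dual_rank_filter(sc, K = 10)), 10)
  # monotone in K
  for (s in 1:5) {
    sc2 <- withr::with_seed(s, {
      d <- tidyr::expand_grid(locus = sprintf("l%02d", 1:15), chain = 1:3)
      d$contig <- d$locus; d$variable <- "v"
      d$bf <- runif(nrow(d)); d$rho <- runif(nrow(d), -1, 1)
      d
    })
    a <- dual_rank_filter(sc2, K = 4)$locus
    b <- dual_rank_filter(sc2, K = 5)$locus
    expect_true(all(a %in% b))
  }
})

test_that("per-contig reduction keeps the best mean rank", {
  sc <- tidyr::expand_grid(locus = c("a1", "a2", "b1"), chain = 1:3)
  sc$contig <- c("A", "A", "B")[match(sc$locus, c("a1", "a2", "b1"))]
  sc$variable <- "MAT"
  # a2 dominates a1 on every list
  sc$bf <- ifelse(sc$locus == "a2", 10, ifelse(sc$locus == "a1", 1, 5))
  sc$rho <- ifelse(sc$locus == "a2", 0.9, ifelse(sc$locus == "a1", 0.1, 0.5))
  red <- reduce_one_per_contig_gea(sc)
  expect_setequal(unique(red$locus), c("a2", "b1"))  # one per contig
  expect_equal(length(unique(red$locus)), length(unique(sc$contig)))
})

test_that("top-N ordering agrees with a brute-force mean-rank sort", {
  withr::with_seed(12, {
    sc <- tidyr::expand_grid(locus = sprintf("l%02d", 1:20), chain = 1:3)
    sc$contig <- sc$locus; sc$variable <- "MAT"
    sc$bf <- runif(nrow(sc), 0.5, 50)
    sc$rho <- runif(nrow(sc), -1, 1)
  })
  top <- top_n_by_rank(sc, N = 5)
  # brute force mean of six ranks
  mr <- sapply(sprintf("l%02d", 1:20), function(l) {
    rks <- c()
    for (ch in 1:3) {
      d <- sc[sc$chain == ch, ]
      rks <- c(rks, match(l, d$locus[order(-d$bf, d$locus)]),
               match(l, d$locus[order(-abs(d$rho), d$locus)]))
    }
    mean(rks)
  })
  expect_equal(top, names(sort(mr))[1:5])
  # single best locus; determinism; pool-overflow warning
  expect_equal(top_n_by_rank(sc, N = 1), names(sort(mr))[1])
  expect_identical(top, top_n_by_rank(sc, N = 5))
  expect_warning(all_loci <- top_n_by_rank(sc, N = 50), "exceeds")
  expect_length(all_loci, 20)
})

test_that("a planted climate-driven cline group is recovered", {
  # one rangewide cline group among neutral candidates; the driving variable
  # is the gradient itself
  n_pops <- 80
  env <- seq(-4, 8, length.out = n_pops)
  grp <- cline_group(20, "rangewide", center = 2,
                     width = cline_width_for_span(0.5, 12), p_lo = 0.05,
                     p_hi = 0.95)
  withr::with_seed(21, {
    base <- simulate_cline_frequencies(env, grp)
    fst_j <- 0.02
    f_cline <- matrix(rbeta(n_pops * 20,
                            rep(base, 20) * (1 - fst_j) / fst_j,
                            rep(1 - base, 20) * (1 - fst_j) / fst_j),
                      nrow = n_pops)
  })
  f_neut <- simulate_neutral_frequencies(480, n_pops, 0.02, seed = 22)
  f <- cbind(f_neut, f_cline)
  colnames(f) <- sprintf("locus_%03d", seq_len(500))
  rownames(f) <- sprintf("pop_%03d", seq_len(n_pops))
  truth <- colnames(f)[481:500]
  f_ctl <- simulate_neutral_frequencies(600, n_pops, 0.02, seed = 23)
  rownames(f_ctl) <- rownames(f)
  om <- estimate_pop_covariance(f_ctl, n_runs = 3, seed = 24,
                                n_alleles = matrix(20L, n_pops, 600))
  sc <- score_env_associations(f, om, setNames(env, rownames(f)))
  cand <- dual_rank_filter(sc, K = 30)  # 1.5x the group size
  expect_gte(mean(truth %in% cand$locus), 0.8)
  # permuting the climate destroys the enrichment
  perm <- withr::with_seed(25, sample(env))
  sc_p <- score_env_associations(f, om, setNames(perm, rownames(f)))
  cand_p <- dual_rank_filter(sc_p, K = 30)
  expect_lt(mean(truth %in% cand_p$locus), 0.5)
})
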