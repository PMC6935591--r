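test_that("logistic clines hit their closed form", {
  gr <- cline_group(1, "rangewide", center = 2, width = 0.5,
                    p_lo = 0, p_hi = 1)
  # midpoint
  expect_equal(simulate_cline_frequencies(2, gr), 0.5)
  # matches direct expit evaluation and saturates at the range ends
  env <- seq(-4, 8, by = 1)
  p <- simulate_cline_frequencies(env, gr)
  expect_equal(p, plogis((env - 2) / 0.5))
  expect_lt(p[1], 0.01)
  expect_gt(p[length(p)], 0.99)
  # degenerate cline is constant
  flat <- cline_group(1, "rangewide", center = 0, width = 1,
                      p_lo = 0.4, p_hi = 0.4)
  expect_equal(simulate_cline_frequencies(env, flat), rep(0.4, length(env)))
  expect_error(simulate_cline_frequencies(c(1, NA), gr), "finite")
})

test_that("neutral frequencies follow the drift parameter", {
  # no-drift limit: population frequencies collapse onto the ancestral one
  f <- simulate_neutral_frequencies(50, 20, fst = 1e-6, seed = 3)
  anc <- attr(f, "ancestral")
  expect_lt(max(abs(sweep(f, 2L, anc))), 0.02)
  # realized differentiation tracks the configured parameter
  f2 <- simulate_neutral_frequencies(2000, 40, fst = 0.05, seed = 4)
  expect_equal(realized_fst(f2), 0.05, tolerance = 0.15)
  # determinism
  expect_identical(simulate_neutral_frequencies(30, 10, 0.1, seed = 9),
                   simulate_neutral_frequencies(30, 10, 0.1, seed = 9))
  expect_error(simulate_neutral_frequencies(10, 5, fst = 1.2), "fst")
})

test_that("genotype sampling has binomial moments and missingness", {
  pf <- matrix(0, nrow = 2, ncol = 3)
  g0 <- sample_genotypes(pf, n_per_pop = 5, seed = 1)
  expect_true(all(geno_codes(g0) == 0L))

  pf5 <- matrix(0.5, nrow = 4, ncol = 100)
  g5 <- sample_genotypes(pf5, n_per_pop = 50, seed = 2)
  m <- mean(geno_codes(g5))
  se <- sqrt(0.5 / (200 * 100))  # var of genotype = 2pq = 0.5
  expect_lt(abs(m - 1), 3 * se)

  gm <- sample_genotypes(matrix(0.5, 10, 100), n_per_pop = 10,
                         missing_rate = 0.1, seed = 5)
  expect_equal(mean(is.na(geno_codes(gm))), 0.1, tolerance = 0.01)
  expect_error(sample_genotypes(pf5, 5, missing_rate = 1), "missing_rate")
})

test_that("phenotype simulation is additive with the stated design variance", {
  pf <- matrix(runif(20 * 30, 0.2, 0.8), 20, 30,
               dimnames = list(sprintf("p%02d", 1:20), sprintf("l%02d", 1:30)))
  g <- sample_genotypes(pf, n_per_pop = 25, seed = 11)

  # all effects zero, no design variance: pure residual noise
  tr0 <- trait_spec("t0", sigma_block = 0, sigma_loc = 0, sigma_e = 1)
  ph0 <- simulate_phenotypes(g, list(tr0),
                             effects = tibble::tibble(trait = character(),
                                                      locus = character(),
                                                      effect = numeric()),
                             seed = 12)
  expect_equal(mean(ph0$t0), 0, tolerance = 0.1)
  expect_equal(sd(ph0$t0), 1, tolerance = 0.1)

  # single causal locus, unit effect, no noise: phenotype equals allele count
  tr1 <- trait_spec("t1", sigma_block = 0, sigma_loc = 0, sigma_e = 0)
  eff1 <- tibble::tibble(trait = "t1", locus = "l01", effect = 1)
  ph1 <- simulate_phenotypes(g, list(tr1), effects = eff1, seed = 13)
  expect_equal(ph1$t1, as.numeric(geno_codes(g)[, "l01"]))

  # among-population variance of genetic values matches a brute-force
  # recomputation straight from the genotype matrix
  effm <- tibble::tibble(trait = "t2", locus = colnames(pf)[1:10],
                         effect = seq(0.05, 0.5, length.out = 10))
  tr2 <- trait_spec("t2", sigma_block = 0, sigma_loc = 0, sigma_e = 0)
  ph2 <- simulate_phenotypes(g, list(tr2), effects = effm, seed = 14)
  gval <- drop(geno_codes(g)[, effm$locus] %*% effm$effect)
  pop <- geno_individuals(g)$population
  expect_equal(tapply(ph2$t2, ph2$population, mean),
               tapply(gval, pop, mean))
  expect_error(
    simulate_phenotypes(g, list(tr1),
                        effects = tibble::tibble(trait = "t1",
                                                 locus = "nope", effect = 1)),
    "absent")
})

test_that("climate variables are affine in the gradient with a clear driver", {
  env <- seq(-4, 8, length.out = 50)
  # zero noise: every variable an exact affine function of env
  c0 <- generate_climate(env, n_vars = 6, climate_noise_sd = 0, seed = 2)
  vals <- as.matrix(c0[, -1])
  cors <- abs(cor(vals))
  expect_true(all(abs(cors - 1) < 1e-12))
  # with noise, the driving variable correlates with env most strongly
  c1 <- generate_climate(env, n_vars = 19, climate_noise_sd = 0.5, seed = 3)
  r <- vapply(names(c1)[-1], function(v) abs(cor(c1[[v]], env)), numeric(1))
  expect_equal(names(which.max(r)), attr(c1, "driving"))
  # determinism
  expect_identical(generate_climate(env, 19, 0.3, seed = 7),
                   generate_climate(env, 19, 0.3, seed = 7))
})

test_that("dataset truth labels partition loci and clines are classifiable", {
  ds <- simulate_dataset(small_config(seed = 21, n_pops = 40, n_per_pop = 4,
                                      n_control = 100, n_neutral = 80))
  tl <- ds$truth$loci
  expect_equal(nrow(tl), ncol(ds$genotypes))
  expect_setequal(tl$locus, geno_loci(ds$genotypes)$locus)
  # control / neutral-candidate / cline members are disjoint and exhaustive
  is_control <- tl$class == "control"
  is_cline <- !is.na(tl$group)
  expect_true(all(!(is_control & is_cline)))
  expect_equal(sum(is_control) + sum(!is_control & !is_cline) + sum(is_cline),
               nrow(tl))
  # every causal locus appears exactly once in the effects per trait
  eff <- ds$truth$effects
  expect_false(any(duplicated(eff[, c("trait", "locus")])))

  # localized groups concentrate >=90% of their change in <=50% of the span;
  # rangewide groups do not (from the closed-form cline)
  env <- ds$truth$env
  span <- diff(range(env))
  for (gi in unique(na.omit(tl$group))) {
    row <- tl[which(tl$group == gi)[1], ]
    gr <- list(center = row$center, width = row$width, p_lo = row$p_lo,
               p_hi = row$p_hi)
    # interval holding 90% of the frequency change (logit 10-90% range)
    act <- 2 * row$width * log(9)
    if (row$kind == "localized") {
      expect_lt(act, 0.5 * span)
    } else {
      expect_gt(act, 0.5 * span)
    }
  }

  # seed determinism of the full generator
  ds2 <- simulate_dataset(small_config(seed = 21, n_pops = 40, n_per_pop = 4,
                                       n_control = 100, n_neutral = 80))
  expect_identical(geno_codes(ds$genotypes), geno_codes(ds2$genotypes))
  expect_identical(ds$phenotypes, ds2$phenotypes)
})
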