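# Frequency matrix with planted cluster structure along a gradient.
planted_freqs <- function(env, groups, n_per_group, jitter_fst = 0.02,
                          seed = 1) {
  n_pops <- length(env)
  withr::with_seed(seed, {
    blocks <- lapply(seq_along(groups), function(i) {
      base <- simulate_cline_frequencies(env, groups[[i]])
      matrix(rbeta(n_pops * n_per_group,
                   rep(base, n_per_group) * (1 - jitter_fst) / jitter_fst,
                   rep(1 - base, n_per_group) * (1 - jitter_fst) / jitter_fst),
             nrow = n_pops)
    })
  })
  f <- do.call(cbind, blocks)
  dimnames(f) <- list(sprintf("pop_%03d", seq_len(n_pops)),
                      sprintf("l%03d", seq_len(ncol(f))))
  attr(f, "truth") <- rep(seq_along(groups), each = n_per_group)
  f
}

test_that("k-means separates offset frequency profiles perfectly", {
  n_pops <- 40
  withr::with_seed(3, {
    prof <- runif(n_pops, 0.05, 0.45)
    f <- cbind(matrix(rep(prof, 10), n_pops) + rnorm(n_pops * 10, 0, 0.01),
               matrix(rep(prof + 0.5, 10), n_pops) + rnorm(n_pops * 10, 0, 0.01))
  })
  f <- pmin(pmax(f, 0), 1)
  dimnames(f) <- list(sprintf("p%02d", 1:n_pops), sprintf("l%02d", 1:20))
  cl <- cluster_snps(f, k = 2, seed = 4, n_init = 10)
  truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand(cl$assignment$cluster, truth), 1)
  # labels ordered by grand-mean frequency
  expect_lt(mean(cl$cluster_mean_cline[1, ]), mean(cl$cluster_mean_cline[2, ]))
  # duplicated locus rows land together
  f2 <- cbind(f, dup = f[, 1])
  colnames(f2)[21] <- "l21"
  cl2 <- cluster_snps(f2, k = 2, seed = 5, n_init = 10)
  a <- cl2$assignment
  expect_equal(a$cluster[a$locus == "l21"], a$cluster[a$locus == "l01"])
})

test_that("k = 1 collapses to the column means", {
  withr::with_seed(6, {
    f <- matrix(runif(60), 10, 6,
                dimnames = list(paste0("p", 1:10), paste0("l", 1:6)))
  })
  cl <- cluster_snps(f, k = 1, seed = 7, n_init = 5)
  expect_equal(unique(cl$assignment$cluster), 1L)
  expect_equal(unname(cl$cluster_mean_cline[1, ]), unname(rowMeans(f)),
               tolerance = 1e-12)
})

test_that("variance restoration is the deviation-rescaling identity", {
  env <- seq(-4, 8, length.out = 50)
  f <- planted_freqs(env, list(
    cline_group(8, "rangewide", 2, cline_width_for_span(0.6, 12)),
    cline_group(8, "rangewide", 2, cline_width_for_span(0.6, 12),
                p_lo = 0, p_hi = 0.5)), 8, seed = 8)
  cl <- restore_variance(cluster_snps(f, k = 2, seed = 9, n_init = 10))
  # post-hoc: across-population SD of each restored cline equals the mean
  # member SD, before clipping
  M <- t(f)
  for (c_ in 1:2) {
    members <- cl$assignment$locus[cl$assignment$cluster == c_]
    s_mem <- mean(apply(M[members, , drop = FALSE], 1, sd))
    expect_equal(sd(cl$restored_unclipped[c_, ]), s_mem, tolerance = 1e-10)
  }
  expect_true(all(cl$restored_cline >= 0 & cl$restored_cline <= 1))

  # single-member cluster: restored cline equals that SNP's own cline
  f1 <- f[, c("l001", "l009"), drop = FALSE]
  cl1 <- restore_variance(cluster_snps(f1, k = 2, seed = 10))
  for (c_ in 1:2) {
    member <- cl1$assignment$locus[cl1$assignment$cluster == c_]
    expect_equal(unname(cl1$restored_unclipped[c_, ]), unname(f1[, member]),
                 tolerance = 1e-10)
  }

  # all-identical members: restored equals the shared cline
  fid <- f[, rep("l001", 3)]
  colnames(fid) <- paste0("d", 1:3)
  clid <- restore_variance(cluster_snps(fid, k = 1, seed = 11))
  expect_equal(unname(clid$restored_unclipped[1, ]), unname(f[, "l001"]),
               tolerance = 1e-10)

  # literal method multiplies the mean cline by the member SD
  cl_lit <- restore_variance(cl, method = "literal")
  for (c_ in 1:2) {
    members <- cl$assignment$locus[cl$assignment$cluster == c_]
    s_mem <- mean(apply(M[members, , drop = FALSE], 1, sd))
    expect_equal(unname(cl_lit$restored_unclipped[c_, ]),
                 unname(cl$cluster_mean_cline[c_, ] * s_mem),
                 tolerance = 1e-12)
  }
})

test_that("expected heterozygosity is 2p(1-p) with its known extremes", {
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(c(0, 1)), c(0, 0))
  # concave with the maximum at 0.5 on a grid
  p <- seq(0, 1, by = 0.01)
  he <- expected_heterozygosity(p)
  expect_equal(p[which.max(he)], 0.5)
  expect_true(all(diff(he[p <= 0.5]) >= 0) && all(diff(he[p >= 0.5]) <= 0))
  # counting oracle: genotypes 0,1,2 in one population give p = 0.5
  g <- geno_matrix(matrix(c(0L, 1L, 2L), 3, 1,
                          dimnames = list(paste0("i", 1:3), "l1")))
  f <- pop_allele_frequencies(g)
  expect_equal(unname(expected_heterozygosity(f)[1, 1]), 0.5)
  expect_true(is.na(expected_heterozygosity(NA_real_)))
  expect_error(expected_heterozygosity(1.2), "0, 1")
})

test_that("proportional polymorphism counts polymorphic members", {
  he <- rbind(pA = c(l1 = 0.1, l2 = 0.2, l3 = 0.3, l4 = 0.4),
              pB = c(0, 0, 0, 0),
              pC = c(0.5, 0, 0, 0.2),
              pD = c(NA, 0.1, 0, NA))
  model <- list(k = 1,
                assignment = tibble::tibble(locus = paste0("l", 1:4),
                                            cluster = 1L))
  pp <- proportional_polymorphism(he, model)
  expect_equal(pp$prop_poly, c(1, 0, 0.5, 0.5))
  # 3 of 4 polymorphic
  he2 <- rbind(pA = c(l1 = 0.1, l2 = 0.2, l3 = 0, l4 = 0.4))
  expect_equal(proportional_polymorphism(he2, model)$prop_poly, 0.75)
})

test_that("cline extent classification recovers planted cline shapes", {
  env <- setNames(seq(-4, 8, length.out = 100), sprintf("pop_%03d", 1:100))
  span <- 12
  shapes <- rbind(
    loc = simulate_cline_frequencies(env, cline_group(
      1, "localized", center = 3, width = cline_width_for_span(0.05, span))),
    rw = simulate_cline_frequencies(env, cline_group(
      1, "rangewide", center = 2, width = cline_width_for_span(0.6, span))),
    flat = rep(0.4, 100))
  colnames(shapes) <- names(env)
  # the constant cline cannot support a logistic fit and falls back to flat
  expect_warning(ext <- classify_extent(shapes, env), "flat")
  expect_equal(ext$label, c("localized", "rangewide", "flat"))
  expect_gt(ext$active_hi[1] - ext$active_lo[1], 0)
})

test_that("planted cline groups are recovered end to end", {
  env <- seq(-4, 8, length.out = 90)
  groups <- list(
    cline_group(15, "rangewide", center = 0,
                width = cline_width_for_span(0.6, 12), p_lo = 0, p_hi = 0.9),
    cline_group(15, "rangewide", center = 4,
                width = cline_width_for_span(0.6, 12), p_lo = 0.1, p_hi = 1),
    cline_group(15, "localized", center = 5,
                width = cline_width_for_span(0.05, 12), p_lo = 0, p_hi = 1))
  f <- planted_freqs(env, groups, 15, seed = 13)
  cl <- restore_variance(cluster_snps(f, k = 3, seed = 14, n_init = 30))
  ari <- adjusted_rand(cl$assignment$cluster, attr(f, "truth"))
  expect_gte(ari, 0.8)
  ext <- classify_extent(cl, setNames(env, rownames(f)))
  expect_equal(sort(ext$label), c("localized", "rangewide", "rangewide"))
})
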