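#' Bioclimatic variable names
#'
#' Abbreviations of the 19 bioclimatic normals used throughout the package
#' (mean annual temperature, warmest/coldest month temperatures,
#' continentality, precipitation and heat:moisture indices, degree-days,
#' frost-free descriptors, snow, temperature extremes, evaporation and
#' moisture deficit).
#' @export
bioclim_names <- c("MAT", "MWMT", "MCMT", "TD", "MAP", "MSP", "AHM", "SHM",
                   "DD_0", "DD5", "NFFD", "FFP", "bFFP", "eFFP", "PAS",
                   "EMT", "EXT", "Eref", "CMD")

#' Specify a group of clinal loci
#'
#' Describes a set of loci whose positive-effect-allele frequency follows a
#' shared logistic cline along the environmental gradient:
#' `p(env) = p_lo + (p_hi - p_lo) * expit((env - center) / width)`.
#' A *rangewide* group uses a width whose 10–90% transition spans most of the
#' gradient; a *localized* group confines the transition to a narrow
#' sub-interval, so standing variation at its loci exists only in part of the
#' range.
#'
#' @param n_loci Number of loci in the group.
#' @param kind `"rangewide"` or `"localized"` (the planted truth label).
#' @param center Gradient value at the cline midpoint (env units).
#' @param width Logistic scale parameter (env units); the 10–90% transition
#'   occupies `2 * width * log(9)` env units.
#' @param p_lo,p_hi Frequencies approached at the low/high end of the
#'   gradient; `0 <= p_lo < p_hi <= 1` (or `p_lo == p_hi` for a flat group).
#' @return A list of class `cline_group`.
#' @seealso [cline_width_for_span()] to set `width` from the fraction of the
#'   gradient the transition should occupy.
#' @export
cline_group <- function(n_loci, kind = c("rangewide", "localized"),
                        center, width, p_lo = 0.05, p_hi = 0.95) {
  kind <- match.arg(kind)
  if (!is.numeric(width) || width <= 0) abort("`width` must be > 0.")
  assert_scalar_in(p_lo, 0, 1, "p_lo")
  assert_scalar_in(p_hi, 0, 1, "p_hi")
  if (p_lo > p_hi) abort("`p_lo` must be <= `p_hi`.")
  structure(list(n_loci = as.integer(n_loci), kind = kind, center = center,
                 width = width, p_lo = p_lo, p_hi = p_hi),
            class = "cline_group")
}

#' Logistic width for a target transition span
#'
#' Returns the logistic `width` such that the 10–90% frequency transition of
#' [simulate_cline_frequencies()] occupies `fraction * span` env units.
#'
#' @param fraction Fraction of the gradient span the transition occupies.
#' @param span Width of the environmental gradient (max - min, env units).
#' @export
cline_width_for_span <- function(fraction, span) {
  fraction * span / (2 * log(9))
}

#' Specify a simulated trait
#'
#' An additive polygenic trait measured in a blocked common garden. Each
#' causal locus contributes `effect_size` per copy of its counted allele;
#' block and location-within-block effects and residual noise are Gaussian.
#'
#' @param name Trait name.
#' @param causal_groups Integer indices into the config's `cline_groups`
#'   whose member loci are causal for this trait (may be empty).
#' @param effect_size Additive effect per allele copy, recycled over causal
#'   loci (trait units per copy).
#' @param sigma_block,sigma_loc,sigma_e Standard deviations of block,
#'   location-within-block and residual effects (trait units).
#' @param prop_measured Fraction of seedlings phenotyped for this trait
#'   (some traits are scored on a subset).
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name, causal_groups = integer(), effect_size = 0.2,
                       sigma_block = 0.5, sigma_loc = 0.3, sigma_e = 1,
                       prop_measured = 1) {
  stopifnot(sigma_block >= 0, sigma_loc >= 0, sigma_e >= 0)
  assert_scalar_in(prop_measured, 0, 1, "prop_measured", open_lo = TRUE)
  structure(list(name = name, causal_groups = as.integer(causal_groups),
                 effect_size = effect_size, sigma_block = sigma_block,
                 sigma_loc = sigma_loc, sigma_e = sigma_e,
                 prop_measured = prop_measured),
            class = "trait_spec")
}

#' Ground-truth configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: populations spread
#' along a one-dimensional environmental gradient (a mean-annual-temperature
#' proxy), neutral structured control SNPs, candidate SNPs with and without
#' planted logistic clines, additive polygenic common-garden phenotypes with
#' block/location random effects, and correlated bioclimatic variables.
#'
#' Defaults emulate a western-Canadian conifer panel: 280 populations of 10
#' seedlings on a -4 to 8 degree gradient, 4,000 intergenic control SNPs and
#' 4,000 candidate SNPs (of which three groups of 40 carry planted clines),
#' weak neutral structure (FST 0.016), and the 19 named bioclimatic
#' variables with mean annual temperature as the driving variable.
#'
#' @param n_pops Number of populations (>= 3).
#' @param n_per_pop Seedlings sampled per population.
#' @param env_gradient Per-population gradient value; default equally spaced
#'   on `[-4, 8]`.
#' @param n_control_loci Neutral intergenic control SNPs.
#' @param n_neutral_candidate_loci Candidate SNPs with no planted cline.
#' @param cline_groups List of [cline_group()]s (the planted adaptive loci).
#' @param traits List of [trait_spec()]s.
#' @param n_blocks,n_locs_per_block Common-garden design.
#' @param fst_neutral Balding–Nichols drift parameter in (0, 1).
#' @param n_climate_vars Number of bioclimatic variables (>= 2).
#' @param climate_noise_sd Noise of non-driving climate variables relative to
#'   the gradient's SD (unitless).
#' @param missing_rate Genotype missingness rate in `[0, 1)`.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_pops = 280,
                         n_per_pop = 10,
                         env_gradient = NULL,
                         n_control_loci = 4000,
                         n_neutral_candidate_loci = 3880,
                         cline_groups = NULL,
                         traits = NULL,
                         n_blocks = 8,
                         n_locs_per_block = 10,
                         fst_neutral = 0.016,
                         n_climate_vars = 19,
                         climate_noise_sd = 0.3,
                         missing_rate = 0.02,
                         seed = 1L) {
  if (n_pops < 3) abort("`n_pops` must be >= 3.")
  assert_scalar_in(fst_neutral, 0, 1, "fst_neutral", open_lo = TRUE, open_hi = TRUE)
  assert_scalar_in(missing_rate, 0, 1, "missing_rate", open_hi = TRUE)
  if (n_climate_vars < 2) abort("`n_climate_vars` must be >= 2.")
  if (is.null(env_gradient)) env_gradient <- seq(-4, 8, length.out = n_pops)
  if (length(env_gradient) != n_pops || any(!is.finite(env_gradient))) {
    abort("`env_gradient` must be a finite vector of length `n_pops`.")
  }
  span <- diff(range(env_gradient))
  if (is.null(cline_groups)) {
    cline_groups <- list(
      cline_group(40, "rangewide", center = stats::median(env_gradient),
                  width = cline_width_for_span(0.8, span)),
      cline_group(40, "rangewide", center = quantile(env_gradient, 0.35),
                  width = cline_width_for_span(0.6, span)),
      cline_group(40, "localized", center = quantile(env_gradient, 0.7),
                  width = cline_width_for_span(0.08, span))
    )
  }
  if (is.null(traits)) {
    traits <- list(
      trait_spec("growth_initiation", causal_groups = 2L, effect_size = 0.15),
      trait_spec("growth_cessation", causal_groups = 1L, effect_size = 0.2),
      trait_spec("cold_injury", causal_groups = c(1L, 3L), effect_size = 0.2,
                 prop_measured = 0.6),
      trait_spec("shoot_mass", causal_groups = 2L, effect_size = 0.2)
    )
  }
  structure(list(n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
                 env_gradient = as.numeric(env_gradient),
                 n_control_loci = as.integer(n_control_loci),
                 n_neutral_candidate_loci = as.integer(n_neutral_candidate_loci),
                 cline_groups = cline_groups, traits = traits,
                 n_blocks = as.integer(n_blocks),
                 n_locs_per_block = as.integer(n_locs_per_block),
                 fst_neutral = fst_neutral,
                 n_climate_vars = as.integer(n_climate_vars),
                 climate_noise_sd = climate_noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "truth_config")
}

#' Logistic cline frequencies along a gradient
#'
#' Evaluates a [cline_group()]'s allele-frequency cline at each gradient
#' value: `p = p_lo + (p_hi - p_lo) * expit((env - center) / width)`.
#'
#' @param env Numeric vector of gradient values (finite).
#' @param group A [cline_group()] (or a list with the same fields).
#' @return Numeric vector of frequencies in `[p_lo, p_hi]`.
#' @export
simulate_cline_frequencies <- function(env, group) {
  if (any(!is.finite(env))) abort("`env` must be finite.")
  if (group$width <= 0) abort("`width` must be > 0.")
  group$p_lo + (group$p_hi - group$p_lo) * plogis((env - group$center) / group$width)
}

#' Neutral structured population allele frequencies
#'
#' Draws per-locus ancestral frequencies from Uniform(0.05, 0.95) and
#' per-population frequencies from the Balding–Nichols model,
#' `Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)`, giving expected differentiation
#' close to the configured `fst`.
#'
#' @param n_loci,n_pops Dimensions.
#' @param fst Drift parameter in (0, 1).
#' @param seed Integer seed (or NULL to use the current RNG stream).
#' @return Matrix of frequencies (populations x loci).
#' @export
simulate_neutral_frequencies <- function(n_loci, n_pops, fst, seed = NULL) {
  assert_scalar_in(fst, 0, 1, "fst", open_lo = TRUE, open_hi = TRUE)
  with_seed(seed, {
    p_anc <- runif(n_loci, 0.05, 0.95)
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    freq <- matrix(rbeta(n_pops * n_loci, rep(a, each = n_pops),
                         rep(b, each = n_pops)),
                   nrow = n_pops, ncol = n_loci)
    attr(freq, "ancestral") <- p_anc
    freq
  })
}

#' Sample genotypes from population allele frequencies
#'
#' Genotypes are Binomial(2, p) draws per individual per locus; missing
#' entries are then set uniformly at random at `missing_rate`.
#'
#' @param pop_frequencies Populations x loci frequency matrix (rownames are
#'   population ids, colnames locus ids; defaults supplied if absent).
#' @param n_per_pop Individuals per population.
#' @param missing_rate Missingness in `[0, 1)`.
#' @param seed Integer seed.
#' @param loci Optional locus metadata tibble passed to [geno_matrix()].
#' @return A [geno_matrix()].
#' @export
sample_genotypes <- function(pop_frequencies, n_per_pop, missing_rate = 0,
                             seed = NULL, loci = NULL) {
  assert_scalar_in(missing_rate, 0, 1, "missing_rate", open_hi = TRUE)
  if (any(pop_frequencies < 0 | pop_frequencies > 1, na.rm = TRUE)) {
    abort("frequencies must be in [0, 1].")
  }
  n_pops <- nrow(pop_frequencies)
  n_loci <- ncol(pop_frequencies)
  pops <- rownames(pop_frequencies) %||% sprintf("pop_%03d", seq_len(n_pops))
  loc_ids <- colnames(pop_frequencies) %||% sprintf("locus_%05d", seq_len(n_loci))
  with_seed(seed, {
    n_ind <- n_pops * n_per_pop
    pop_of <- rep(seq_len(n_pops), each = n_per_pop)
    codes <- matrix(rbinom(n_ind * n_loci, 2L,
                           pop_frequencies[pop_of, , drop = FALSE]),
                    nrow = n_ind, ncol = n_loci)
    if (missing_rate > 0) {
      codes[runif(length(codes)) < missing_rate] <- NA_integer_
    }
    rownames(codes) <- paste0(pops[pop_of], "_i", rep(seq_len(n_per_pop), n_pops))
    colnames(codes) <- loc_ids
    geno_matrix(codes,
                loci = loci,
                individuals = tibble(individual = rownames(codes),
                                     population = pops[pop_of]))
  })
}

#' Simulate blocked common-garden phenotypes
#'
#' Builds additive polygenic phenotypes
#' `y = sum(effect * allele count) + B_j + L(B)_jk + e` with Gaussian block,
#' location-within-block and residual effects. Individuals are randomized to
#' blocks and locations irrespective of population, as in a common garden.
#' Missing causal genotypes are mean-imputed per locus when forming genetic
#' values.
#'
#' @param genotypes A [geno_matrix()].
#' @param traits List of [trait_spec()]s.
#' @param effects Tibble `trait, locus, effect` (trait units per copy of the
#'   counted allele). Usually built by [simulate_dataset()]; supply directly
#'   for custom truths.
#' @param n_blocks,n_locs_per_block Design dimensions.
#' @param seed Integer seed.
#' @return A tibble: `individual`, `population`, `block`, `location`, then
#'   one column per trait (NA where the trait was not measured).
#' @export
simulate_phenotypes <- function(genotypes, traits, effects,
                                n_blocks = 8, n_locs_per_block = 10,
                                seed = NULL) {
  ind <- geno_individuals(genotypes)
  n <- nrow(ind)
  if (!all(effects$locus %in% geno_loci(genotypes)$locus)) {
    abort("`effects` refers to loci absent from `genotypes`.")
  }
  with_seed(seed, {
    block <- sprintf("B%02d", sample(rep_len(seq_len(n_blocks), n)))
    loc <- sprintf("%s_L%02d", block,
                   sample(rep_len(seq_len(n_locs_per_block), n)))
    out <- tibble(individual = ind$individual, population = ind$population,
                  block = block, location = loc)
    codes <- geno_codes(genotypes)
    for (tr in traits) {
      eff <- effects[effects$trait == tr$name, , drop = FALSE]
      gval <- rep(0, n)
      if (nrow(eff)) {
        X <- codes[, eff$locus, drop = FALSE]
        X <- apply(X, 2L, function(col) {
          col[is.na(col)] <- mean(col, na.rm = TRUE)
          col
        })
        gval <- drop(X %*% eff$effect)
      }
      b_eff <- rnorm(n_blocks, 0, tr$sigma_block)
      names(b_eff) <- sprintf("B%02d", seq_len(n_blocks))
      locs <- unique(loc)
      l_eff <- rnorm(length(locs), 0, tr$sigma_loc)
      names(l_eff) <- locs
      y <- gval + b_eff[block] + l_eff[loc] + rnorm(n, 0, tr$sigma_e)
      if (tr$prop_measured < 1) {
        y[sample.int(n, round((1 - tr$prop_measured) * n))] <- NA_real_
      }
      out[[tr$name]] <- unname(y)
    }
    out
  })
}

#' Simulate correlated bioclimatic variables along the gradient
#'
#' Each variable is an affine function of the gradient plus Gaussian noise,
#' `x_v = a_v + b_v * env + noise`. The first variable (MAT by default) is
#' the *driving* variable: it has the largest signal-to-noise ratio, so it
#' tracks the gradient most faithfully. Some variable pairs share noise to
#' emulate the strong collinearity of real bioclimatic normals.
#'
#' @param env Per-population gradient values.
#' @param n_vars Number of variables (>= 2).
#' @param climate_noise_sd Noise SD of non-driving variables as a fraction of
#'   `sd(env)`; the driving variable gets a tenth of this.
#' @param seed Integer seed.
#' @param populations Optional population ids (first column of the output).
#' @return A tibble `population` + one column per variable, with attributes
#'   `driving` (name of the driving variable) and `slopes`.
#' @export
generate_climate <- function(env, n_vars = 19, climate_noise_sd = 0.3,
                             seed = NULL, populations = NULL) {
  if (n_vars < 2) abort("`n_vars` must be >= 2.")
  if (any(!is.finite(env))) abort("`env` must be finite.")
  n <- length(env)
  pops <- populations %||% sprintf("pop_%03d", seq_len(n))
  nm <- if (n_vars <= length(bioclim_names)) bioclim_names[seq_len(n_vars)] else
    c(bioclim_names, sprintf("VAR%02d", seq_len(n_vars - length(bioclim_names))))
  with_seed(seed, {
    sde <- sd(env)
    if (!is.finite(sde) || sde == 0) sde <- 1
    b <- runif(n_vars, 0.4, 0.95) * sample(c(-1, 1), n_vars, replace = TRUE)
    b[1] <- 1
    a <- runif(n_vars, -1, 1)
    noise <- matrix(rnorm(n * n_vars), n, n_vars)
    # correlated pairs (2,3), (4,5), ... share most of their noise
    for (j in seq(3, n_vars, by = 2)) {
      noise[, j] <- 0.9 * noise[, j - 1] + sqrt(1 - 0.81) * noise[, j]
    }
    sd_v <- rep(climate_noise_sd * sde, n_vars)
    sd_v[1] <- 0.1 * climate_noise_sd * sde
    x <- sweep(outer(env, b), 2L, a, `+`) + sweep(noise, 2L, sd_v, `*`)
    out <- as_tibble(as.data.frame(x, col.names = nm))
    names(out) <- nm
    out <- dplyr::bind_cols(tibble(population = pops), out)
    attr(out, "driving") <- nm[1]
    attr(out, "slopes") <- setNames(b, nm)
    out
  })
}

#' Generate a full synthetic dataset with ground truth
#'
#' Assembles the population panel, genotype matrix (control + candidate SNPs
#' with planted clines), climate table, blocked common-garden phenotypes and
#' truth labels from a [truth_config()]. Control loci each sit on their own
#' contig; candidate loci are grouped onto contigs of 1–3 SNPs so that
#' one-per-contig reduction is exercised.
#'
#' @param config A [truth_config()].
#' @return A list of class `synthetic_dataset` with elements `panel`,
#'   `genotypes`, `climate`, `phenotypes`, `truth` (list: `loci`, `effects`,
#'   `driving_var`, `env`), and `freq_truth` (populations x loci matrix of
#'   the generating frequencies).
#' @export
simulate_dataset <- function(config = truth_config()) {
  stopifnot(inherits(config, "truth_config"))
  cfg <- config
  env <- cfg$env_gradient
  n_pops <- cfg$n_pops
  pops <- sprintf("pop_%03d", seq_len(n_pops))

  n_cline <- sum(vapply(cfg$cline_groups, `[[`, integer(1), "n_loci"))
  n_cand <- cfg$n_neutral_candidate_loci + n_cline
  n_all <- cfg$n_control_loci + n_cand

  # frequencies: controls + neutral candidates are Balding-Nichols; cline loci
  # follow their group's logistic plus a little Balding-Nichols jitter so they
  # are not deterministic copies of one another
  freq_neutral <- simulate_neutral_frequencies(
    cfg$n_control_loci + cfg$n_neutral_candidate_loci, n_pops,
    cfg$fst_neutral, seed = child_seed(cfg$seed, 1))
  cline_freq <- NULL
  cline_meta <- NULL
  if (n_cline > 0) {
    jit_fst <- max(cfg$fst_neutral, 1e-4)
    blocks <- with_seed(child_seed(cfg$seed, 2), {
      lapply(seq_along(cfg$cline_groups), function(gi) {
        gr <- cfg$cline_groups[[gi]]
        base <- simulate_cline_frequencies(env, gr)
        f <- matrix(rbeta(n_pops * gr$n_loci,
                          rep(base, gr$n_loci) * (1 - jit_fst) / jit_fst,
                          rep(1 - base, gr$n_loci) * (1 - jit_fst) / jit_fst),
                    nrow = n_pops)
        list(freq = f,
             meta = tibble(group = gi, kind = gr$kind, center = gr$center,
                           width = gr$width, p_lo = gr$p_lo, p_hi = gr$p_hi,
                           .rows = gr$n_loci))
      })
    })
    cline_freq <- do.call(cbind, lapply(blocks, `[[`, "freq"))
    cline_meta <- dplyr::bind_rows(lapply(blocks, `[[`, "meta"))
  }
  freq <- cbind(freq_neutral, cline_freq)
  rownames(freq) <- pops
  loc_ids <- sprintf("locus_%05d", seq_len(n_all))
  colnames(freq) <- loc_ids

  cls <- rep(c("control", "candidate"), c(cfg$n_control_loci, n_cand))
  # contigs: controls singleton; candidates in runs of 1-3 SNPs
  cand_sizes <- with_seed(child_seed(cfg$seed, 3),
                          sample(1:3, n_cand, replace = TRUE))
  cand_contig <- rep(seq_along(cand_sizes), cand_sizes)[seq_len(n_cand)]
  contig <- c(sprintf("ctg_ctl_%05d", seq_len(cfg$n_control_loci)),
              sprintf("ctg_%05d", cand_contig))
  loci <- tibble(locus = loc_ids, contig = contig, class = cls,
                 ref = "A", alt = "B")

  genotypes <- sample_genotypes(freq, cfg$n_per_pop,
                                missing_rate = cfg$missing_rate,
                                seed = child_seed(cfg$seed, 4), loci = loci)

  climate <- generate_climate(env, cfg$n_climate_vars, cfg$climate_noise_sd,
                              seed = child_seed(cfg$seed, 5), populations = pops)

  # truth labels (one row per locus; cline members carry their group params)
  truth_loci <- tibble(locus = loc_ids, class = cls,
                       group = NA_integer_, kind = NA_character_,
                       center = NA_real_, width = NA_real_,
                       p_lo = NA_real_, p_hi = NA_real_)
  if (n_cline > 0) {
    idx <- (n_all - n_cline + 1):n_all
    truth_loci$group[idx] <- cline_meta$group
    truth_loci$kind[idx] <- cline_meta$kind
    truth_loci$center[idx] <- cline_meta$center
    truth_loci$width[idx] <- cline_meta$width
    truth_loci$p_lo[idx] <- cline_meta$p_lo
    truth_loci$p_hi[idx] <- cline_meta$p_hi
  }

  effects <- dplyr::bind_rows(lapply(cfg$traits, function(tr) {
    loci_tr <- truth_loci$locus[!is.na(truth_loci$group) &
                                  truth_loci$group %in% tr$causal_groups]
    if (!length(loci_tr)) return(NULL)
    tibble(trait = tr$name, locus = loci_tr,
           effect = rep_len(tr$effect_size, length(loci_tr)))
  }))
  truth_loci$causal <- truth_loci$locus %in% effects$locus

  phenotypes <- simulate_phenotypes(genotypes, cfg$traits, effects,
                                    n_blocks = cfg$n_blocks,
                                    n_locs_per_block = cfg$n_locs_per_block,
                                    seed = child_seed(cfg$seed, 6))

  panel <- with_seed(child_seed(cfg$seed, 7), {
    rng <- range(env)
    tibble(population = pops,
           latitude = 60 - 10 * (env - rng[1]) / diff(rng) + rnorm(n_pops, 0, 0.3),
           longitude = -125 + runif(n_pops, 0, 10),
           elevation = pmax(0, 1500 - 80 * env + rnorm(n_pops, 0, 150)),
           n = cfg$n_per_pop, env = env)
  })

  structure(list(panel = panel, genotypes = genotypes, climate = climate,
                 phenotypes = phenotypes,
                 truth = list(loci = truth_loci, effects = effects,
                              driving_var = attr(climate, "driving"),
                              env = setNames(env, pops), config = cfg),
                 freq_truth = freq),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d populations, %d individuals, %d loci\n",
              nrow(x$panel), nrow(geno_individuals(x$genotypes)),
              ncol(x$genotypes)))
  tl <- x$truth$loci
  cat(sprintf("  planted cline loci: %d (%s); traits: %s\n",
              sum(!is.na(tl$group)),
              paste(unique(stats::na.omit(tl$kind)), collapse = "/"),
              paste(unique(x$truth$effects$trait), collapse = ", ")))
  invisible(x)
}
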