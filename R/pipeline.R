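#' Pipeline configuration
#'
#' Collects every stage parameter of the analysis with explicit seeds so a
#' run is fully reproducible from its config.
#'
#' @param truth A [truth_config()] describing the synthetic dataset (or NULL
#'   when supplying a pre-built dataset to [run_pipeline()]).
#' @param gpa_fraction Bottom-fraction for candidate selection (default
#'   0.01).
#' @param gea_K Dual-rank cutoff per chain (default 300).
#' @param gea_N Top-N loci per variable for driver analysis (default 300).
#' @param n_chains Omega bootstrap runs / chains (default 3).
#' @param tau_grid Prior scales for the Bayes factor.
#' @param k_clusters k-means cluster count (default 6).
#' @param n_init k-means restarts.
#' @param folds CV folds (default 5).
#' @param n_pcs_climate Climate PCs for the association threshold (default
#'   5).
#' @param n_pcs_driver PCs of GEA frequencies in driver regressions
#'   (default 4).
#' @param threshold_percentile Control percentile calibrating the
#'   climate-association threshold (default 99.7).
#' @param rarefy_size Control rarefaction subsample size (default 186).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(truth = truth_config(),
                            gpa_fraction = 0.01,
                            gea_K = 300,
                            gea_N = 300,
                            n_chains = 3,
                            tau_grid = c(0.01, 0.1, 1),
                            k_clusters = 6,
                            n_init = 50,
                            folds = 5,
                            n_pcs_climate = 5,
                            n_pcs_driver = 4,
                            threshold_percentile = 99.7,
                            rarefy_size = 186,
                            seed = 1L) {
  assert_scalar_in(gpa_fraction, 0, 1, "gpa_fraction",
                   open_lo = TRUE, open_hi = TRUE)
  assert_scalar_in(threshold_percentile, 0, 100, "threshold_percentile")
  if (gea_K < 1 || gea_N < 1 || k_clusters < 1 || folds < 1) {
    abort("gea_K, gea_N, k_clusters and folds must be >= 1.")
  }
  structure(list(truth = truth, gpa_fraction = gpa_fraction, gea_K = gea_K,
                 gea_N = gea_N, n_chains = n_chains, tau_grid = tau_grid,
                 k_clusters = k_clusters, n_init = n_init, folds = folds,
                 n_pcs_climate = n_pcs_climate, n_pcs_driver = n_pcs_driver,
                 threshold_percentile = threshold_percentile,
                 rarefy_size = rarefy_size, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains the stages in analysis order on a synthetic (or supplied)
#' dataset: simulate, adjust phenotypes, structure objects (GRM, population
#' frequencies, Omega), GPA scan with candidate selection and PEA
#' polarization, GEA scoring with dual-rank filtering, explained-variance
#' curves for the predictor sets, climate-driver ranking with congruence,
#' and cline clustering with variance restoration, He and proportional
#' polymorphism. When `out_dir` is given, stage artifacts are written as
#' TSV/JSON together with a manifest (config echo + hash).
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional pre-built [simulate_dataset()] result; default is
#'   simulated from `config$truth`.
#' @param out_dir Optional output directory.
#' @param stages Character vector of stages to run (in order); default all.
#' @return A named list of stage artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         out_dir = NULL,
                         stages = c("simulate", "adjust", "structure", "gpa",
                                    "gea", "varexp", "drivers", "clines")) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)
  seed <- config$seed

  if (is.null(dataset)) {
    if (is.null(config$truth)) abort("No dataset and no truth config.")
    dataset <- simulate_dataset(config$truth)
  }
  res$dataset <- dataset
  g <- dataset$genotypes
  li <- geno_loci(g)
  control_loci <- li$locus[li$class == "control"]
  candidate_loci <- li$locus[li$class == "candidate"]
  traits <- unique(vapply(dataset$truth$config$traits, `[[`, character(1),
                          "name"))

  if ("adjust" %in% stages) {
    res$adjusted <- adjust_phenotypes(dataset$phenotypes, traits)
    res$pop_means <- population_means(res$adjusted, dataset$panel)
  }

  if ("structure" %in% stages) {
    res$grm <- compute_grm(g, loci = control_loci)
    res$freq_minor <- pop_allele_frequencies(g, allele = "minor")
    res$omega <- estimate_pop_covariance(
      res$freq_minor[, control_loci, drop = FALSE],
      n_runs = config$n_chains, seed = child_seed(seed, 11),
      n_alleles = attr(res$freq_minor, "n_alleles")[, control_loci])
  }

  if ("gpa" %in% stages) {
    res$gpa <- purrr::map(setNames(traits, traits), function(tr) {
      ph <- res$adjusted[res$adjusted$trait == tr, ]
      scan <- mlma_scan(g, ph, res$grm, loci = candidate_loci, trait = tr)
      dedup <- reduce_one_per_contig(scan)
      cands <- polarize_pea(select_candidates(dedup, config$gpa_fraction))
      list(scan = scan, dedup = dedup, candidates = cands)
    })
  }

  if ("gea" %in% stages) {
    contigs <- setNames(li$contig, li$locus)
    climate_vars <- setdiff(
      names(dataset$climate)[vapply(dataset$climate, is.numeric, logical(1))],
      "population")
    cand_freq <- res$freq_minor[, candidate_loci, drop = FALSE]
    res$gea <- purrr::map(setNames(climate_vars, climate_vars), function(v) {
      sc <- score_env_associations(cand_freq, res$omega, dataset$climate,
                                   variable = v, tau_grid = config$tau_grid,
                                   contigs = contigs)
      dedup <- reduce_one_per_contig_gea(sc)
      list(scores = dedup,
           candidates = dual_rank_filter(dedup, K = config$gea_K),
           top = suppressWarnings(top_n_by_rank(dedup, N = config$gea_N)))
    })
  }

  if ("varexp" %in% stages) {
    res$threshold <- calibrate_threshold(
      res$freq_minor[, control_loci, drop = FALSE], dataset$climate,
      percentile = config$threshold_percentile, n_pcs = config$n_pcs_climate)
    geo <- as.matrix(dataset$panel[, c("latitude", "longitude", "elevation")])
    rownames(geo) <- dataset$panel$population
    clim <- as.matrix(dplyr::select(dataset$climate, -"population"))
    rownames(clim) <- dataset$climate$population
    res$varexp <- purrr::map(setNames(traits, traits), function(tr) {
      pm <- res$pop_means[res$pop_means$trait == tr & res$pop_means$n > 0, ]
      y <- setNames(pm$mean_residual, pm$population)
      cands <- res$gpa[[tr]]$candidates
      pea_freq <- pop_allele_frequencies(
        g, loci = cands$locus, allele = "pea",
        pea = cands[, c("locus", "pea_is_counted")])
      clim_assoc <- select_climate_associated(
        res$freq_minor[, cands$locus, drop = FALSE], dataset$climate,
        threshold = res$threshold, n_pcs = config$n_pcs_climate)
      sets <- list(
        geography = geo, climate = clim,
        full_array = res$freq_minor,
        control = res$freq_minor[, control_loci, drop = FALSE],
        gpa = pea_freq,
        gpa_climate_associated =
          pea_freq[, clim_assoc$locus[clim_assoc$selected], drop = FALSE])
      curves <- purrr::imap(sets, function(tab, nm) {
        if (ncol(tab) < 1) return(NULL)
        cv_r2_curve(y, tab, m_max = min(10, ncol(tab)), folds = config$folds,
                    seed = child_seed(seed, 21), set = nm, trait = tr)
      })
      list(curves = dplyr::bind_rows(curves),
           climate_associated = clim_assoc)
    })
  }

  if ("drivers" %in% stages) {
    pm_wide <- res$pop_means |>
      dplyr::filter(.data$n > 0) |>
      tidyr::pivot_wider(id_cols = "population", names_from = "trait",
                         values_from = "mean_residual")
    pheno_tab <- as.matrix(dplyr::select(pm_wide, -"population"))
    rownames(pheno_tab) <- pm_wide$population
    genomic_fun <- function(v) {
      res$freq_minor[, res$gea[[v]]$top, drop = FALSE]
    }
    res$drivers <- rank_climate_drivers(
      dataset$climate,
      sources = list(genomic = genomic_fun, seedling_phenotypes = pheno_tab),
      n_pcs = config$n_pcs_driver, folds = config$folds,
      seed = child_seed(seed, 31))
    res$congruence <- congruence(
      dplyr::filter(res$drivers, .data$source == "genomic"),
      dplyr::filter(res$drivers, .data$source == "seedling_phenotypes"))
  }

  if ("clines" %in% stages) {
    # cline analysis on the climate-associated candidates of the trait with
    # the most of them (the paper's focal trait is its cold-injury set)
    focal <- names(which.max(vapply(res$varexp, function(v)
      sum(v$climate_associated$selected), numeric(1))))
    cands <- res$gpa[[focal]]$candidates
    sel <- res$varexp[[focal]]$climate_associated
    loci_cl <- intersect(sel$locus[sel$selected], cands$locus)
    if (length(loci_cl) >= max(config$k_clusters, 2L)) {
      pea_freq <- pop_allele_frequencies(
        g, loci = loci_cl, allele = "pea",
        pea = cands[, c("locus", "pea_is_counted")])
      cl <- cluster_snps(pea_freq, k = config$k_clusters,
                         seed = child_seed(seed, 41),
                         n_init = config$n_init)
      cl <- restore_variance(cl)
      he <- expected_heterozygosity(pea_freq)
      env <- dataset$truth$env
      res$clines <- list(
        trait = focal, model = cl,
        he = he,
        prop_poly = proportional_polymorphism(he, cl),
        extent = classify_extent(cl, env))
    } else {
      warn("Too few climate-associated candidates for cline clustering.")
    }
  }

  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

# Write stage artifacts + manifest to a directory.
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  manifest <- list(
    config = cfg[setdiff(names(cfg), "truth")],
    truth = if (!is.null(cfg$truth)) {
      cfg$truth[c("n_pops", "n_per_pop", "n_control_loci",
                  "n_neutral_candidate_loci", "fst_neutral", "seed")]
    },
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("genecol")),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  if (!is.null(res$dataset$truth)) {
    jsonlite::write_json(res$dataset$truth$loci,
                         file.path(out_dir, "truth_labels.json"),
                         auto_unbox = TRUE, na = "null")
  }
  if (!is.null(res$pop_means)) {
    readr::write_tsv(res$pop_means, file.path(out_dir, "population_means.tsv"))
  }
  if (!is.null(res$gpa)) {
    readr::write_tsv(
      dplyr::bind_rows(purrr::map(res$gpa, function(x)
        as_tibble(x$candidates))),
      file.path(out_dir, "gpa_candidates.tsv"))
  }
  if (!is.null(res$gea)) {
    readr::write_tsv(
      dplyr::bind_rows(purrr::map(res$gea, function(x)
        as_tibble(x$candidates))),
      file.path(out_dir, "gea_candidates.tsv"))
  }
  if (!is.null(res$varexp)) {
    readr::write_tsv(
      dplyr::bind_rows(purrr::map(res$varexp, "curves")),
      file.path(out_dir, "explained_variance_curves.tsv"))
  }
  if (!is.null(res$drivers)) {
    readr::write_tsv(res$drivers, file.path(out_dir, "driver_ranking.tsv"))
    readr::write_tsv(res$congruence, file.path(out_dir, "congruence.tsv"))
  }
  if (!is.null(res$clines)) {
    readr::write_tsv(res$clines$model$assignment,
                     file.path(out_dir, "cline_clusters.tsv"))
    readr::write_tsv(res$clines$extent, file.path(out_dir, "cline_extent.tsv"))
    readr::write_tsv(res$clines$prop_poly,
                     file.path(out_dir, "proportional_polymorphism.tsv"))
  }
  invisible(out_dir)
}
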