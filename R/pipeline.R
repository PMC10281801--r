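#' Read a YAML run configuration
#'
#' Missing fields fall back to the study conventions: association radius
#' 1.85 m, kernel smoothing 7 m, minimum 30 sightings for social metrics and
#' 25 for home ranges, 50% core contour.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(association_radius = 1.85, smoothing_h = 7,
                   cell_size = 1, min_sightings_social = 30,
                   min_sightings_hr = 25, contour_level = 0.5,
                   iterations = 10000, burn_in = 2000, thinning = 5,
                   seed = 1L, maturity_cutoff = NULL,
                   min_ess = 1000, max_lag1 = 0.1)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  stopifnot(cfg$association_radius > 0, cfg$smoothing_h > 0,
            cfg$min_sightings_social > 0, cfg$min_sightings_hr > 0,
            !is.null(cfg$seed))
  cfg
}

# Gaussian-modelled trait columns for a category (internal).
gaussian_cols <- function(category) {
  paste0(c("tendency_", "hwi_", "density_"), category)
}

# Prepare one sex x category modelling frame: filter, complete-case the four
# traits, standardize Gaussian traits and covariates (internal).
prep_model_frame <- function(measures, sex, category, covars) {
  cols <- paste0(c("tendency_", "degree_", "hwi_", "density_"), category)
  d <- measures[measures$sex == sex, , drop = FALSE]
  d <- d[stats::complete.cases(d[, cols]), , drop = FALSE]
  if (nrow(d) < 4) stop("too few rows for sex ", sex, ", category ", category)
  d <- standardize_traits(d, gaussian_cols(category))
  for (cv in covars) {
    if (stats::sd(d[[cv]], na.rm = TRUE) > 0) {
      d[[cv]] <- as.numeric(scale(d[[cv]]))
    } else {
      d[[cv]] <- 0
    }
  }
  d
}

# Covariates actually present in the table (internal).
present_covars <- function(measures, wanted = c("n_sightings", "age")) {
  intersect(wanted, names(measures))
}

#' Repeatability models (one per sex and sex-category)
#'
#' Fits four multivariate `idh` models (females x opposite-sex, females x
#' same-sex, males x opposite-sex, males x same-sex), each over social
#' tendency, degree, mean HWI and conspecific density of that category.
#' Degree is Poisson(log); the other three are Gaussian, centred and scaled.
#' Outputs latent-scale repeatability for every trait and observed-scale
#' repeatability for degree.
#'
#' @param measures Yearly social measures (already filtered to the sighting
#'   threshold).
#' @param sexes,categories Subsets to run (defaults: both sexes, both
#'   categories).
#' @param iterations,burn_in,thinning,seed MCMC settings.
#' @param min_ess,max_lag1 Convergence gates; failing models are flagged in
#'   the output, not dropped.
#' @param parameter_expansion Use parameter-expanded priors.
#' @return List: `table` (repeatability tibble with a `converged` flag),
#'   `chains` (named list), `convergence` (named list of gate tables).
#' @export
run_repeatability <- function(measures, sexes = c("F", "M"),
                              categories = c("os", "ss"),
                              iterations = 10000, burn_in = 2000,
                              thinning = 5, seed = 1L,
                              min_ess = 1000, max_lag1 = 0.1,
                              parameter_expansion = FALSE) {
  covars <- present_covars(measures)
  chains <- list(); conv <- list(); tabs <- list()
  for (sx in sexes) {
    for (cat in categories) {
      d <- prep_model_frame(measures, sx, cat, covars)
      traits <- list(
        trait_spec(paste0("tendency_", cat), "gaussian", fixed_effects = covars),
        trait_spec(paste0("degree_", cat), "poisson_log", fixed_effects = covars),
        trait_spec(paste0("hwi_", cat), "gaussian", fixed_effects = covars),
        trait_spec(paste0("density_", cat), "gaussian", fixed_effects = covars))
      sp <- model_spec(traits, "idh", iterations = iterations,
                       burn_in = burn_in, thinning = thinning,
                       parameter_expansion = parameter_expansion,
                       seed = seed + 13L * match(sx, c("F", "M")) +
                         101L * match(cat, c("os", "ss")))
      ch <- fit_mvmm(build_design(d, sp))
      key <- paste(sx, cat, sep = "_")
      chains[[key]] <- ch
      cv <- check_convergence(ch, min_ess = min_ess, max_lag1 = max_lag1)
      conv[[key]] <- cv
      tb <- repeatability_table(ch, sex = sx)
      tb$category <- cat
      tb$converged <- attr(cv, "converged")
      tabs[[key]] <- tb
    }
  }
  list(table = dplyr::bind_rows(tabs), chains = chains, convergence = conv)
}

#' Among-individual correlation models
#'
#' Per sex and category, a four-trait `corgh` model yields the six pairwise
#' among-individual correlations (within-category table); per sex and trait,
#' a bivariate `corgh` model of the trait's opposite-sex and same-sex
#' versions yields the OS-SS correlation (between-category table).
#'
#' @inheritParams run_repeatability
#' @param bivariate_iterations Iterations for the bivariate OS-SS models
#'   (the study convention runs these shorter).
#' @return List: `within` (within-category correlation tibble), `between`
#'   (OS-SS tibble), `chains`, `convergence`.
#' @export
run_correlations <- function(measures, sexes = c("F", "M"),
                             categories = c("os", "ss"),
                             iterations = 10000, burn_in = 2000,
                             thinning = 5, seed = 1L,
                             bivariate_iterations = NULL,
                             min_ess = 1000, max_lag1 = 0.1) {
  if (is.null(bivariate_iterations)) bivariate_iterations <- iterations
  covars <- present_covars(measures)
  chains <- list(); conv <- list(); within <- list(); between <- list()
  for (sx in sexes) {
    for (cat in categories) {
      d <- prep_model_frame(measures, sx, cat, covars)
      traits <- list(
        trait_spec(paste0("tendency_", cat), "gaussian", fixed_effects = covars),
        trait_spec(paste0("degree_", cat), "poisson_log", fixed_effects = covars),
        trait_spec(paste0("hwi_", cat), "gaussian", fixed_effects = covars),
        trait_spec(paste0("density_", cat), "gaussian", fixed_effects = covars))
      sp <- model_spec(traits, "corgh", iterations = iterations,
                       burn_in = burn_in, thinning = thinning,
                       seed = seed + 17L * match(sx, c("F", "M")) +
                         103L * match(cat, c("os", "ss")))
      ch <- fit_mvmm(build_design(d, sp))
      key <- paste("within", sx, cat, sep = "_")
      chains[[key]] <- ch
      cv <- check_convergence(ch, min_ess, max_lag1)
      conv[[key]] <- cv
      tb <- correlation_table(ch, sex = sx)
      tb$category <- cat
      tb$converged <- attr(cv, "converged")
      within[[key]] <- tb
    }
    # OS-SS bivariate models, one per trait
    for (trn in c("tendency", "degree", "hwi", "density")) {
      dist <- if (trn == "degree") "poisson_log" else "gaussian"
      cols <- paste0(trn, c("_os", "_ss"))
      d <- measures[measures$sex == sx, , drop = FALSE]
      d <- d[stats::complete.cases(d[, cols]), , drop = FALSE]
      if (dist == "gaussian") d <- standardize_traits(d, cols)
      for (cv_ in covars) d[[cv_]] <- if (stats::sd(d[[cv_]]) > 0)
        as.numeric(scale(d[[cv_]])) else 0
      traits <- list(trait_spec(cols[1], dist, fixed_effects = covars),
                     trait_spec(cols[2], dist, fixed_effects = covars))
      sp <- model_spec(traits, "corgh", iterations = bivariate_iterations,
                       burn_in = burn_in, thinning = thinning,
                       seed = seed + 19L * match(sx, c("F", "M")) +
                         7L * match(trn, c("tendency", "degree", "hwi", "density")))
      ch <- fit_mvmm(build_design(d, sp))
      key <- paste("between", sx, trn, sep = "_")
      chains[[key]] <- ch
      cv <- check_convergence(ch, min_ess, max_lag1)
      conv[[key]] <- cv
      tb <- correlation_table(ch, sex = sx)
      tb$trait <- trn
      tb$converged <- attr(cv, "converged")
      between[[key]] <- tb
    }
  }
  list(within = dplyr::bind_rows(within), between = dplyr::bind_rows(between),
       chains = chains, convergence = conv)
}

#' Behaviour-fitness correlation models
#'
#' Per sex and category, a five-trait `corgh` model of the four repeated
#' social traits plus the single-measure Poisson offspring count, whose
#' residual and individual variances are fixed to 1. Fixed effects:
#' sightings and age on the social traits; heterozygosity and (mean yearly)
#' social dominance on fitness, where available. Individuals maturing at or
#' after `maturity_cutoff` are excluded (their offspring could not have
#' reached adulthood within the study window).
#'
#' @inheritParams run_repeatability
#' @param maturity_cutoff Exclusion year (e.g. 2018); `NULL` disables.
#' @return List: `table` (trait-fitness correlation tibble), `chains`,
#'   `convergence`.
#' @export
run_fitness <- function(measures, sexes = c("F", "M"),
                        categories = c("os", "ss"),
                        iterations = 10000, burn_in = 2000, thinning = 5,
                        seed = 1L, maturity_cutoff = NULL,
                        min_ess = 1000, max_lag1 = 0.1) {
  if (!"offspring" %in% names(measures)) stop("measures lack 'offspring'")
  if (!is.null(maturity_cutoff) && "maturity_year" %in% names(measures)) {
    measures <- measures[is.na(measures$maturity_year) |
                           measures$maturity_year < maturity_cutoff, ,
                         drop = FALSE]
  }
  if (all(measures$offspring == 0, na.rm = TRUE)) {
    stop("degenerate fitness data: all offspring counts are zero")
  }
  covars <- present_covars(measures)
  fit_covars <- present_covars(measures, c("heterozygosity", "dominance_mean"))
  if ("dominance" %in% names(measures) &&
      !"dominance_mean" %in% names(measures)) {
    dm <- stats::aggregate(dominance ~ individual_id, measures, mean)
    names(dm)[2] <- "dominance_mean"
    measures <- dplyr::left_join(measures, dm, by = "individual_id")
    fit_covars <- union(fit_covars, "dominance_mean")
  }
  chains <- list(); conv <- list(); tabs <- list()
  for (sx in sexes) {
    for (cat in categories) {
      d <- prep_model_frame(measures, sx, cat, covars)
      for (cv_ in fit_covars) {
        d[[cv_]] <- if (stats::sd(d[[cv_]], na.rm = TRUE) > 0)
          as.numeric(scale(d[[cv_]])) else 0
      }
      traits <- list(
        trait_spec(paste0("tendency_", cat), "gaussian", fixed_effects = covars),
        trait_spec(paste0("degree_", cat), "poisson_log", fixed_effects = covars),
        trait_spec(paste0("hwi_", cat), "gaussian", fixed_effects = covars),
        trait_spec(paste0("density_", cat), "gaussian", fixed_effects = covars),
        trait_spec("offspring", "poisson_log", repeated = FALSE,
                   fixed_effects = fit_covars,
                   residual_variance_fixed = 1,
                   individual_variance_fixed = 1))
      sp <- model_spec(traits, "corgh", iterations = iterations,
                       burn_in = burn_in, thinning = thinning,
                       seed = seed + 23L * match(sx, c("F", "M")) +
                         107L * match(cat, c("os", "ss")))
      ch <- fit_mvmm(build_design(d, sp))
      key <- paste(sx, cat, sep = "_")
      chains[[key]] <- ch
      cv <- check_convergence(ch, min_ess, max_lag1)
      conv[[key]] <- cv
      social <- paste0(c("tendency_", "degree_", "hwi_", "density_"), cat)
      tb <- correlation_table(ch, sex = sx,
                              pairs = cbind(social, "offspring"))
      tb$category <- cat
      tb$converged <- attr(cv, "converged")
      tabs[[key]] <- tb
    }
  }
  list(table = dplyr::bind_rows(tabs), chains = chains, convergence = conv)
}

#' Run the full pipeline from sightings to result tables
#'
#' Orchestrates: sighting aggregation into yearly social measures, the
#' sighting-count filter, and the three analysis stages (repeatability,
#' correlations, fitness when an `offspring` covariate is supplied), writing
#' CSV/JSON outputs and a manifest into `out_dir`.
#'
#' @param sightings Sighting tibble or CSV path.
#' @param covariates Optional per-individual covariate tibble or CSV path
#'   (`individual_id`, `maturity_year`, `heterozygosity`, `offspring`).
#' @param config Configuration list (see [read_run_config()]).
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param stages Character subset of `c("repeatability", "correlations",
#'   "fitness")`.
#' @return List of stage results plus `measures` and `log`.
#' @export
run_pipeline <- function(sightings, covariates = NULL, config = list(),
                         out_dir = NULL,
                         stages = c("repeatability", "correlations")) {
  defaults <- list(association_radius = 1.85, smoothing_h = 7, cell_size = 1,
                   min_sightings_social = 30, min_sightings_hr = 25,
                   iterations = 10000, burn_in = 2000, thinning = 5,
                   seed = 1L, maturity_cutoff = NULL,
                   min_ess = 1000, max_lag1 = 0.1)
  for (nm in names(defaults)) if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.character(sightings)) sightings <- read_sightings(sightings)
  if (nrow(sightings) == 0) stop("empty sighting input")
  if (is.character(covariates)) {
    covariates <- readr::read_csv(covariates, show_col_types = FALSE)
  }
  ym <- yearly_social_measures(sightings, covariates = covariates,
                               radius = config$association_radius,
                               h = config$smoothing_h,
                               cell_size = config$cell_size,
                               min_sightings_hr = config$min_sightings_hr)
  modelled <- filter_min_sightings(ym$measures, config$min_sightings_social)
  log <- c(ym$log, attr(modelled, "filter_log"))
  res <- list(measures = modelled, dyads = ym$dyads,
              home_ranges = ym$home_ranges, log = log)
  mc <- config[c("iterations", "burn_in", "thinning", "seed")]
  if ("repeatability" %in% stages) {
    res$repeatability <- run_repeatability(
      modelled, iterations = mc$iterations, burn_in = mc$burn_in,
      thinning = mc$thinning, seed = mc$seed,
      min_ess = config$min_ess, max_lag1 = config$max_lag1)
  }
  if ("correlations" %in% stages) {
    res$correlations <- run_correlations(
      modelled, iterations = mc$iterations, burn_in = mc$burn_in,
      thinning = mc$thinning, seed = mc$seed,
      min_ess = config$min_ess, max_lag1 = config$max_lag1)
  }
  if ("fitness" %in% stages) {
    res$fitness <- run_fitness(
      modelled, iterations = mc$iterations, burn_in = mc$burn_in,
      thinning = mc$thinning, seed = mc$seed,
      maturity_cutoff = config$maturity_cutoff,
      min_ess = config$min_ess, max_lag1 = config$max_lag1)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(res$measures, file.path(out_dir, "yearly_measures.csv"))
    readr::write_csv(res$dyads, file.path(out_dir, "dyad_hwi.csv"))
    readr::write_csv(res$home_ranges, file.path(out_dir, "home_ranges.csv"))
    if (!is.null(res$repeatability)) {
      readr::write_csv(res$repeatability$table,
                       file.path(out_dir, "repeatability.csv"))
    }
    if (!is.null(res$correlations)) {
      readr::write_csv(res$correlations$within,
                       file.path(out_dir, "correlations_within.csv"))
      readr::write_csv(res$correlations$between,
                       file.path(out_dir, "correlations_os_ss.csv"))
    }
    if (!is.null(res$fitness)) {
      readr::write_csv(res$fitness$table,
                       file.path(out_dir, "fitness_correlations.csv"))
    }
    manifest <- list(seed = config$seed,
                     config = config[setdiff(names(config), "seed")],
                     r_version = as.character(getRversion()),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     log = log)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}
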