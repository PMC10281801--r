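#' Configuration for trait-level panel simulation
#'
#' Describes the generative multivariate mixed model from which yearly trait
#' panels are drawn: per-trait latent intercepts, among-individual, among-year
#' and residual variances on the latent scale, and an among-individual
#' correlation matrix linking the traits' individual effects.
#'
#' Gaussian traits return the latent value itself; `poisson_log` traits return
#' a Poisson draw with rate `exp(latent)`, mimicking count traits such as
#' degree or offspring number.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_years Number of years (>= 1).
#' @param trait_names Character vector of trait names.
#' @param distributions Per-trait distribution, `"gaussian"` or
#'   `"poisson_log"`; recycled if length 1.
#' @param mu Per-trait latent intercept (recycled).
#' @param V_I Per-trait among-individual variance, latent scale (recycled).
#' @param V_year Per-trait among-year variance (recycled).
#' @param V_R Per-trait residual (within-individual) variance (recycled).
#' @param Omega_I Among-individual correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite). Default identity.
#' @param fitness_link List with `rho_fit` (correlation(s) between the fitness
#'   latent effect and the traits' individual effects) and `base_log_rate`.
#' @param obs_per_individual_year Repeated measures within an individual-year
#'   (1 for yearly social measures).
#' @param unbalanced If `TRUE`, each individual is present in a random subset
#'   of years (at least one), emulating an unbalanced field panel.
#' @param presence_prob Per-year presence probability when `unbalanced`.
#' @param seed Integer seed; drives all randomness in the generator.
#'
#' @return An object of class `trait_sim_config`.
#' @export
trait_sim_config <- function(n_individuals = 200,
                             n_years = 4,
                             trait_names = c("tendency", "degree", "hwi", "density"),
                             distributions = "gaussian",
                             mu = 0,
                             V_I = 1,
                             V_year = 0.1,
                             V_R = 1,
                             Omega_I = NULL,
                             fitness_link = list(rho_fit = 0, base_log_rate = 0),
                             obs_per_individual_year = 1,
                             unbalanced = FALSE,
                             presence_prob = 0.7,
                             seed = 1L) {
  k <- length(trait_names)
  stopifnot(k >= 1, n_individuals >= 2, n_years >= 1,
            obs_per_individual_year >= 1)
  rec <- function(x) {
    if (length(x) == 1L) x <- rep(x, k)
    stopifnot(length(x) == k)
    x
  }
  distributions <- match.arg(rec(distributions),
                             c("gaussian", "poisson_log"), several.ok = TRUE)
  mu <- rec(mu); V_I <- rec(V_I); V_year <- rec(V_year); V_R <- rec(V_R)
  if (any(c(V_I, V_year, V_R) < 0)) {
    stop("variances must be non-negative")
  }
  if (is.null(Omega_I)) Omega_I <- diag(k)
  Omega_I <- as.matrix(Omega_I)
  check_corr_matrix(Omega_I, k, "Omega_I")
  names(mu) <- names(V_I) <- names(V_year) <- names(V_R) <-
    names(distributions) <- trait_names
  dimnames(Omega_I) <- list(trait_names, trait_names)
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_years = as.integer(n_years),
         trait_names = trait_names,
         distributions = distributions,
         mu = mu, V_I = V_I, V_year = V_year, V_R = V_R,
         Omega_I = Omega_I,
         fitness_link = fitness_link,
         obs_per_individual_year = as.integer(obs_per_individual_year),
         unbalanced = isTRUE(unbalanced),
         presence_prob = presence_prob,
         seed = as.integer(seed)),
    class = "trait_sim_config"
  )
}

check_corr_matrix <- function(m, k, name) {
  if (!is.matrix(m) || nrow(m) != k || ncol(m) != k) {
    stop(name, " must be a ", k, "x", k, " matrix")
  }
  if (max(abs(m - t(m))) > 1e-8) stop(name, " must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop(name, " must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(name, " is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  }
  invisible(TRUE)
}

# Draw n x k matrix from N(0, Sigma) allowing PSD (rank-deficient) Sigma.
rmvnorm_psd <- function(n, Sigma) {
  k <- nrow(Sigma)
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(lam), k)
  matrix(stats::rnorm(n * k), n, k) %*% t(L)
}

#' Simulate a yearly trait panel from the assumed mixed model
#'
#' For each trait k, individual i, year t (and replicate r), the latent value
#' is `mu_k + a_ik + y_kt + e_ikrt`, where the individual effects `a_i.` are
#' drawn jointly across traits with correlation `Omega_I` and per-trait
#' variances `V_I`, and year and residual effects are independent Gaussians.
#' Gaussian traits return the latent value; `poisson_log` traits return a
#' Poisson draw with rate `exp(latent)`.
#'
#' @param cfg A [trait_sim_config()].
#' @return A list with `panel` (tibble: `individual_id`, `year`, one column
#'   per trait) and `truth` (list of the latent individual effects `a`
#'   (individuals x traits), year effects `y`, and the generating parameters).
#' @export
simulate_trait_panel <- function(cfg) {
  stopifnot(inherits(cfg, "trait_sim_config"))
  set.seed(cfg$seed)
  k <- length(cfg$trait_names)
  n <- cfg$n_individuals
  ny <- cfg$n_years
  nr <- cfg$obs_per_individual_year

  # a: joint across traits; scale the correlation matrix by sd outer product
  D <- sqrt(cfg$V_I)
  Sigma <- outer(D, D) * cfg$Omega_I
  a <- rmvnorm_psd(n, Sigma)
  dimnames(a) <- list(sprintf("ind%03d", seq_len(n)), cfg$trait_names)

  yeff <- sapply(seq_len(k), function(j) stats::rnorm(ny, 0, sqrt(cfg$V_year[j])))
  yeff <- matrix(yeff, ny, k, dimnames = list(NULL, cfg$trait_names))

  present <- matrix(TRUE, n, ny)
  if (cfg$unbalanced) {
    present <- matrix(stats::runif(n * ny) < cfg$presence_prob, n, ny)
    none <- rowSums(present) == 0L
    present[cbind(which(none), sample.int(ny, sum(none), replace = TRUE))] <- TRUE
  }

  idx <- which(present, arr.ind = TRUE)
  idx <- idx[rep(seq_len(nrow(idx)), each = nr), , drop = FALSE]
  ind <- idx[, 1]; yr <- idx[, 2]
  vals <- matrix(NA_real_, nrow(idx), k, dimnames = list(NULL, cfg$trait_names))
  for (j in seq_len(k)) {
    latent <- cfg$mu[j] + a[ind, j] + yeff[yr, j] +
      stats::rnorm(nrow(idx), 0, sqrt(cfg$V_R[j]))
    vals[, j] <- if (cfg$distributions[j] == "gaussian") latent
                 else stats::rpois(nrow(idx), exp(latent))
  }
  panel <- tibble::tibble(
    individual_id = rownames(a)[ind],
    year = 2000L + as.integer(yr)
  )
  panel <- dplyr::bind_cols(panel, tibble::as_tibble(vals))
  panel <- dplyr::arrange(panel, .data$individual_id, .data$year)

  list(panel = panel,
       truth = list(a = a, year_effects = yeff, config = cfg))
}

#' Simulate a single-measure Poisson fitness trait linked to sociality
#'
#' Each individual receives one Poisson offspring count with log-rate
#' `base_log_rate + b_i`, where the fitness latent effect `b_i` has unit
#' variance and the requested correlation(s) with the (standardized) latent
#' individual effects of the simulated traits. With a single `rho_fit`, the
#' link targets the first trait only.
#'
#' @param truth The `truth` component returned by [simulate_trait_panel()].
#' @param rho_fit Correlation(s) in `[-1, 1]`; either a scalar (first trait)
#'   or one value per trait. Must be jointly feasible given `Omega_I`.
#' @param base_log_rate Baseline log expected offspring count.
#' @param seed Integer seed.
#' @return Tibble `individual_id`, `offspring`, `b` (the latent fitness
#'   effect, kept for validation).
#' @export
simulate_fitness <- function(truth, rho_fit = 0.5, base_log_rate = 0,
                             seed = 1L) {
  cfg <- truth$config
  k <- length(cfg$trait_names)
  if (length(rho_fit) == 1L && k > 1L) rho_fit <- c(rho_fit, rep(0, k - 1L))
  stopifnot(length(rho_fit) == k)
  if (any(abs(rho_fit) > 1)) stop("|rho_fit| must be <= 1")
  set.seed(seed)

  # standardized individual effects (unit variance, correlation Omega_I)
  sdv <- sqrt(cfg$V_I)
  usable <- sdv > 0
  a_std <- truth$a
  a_std[, usable] <- sweep(truth$a[, usable, drop = FALSE], 2, sdv[usable], "/")
  a_std[, !usable] <- 0
  rho <- rho_fit
  rho[!usable] <- 0

  # b = a_std %*% w + resid with Var(b) = 1 and Cor(b, a_std_k) = rho_k:
  # solves Omega w = rho; feasible iff rho' Omega^{-1} rho <= 1.
  Om <- cfg$Omega_I
  w <- solve(Om, rho)
  s2 <- 1 - sum(w * rho)
  if (s2 < -1e-8) stop("rho_fit is jointly infeasible given Omega_I")
  b <- as.numeric(a_std %*% w) + stats::rnorm(cfg$n_individuals) * sqrt(max(s2, 0))
  offspring <- stats::rpois(cfg$n_individuals, exp(base_log_rate + b))
  tibble::tibble(individual_id = rownames(truth$a),
                 offspring = offspring, b = b)
}
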