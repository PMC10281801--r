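# Independent oracles used across tests.

# One-way ANOVA intraclass correlation on a balanced panel: the classical
# moment estimator of among-individual variance and repeatability,
# independent of the MCMC machinery.
anova_repeatability <- function(panel, trait, n_per_group) {
  f <- factor(panel$individual_id)
  a <- stats::anova(stats::lm(panel[[trait]] ~ f))
  msa <- a$`Mean Sq`[1]
  msw <- a$`Mean Sq`[2]
  v_i <- (msa - msw) / n_per_group
  list(V_I = v_i, V_W = msw, R = v_i / (v_i + msw))
}

# Monte-Carlo variance decomposition of a log-link Poisson trait on the
# observed scale: many individuals x many observations, among-individual
# variance of the data-scale values estimated by one-way ANOVA moments.
mc_observed_R <- function(mu, V_I, V_R, n_ind = 1e5, n_obs = 100, seed = 1) {
  set.seed(seed)
  a <- stats::rnorm(n_ind, 0, sqrt(V_I))
  e <- matrix(stats::rnorm(n_ind * n_obs, 0, sqrt(V_R)), n_obs, n_ind)
  lam <- exp(sweep(e, 2, mu + a, "+"))
  y <- matrix(stats::rpois(n_ind * n_obs, lam), n_obs, n_ind)
  gm <- colMeans(y)
  ssw <- colSums(y^2) - n_obs * gm^2
  msw <- sum(ssw) / (n_ind * (n_obs - 1))
  msa <- n_obs * stats::var(gm)
  v_among <- (msa - msw) / n_obs
  v_among / (v_among + msw)
}

# A core home range whose membership covers an entire rectangle: uniform
# utilization grid, full-mass contour. Used to study association logic in
# isolation from home-range estimation.
open_core_range <- function(xlim = c(-60, 60), ylim = c(-60, 60),
                            cell_size = 2) {
  xs <- seq(xlim[1] + cell_size / 2, xlim[2], by = cell_size)
  ys <- seq(ylim[1] + cell_size / 2, ylim[2], by = cell_size)
  vals <- matrix(1, length(xs), length(ys))
  vals <- vals / (sum(vals) * cell_size^2)
  grid <- structure(list(xs = xs, ys = ys, values = vals,
                         cell_size = cell_size),
                    class = "utilization_grid")
  core_contour(grid, level = 1.0)
}

# Hand-built five-individual, eight-survey sighting fixture with known
# association counts (see test-social-metrics.R for the hand counts).
toy_sightings <- function() {
  rows <- list()
  add <- function(id, sex, survey, x, y) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      individual_id = id, sex = sex, year = 2014L,
      survey_id = sprintf("S%d", survey), x_m = x, y_m = y,
      behaviour = "rest")
  }
  for (s in 1:4) { add("A", "F", s, 0, 0); add("B", "M", s, 1, 0) }
  add("A", "F", 5, 0, 0); add("C", "M", 5, 0, 1)
  add("A", "F", 6, 0, 0)
  for (s in 7:8) { add("B", "M", s, 10, 10); add("D", "F", s, 11, 10) }
  for (s in 1:8) add("E", "F", s, 50, 50)
  dplyr::bind_rows(rows)
}

toy_ranges <- function() {
  hr <- open_core_range()
  ids <- c("A", "B", "C", "D", "E")
  stats::setNames(rep(list(hr), length(ids)), paste(ids, 2014L, sep = "."))
}

# Fast default MCMC settings for desk-scale tests.
test_mcmc <- list(iterations = 3000, burn_in = 1000, thinning = 2)

# Panel-level fixture: yearly measures drawn straight from the generative
# model (sighting aggregation is exercised elsewhere); one sex, same-sex
# category, known truth.
panel_measures <- function(n_ind = 60, seed = 21, rho = NULL, sex = "M") {
  tn <- c("tendency_ss", "degree_ss", "hwi_ss", "density_ss")
  Om <- diag(4)
  if (!is.null(rho)) { Om[1, 2] <- Om[2, 1] <- rho }
  cfg <- trait_sim_config(
    n_individuals = n_ind, n_years = 4, trait_names = tn,
    distributions = c("gaussian", "poisson_log", "gaussian", "gaussian"),
    mu = c(0, 1, 0, 0), V_I = c(0.4, 0.3, 0.4, 0.4),
    V_year = 0.05, V_R = c(0.6, 0.2, 0.6, 0.6), Omega_I = Om, seed = seed)
  sim <- simulate_trait_panel(cfg)
  m <- sim$panel
  m$sex <- sex
  m$n_sightings <- 35L
  list(measures = m, truth = sim$truth)
}
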