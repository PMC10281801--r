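test_that("trait panel matches its generating variance components (ANOVA oracle)", {
  cfg <- trait_sim_config(n_individuals = 2000, n_years = 4,
                          trait_names = "t1", V_I = 1, V_year = 0, V_R = 1,
                          seed = 42)
  sim <- simulate_trait_panel(cfg)
  or <- anova_repeatability(sim$panel, "t1", 4)
  expect_lt(abs(or$R - 0.5), 0.03)

  # no individual signal: among-individual variance of means ~ V_R / n_years
  cfg0 <- trait_sim_config(n_individuals = 2000, n_years = 4,
                           trait_names = "t1", V_I = 0, V_year = 0, V_R = 1,
                           seed = 43)
  sim0 <- simulate_trait_panel(cfg0)
  m <- tapply(sim0$panel$t1, sim0$panel$individual_id, mean)
  expect_lt(abs(stats::var(m) - 1 / 4), 0.03)
})

test_that("panel generation is deterministic under a fixed seed", {
  cfg <- trait_sim_config(n_individuals = 20, n_years = 3, seed = 7)
  expect_identical(simulate_trait_panel(cfg)$panel,
                   simulate_trait_panel(cfg)$panel)
})

test_that("among-individual correlations converge to Omega_I", {
  Om <- matrix(c(1, 0.6, 0.6, 1), 2)
  cfg <- trait_sim_config(n_individuals = 3000, n_years = 6,
                          trait_names = c("t1", "t2"), V_I = 1,
                          V_year = 0, V_R = 0.3, Omega_I = Om, seed = 5)
  sim <- simulate_trait_panel(cfg)
  expect_lt(abs(stats::cor(sim$truth$a)[1, 2] - 0.6), 0.05)
  # individual-mean traits inherit the correlation (attenuated by residual)
  mm <- stats::aggregate(cbind(t1, t2) ~ individual_id, sim$panel, mean)
  expect_gt(stats::cor(mm$t1, mm$t2), 0.5)
})

test_that("invalid correlation matrices are rejected by name", {
  Om <- matrix(c(1, 2, 2, 1), 2)   # not PSD
  expect_error(trait_sim_config(trait_names = c("a", "b"), Omega_I = Om),
               "Omega_I")
  Om2 <- matrix(c(1, 0.2, 0.3, 1), 2)  # asymmetric
  expect_error(trait_sim_config(trait_names = c("a", "b"), Omega_I = Om2),
               "symmetric")
})

test_that("poisson_log traits produce counts with the right latent scale", {
  cfg <- trait_sim_config(n_individuals = 1000, n_years = 2,
                          trait_names = "deg", distributions = "poisson_log",
                          mu = 1, V_I = 0.2, V_year = 0, V_R = 0.1, seed = 9)
  sim <- simulate_trait_panel(cfg)
  expect_true(all(sim$panel$deg >= 0), all(sim$panel$deg == round(sim$panel$deg)))
  # E[y] = exp(mu + (V_I + V_R)/2)
  expect_lt(abs(mean(sim$panel$deg) - exp(1 + 0.15)), 0.15)
})

test_that("unbalanced panels keep every individual at least once", {
  cfg <- trait_sim_config(n_individuals = 100, n_years = 4, unbalanced = TRUE,
                          presence_prob = 0.5, seed = 3)
  sim <- simulate_trait_panel(cfg)
  counts <- table(sim$panel$individual_id)
  expect_equal(length(counts), 100)
  expect_true(all(counts >= 1))
  expect_lt(mean(counts), 4)
})

test_that("fitness link hits the requested latent correlation", {
  cfg <- trait_sim_config(n_individuals = 5000, n_years = 1,
                          trait_names = "t1", V_I = 1, V_year = 0, V_R = 1,
                          seed = 13)
  sim <- simulate_trait_panel(cfg)
  f5 <- simulate_fitness(sim$truth, rho_fit = 0.5, base_log_rate = 0, seed = 2)
  expect_lt(abs(stats::cor(sim$truth$a[, 1], f5$b) - 0.5), 0.03)
  f0 <- simulate_fitness(sim$truth, rho_fit = 0, base_log_rate = 0, seed = 2)
  expect_lt(abs(stats::cor(sim$truth$a[, 1], f0$b)), 0.05)
  # rate -> 0 gives all-zero counts
  fz <- simulate_fitness(sim$truth, rho_fit = 0.2, base_log_rate = -10, seed = 2)
  expect_true(mean(fz$offspring == 0) > 0.999)
  expect_error(simulate_fitness(sim$truth, rho_fit = 1.2), "rho_fit")
})
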