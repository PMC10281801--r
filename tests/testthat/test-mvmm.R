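test_that("design building handles unbalanced layouts and rejects bad input", {
  m <- tibble::tibble(individual_id = c("a", "a", "b", "b", "c"),
                      year = c(1, 2, 1, 2, 1),
                      t1 = c(1, 2, 3, NA, 5), cov = c(1, 2, 3, 4, NA))
  sp <- model_spec(list(trait_spec("t1", "gaussian", fixed_effects = "cov")),
                   "idh")
  d <- build_design(m, sp)
  expect_equal(length(d$traits$t1$y), 3)          # two incomplete rows dropped
  expect_match(paste(d$log, collapse = " "), "dropped 2")
  expect_equal(d$n_ind, 2)   # individual c lost its only complete row
  expect_error(build_design(m[1:2, ], sp), "fewer than 2")
  expect_error(build_design(m[, -3], sp), "lack column")
  # a single-measure trait collapses to one row per individual
  m$fit <- 1
  spf <- model_spec(list(
    trait_spec("t1", "gaussian"),
    trait_spec("fit", "poisson_log", repeated = FALSE,
               residual_variance_fixed = 1, individual_variance_fixed = 1)),
    "corgh")
  df <- build_design(m, spf)
  expect_equal(length(df$traits$fit$y), 3)
})

test_that("single-measure traits must fix both variances", {
  expect_error(trait_spec("w", "poisson_log", repeated = FALSE),
               "must fix")
})

test_that("gaussian variance components are recovered and match the ANOVA oracle", {
  cfg <- trait_sim_config(n_individuals = 150, n_years = 4, trait_names = "t1",
                          V_I = 1, V_year = 0.05, V_R = 1, seed = 11)
  sim <- simulate_trait_panel(cfg)
  sp <- model_spec(list(trait_spec("t1", "gaussian")), "idh",
                   iterations = test_mcmc$iterations,
                   burn_in = test_mcmc$burn_in,
                   thinning = test_mcmc$thinning, seed = 1)
  ch <- fit_mvmm(build_design(sim$panel, sp))
  R_post <- mean(repeatability_latent(chain_draws(ch, "V_I[t1]"),
                                      chain_draws(ch, "V_R[t1]")))
  or <- anova_repeatability(sim$panel, "t1", 4)
  expect_lt(abs(R_post - or$R), 0.06)
  # fixed seed reproducibility of the sampler
  ch2 <- fit_mvmm(build_design(sim$panel, sp))
  expect_equal(as.numeric(ch$samples), as.numeric(ch2$samples))
})

test_that("a signal-free trait concentrates repeatability near zero", {
  cfg <- trait_sim_config(n_individuals = 150, n_years = 4, trait_names = "t1",
                          V_I = 0, V_year = 0.05, V_R = 1, seed = 12)
  sim <- simulate_trait_panel(cfg)
  sp <- model_spec(list(trait_spec("t1", "gaussian")), "idh",
                   iterations = test_mcmc$iterations,
                   burn_in = test_mcmc$burn_in,
                   thinning = test_mcmc$thinning, seed = 2)
  ch <- fit_mvmm(build_design(sim$panel, sp))
  R_post <- repeatability_latent(chain_draws(ch, "V_I[t1]"),
                                 chain_draws(ch, "V_R[t1]"))
  expect_lt(mean(R_post), 0.1)
})

test_that("parameter expansion leaves posterior mean variances unchanged", {
  cfg <- trait_sim_config(n_individuals = 120, n_years = 4, trait_names = "t1",
                          V_I = 0.4, V_year = 0.05, V_R = 0.6, seed = 14)
  sim <- simulate_trait_panel(cfg)
  vi <- sapply(c(FALSE, TRUE), function(px) {
    sp <- model_spec(list(trait_spec("t1", "gaussian")), "idh",
                     parameter_expansion = px,
                     iterations = 4000, burn_in = 1500, thinning = 2, seed = 3)
    mean(chain_draws(fit_mvmm(build_design(sim$panel, sp)), "V_I[t1]"))
  })
  expect_lt(abs(vi[1] - vi[2]), 0.05)
})

test_that("poisson traits recover latent variance components", {
  cfg <- trait_sim_config(n_individuals = 120, n_years = 4, trait_names = "deg",
                          distributions = "poisson_log", mu = 1, V_I = 0.3,
                          V_year = 0.02, V_R = 0.2, seed = 15)
  sim <- simulate_trait_panel(cfg)
  sp <- model_spec(list(trait_spec("deg", "poisson_log")), "idh",
                   iterations = 4000, burn_in = 1500, thinning = 3, seed = 4)
  ch <- fit_mvmm(build_design(sim$panel, sp))
  expect_lt(abs(mean(chain_draws(ch, "V_I[deg]")) - 0.3), 0.12)
  expect_true(all(chain_draws(ch, "V_I[deg]") > 0))
})

test_that("corgh draws stay in [-1,1] and fix unit variances", {
  Om <- matrix(c(1, 0.5, 0.5, 1), 2)
  cfg <- trait_sim_config(n_individuals = 100, n_years = 4,
                          trait_names = c("t1", "t2"), V_I = 1, V_year = 0.05,
                          V_R = 1, Omega_I = Om, seed = 16)
  sim <- simulate_trait_panel(cfg)
  sp <- model_spec(list(trait_spec("t1", "gaussian"),
                        trait_spec("t2", "gaussian")), "corgh",
                   iterations = test_mcmc$iterations,
                   burn_in = test_mcmc$burn_in,
                   thinning = test_mcmc$thinning, seed = 5)
  ch <- fit_mvmm(build_design(sim$panel, sp))
  r <- chain_draws(ch, "r_I[t1,t2]")
  expect_true(all(r >= -1 & r <= 1))
  expect_true(all(chain_draws(ch, "V_I[t1]") == 1))
  expect_gt(mean(r), 0.2)   # truth 0.5; direction and rough size recovered
})

test_that("individual effects track the simulated truth under strong signal", {
  cfg <- trait_sim_config(n_individuals = 60, n_years = 6, trait_names = "t1",
                          V_I = 1, V_year = 0.02, V_R = 0.3, seed = 17)
  sim <- simulate_trait_panel(cfg)
  sp <- model_spec(list(trait_spec("t1", "gaussian")), "idh",
                   iterations = 2000, burn_in = 800, thinning = 2, seed = 6)
  ch <- fit_mvmm(build_design(sim$panel, sp), monitor_individual = TRUE)
  eff <- extract_individual_effects(ch)
  eff <- eff[order(eff$individual_id), ]
  truth <- sim$truth$a[order(rownames(sim$truth$a)), 1]
  expect_gt(stats::cor(eff$post_mean, truth, method = "spearman"), 0.8)
  expect_true(all(eff$upper > eff$lower))       # uncertainty retained
  # shrinkage: effects are pulled inside the raw mean deviations
  devs <- tapply(sim$panel$t1, sim$panel$individual_id, mean) -
    mean(sim$panel$t1)
  expect_lt(max(abs(eff$post_mean)), max(abs(devs)))
})

test_that("convergence gates use ESS and lag-1 autocorrelation", {
  cfg <- trait_sim_config(n_individuals = 60, n_years = 4, trait_names = "t1",
                          V_I = 0.5, V_year = 0.02, V_R = 0.5, seed = 18)
  sim <- simulate_trait_panel(cfg)
  sp <- model_spec(list(trait_spec("t1", "gaussian")), "idh",
                   iterations = 1500, burn_in = 500, thinning = 1, seed = 7)
  ch <- fit_mvmm(build_design(sim$panel, sp))
  gates <- check_convergence(ch, min_ess = 10, max_lag1 = 0.99)
  expect_true(attr(gates, "converged"))
  strict <- check_convergence(ch, min_ess = 1e6, max_lag1 = 0.001)
  expect_false(attr(strict, "converged"))
  # constant chains are flagged as undiagnosable, not passed
  expect_true(is.na(effective_sample_size(rep(1, 100))))
  expect_true(is.na(lag_autocorrelation(rep(1, 100))))
})

test_that("effective sample size matches iid and AR(1) oracles", {
  set.seed(9)
  x <- stats::rnorm(4000)
  expect_lt(abs(effective_sample_size(x) / 4000 - 1), 0.15)
  phi <- 0.9; n <- 20000
  ar <- as.numeric(stats::arima.sim(list(ar = phi), n))
  expect_lt(abs(effective_sample_size(ar) / (n * (1 - phi) / (1 + phi)) - 1),
            0.15)
  expect_lt(abs(lag_autocorrelation(ar) - phi), 0.05)
})
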