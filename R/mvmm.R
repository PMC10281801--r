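#' Declare one response trait of a multivariate mixed model
#'
#' @param name Column name of the response in the measures table.
#' @param distribution `"gaussian"` or `"poisson_log"` (log link with an
#'   observation-level latent residual, i.e. log-normal overdispersion).
#' @param repeated Is the trait measured repeatedly (gets a year random
#'   effect)? Single-measure traits (e.g. lifetime offspring count) must fix
#'   both their residual and individual variances.
#' @param fixed_effects Character vector of covariate columns (an intercept
#'   is always included, per trait).
#' @param residual_variance_fixed Optional fixed residual variance.
#' @param individual_variance_fixed Optional fixed among-individual variance.
#' @return Object of class `trait_spec`.
#' @export
trait_spec <- function(name, distribution = c("gaussian", "poisson_log"),
                       repeated = TRUE, fixed_effects = character(),
                       residual_variance_fixed = NULL,
                       individual_variance_fixed = NULL) {
  distribution <- match.arg(distribution)
  if (!repeated && (is.null(residual_variance_fixed) ||
                    is.null(individual_variance_fixed))) {
    stop("single-measure trait '", name,
         "' must fix both residual and individual variances")
  }
  structure(list(name = name, distribution = distribution,
                 repeated = isTRUE(repeated), fixed_effects = fixed_effects,
                 residual_variance_fixed = residual_variance_fixed,
                 individual_variance_fixed = individual_variance_fixed),
            class = "trait_spec")
}

#' Declare a multivariate mixed model
#'
#' Individual random effects take either an `idh` structure (heterogeneous
#' per-trait variances, zero covariances) or a `corgh` structure (variances
#' fixed to 1, free correlation matrix — used to estimate among-individual
#' correlations directly). Year effects are always `idh` over the repeated
#' traits. Variance priors are scaled-inverse-chi-square with scale `V = 1`
#' and degree-of-belief `nu` (weakly informative defaults `nu = 0.002` for
#' random effects, `0.02` for residuals); `corgh` correlation matrices get a
#' rescaled inverse-Wishart prior with near-uniform marginal correlations.
#'
#' @param traits List of [trait_spec()] objects.
#' @param individual_struct `"idh"` or `"corgh"`.
#' @param nu_random,nu_residual Prior degrees of belief.
#' @param parameter_expansion Use the multiplicative redundant
#'   parametrization for free `idh` variances (prior-robustness check).
#' @param iterations,burn_in,thinning,seed MCMC settings (post-burn-in
#'   iterations, burn-in length, thinning interval, RNG seed).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(traits, individual_struct = c("idh", "corgh"),
                       nu_random = 0.002, nu_residual = 0.02,
                       parameter_expansion = FALSE,
                       iterations = 10000, burn_in = 2000, thinning = 5,
                       seed = 1L) {
  individual_struct <- match.arg(individual_struct)
  stopifnot(length(traits) >= 1,
            all(vapply(traits, inherits, logical(1), "trait_spec")))
  nm <- vapply(traits, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate trait names")
  if (individual_struct == "corgh") {
    if (length(traits) < 2) stop("corgh needs at least two traits")
    # corgh estimates only correlations; variances are fixed to 1
    traits <- lapply(traits, function(tr) {
      tr$individual_variance_fixed <- 1; tr
    })
  }
  structure(list(traits = traits, trait_names = nm,
                 individual_struct = individual_struct,
                 nu_random = nu_random, nu_residual = nu_residual,
                 parameter_expansion = isTRUE(parameter_expansion),
                 mcmc = list(iterations = as.integer(iterations),
                             burn_in = as.integer(burn_in),
                             thinning = as.integer(thinning),
                             seed = as.integer(seed))),
            class = "model_spec")
}

#' Build the internal design of a multivariate mixed model
#'
#' Assembles, per trait, the response vector, covariate matrix (per-trait
#' intercept plus declared fixed effects) and individual/year index maps.
#' Traits may have different row sets (unbalanced multivariate layout); rows
#' with missing response or covariates are dropped from that trait's
#' likelihood only and logged.
#'
#' @param measures Data frame of yearly measures (one row per
#'   individual-year) and, for single-measure traits, one row per individual
#'   (its `year` is ignored).
#' @param spec A [model_spec()].
#' @param individual_col,year_col Key columns.
#' @return Object of class `mvmm_design`.
#' @export
build_design <- function(measures, spec, individual_col = "individual_id",
                         year_col = "year") {
  stopifnot(inherits(spec, "model_spec"))
  log <- character()
  tr_data <- list()
  for (tr in spec$traits) {
    cols <- c(tr$name, tr$fixed_effects, individual_col,
              if (tr$repeated) year_col)
    miss <- setdiff(cols, names(measures))
    if (length(miss)) stop("measures lack column(s): ", paste(miss, collapse = ", "))
    sub <- measures[, cols, drop = FALSE]
    ok <- stats::complete.cases(sub)
    if (any(!ok)) log <- c(log, sprintf(
      "trait %s: dropped %d incomplete row(s)", tr$name, sum(!ok)))
    sub <- sub[ok, , drop = FALSE]
    if (!tr$repeated) {
      # one row per individual
      sub <- sub[!duplicated(sub[[individual_col]]), , drop = FALSE]
    }
    if (length(unique(sub[[individual_col]])) < 2) {
      stop("trait ", tr$name, " has fewer than 2 individuals")
    }
    X <- matrix(1, nrow(sub), 1, dimnames = list(NULL, "(Intercept)"))
    if (length(tr$fixed_effects)) {
      X <- cbind(X, as.matrix(sub[, tr$fixed_effects, drop = FALSE]))
    }
    tr_data[[tr$name]] <- list(spec = tr, y = sub[[tr$name]], X = X,
                               ind_id = as.character(sub[[individual_col]]),
                               year = if (tr$repeated) sub[[year_col]] else NULL)
  }
  ind_levels <- sort(unique(unlist(lapply(tr_data, `[[`, "ind_id"))))
  year_levels <- sort(unique(unlist(lapply(tr_data, `[[`, "year"))))
  for (k in seq_along(tr_data)) {
    tr_data[[k]]$ind <- match(tr_data[[k]]$ind_id, ind_levels)
    if (!is.null(tr_data[[k]]$year)) {
      tr_data[[k]]$yr <- match(tr_data[[k]]$year, year_levels)
    }
  }
  structure(list(traits = tr_data, ind_levels = ind_levels,
                 year_levels = year_levels, n_ind = length(ind_levels),
                 n_year = length(year_levels), log = log,
                 spec = spec),
            class = "mvmm_design")
}

# Assemble the JAGS model string for a design (internal).
jags_model_string <- function(design) {
  spec <- design$spec
  K <- length(spec$traits)
  px <- spec$parameter_expansion
  lines <- c("model {")
  add <- function(...) lines <<- c(lines, sprintf(...))

  for (k in seq_len(K)) {
    tr <- spec$traits[[k]]
    yrterm <- if (tr$repeated) sprintf(" + yrA[yr%d[j], %d]", k, k) else ""
    if (tr$distribution == "gaussian") {
      add("  for (j in 1:N%d) {", k)
      add("    mu%d[j] <- inprod(X%d[j,], beta%d[]) + a[ind%d[j], %d]%s",
          k, k, k, k, k, yrterm)
      add("    y%d[j] ~ dnorm(mu%d[j], tauR[%d])", k, k, k)
      add("  }")
    } else {
      add("  for (j in 1:N%d) {", k)
      add("    mu%d[j] <- inprod(X%d[j,], beta%d[]) + a[ind%d[j], %d]%s + e%d[j]",
          k, k, k, k, k, yrterm, k)
      add("    e%d[j] ~ dnorm(0, tauR[%d])", k, k)
      add("    y%d[j] ~ dpois(exp(mu%d[j]))", k, k)
      add("  }")
    }
    add("  for (p in 1:P%d) { beta%d[p] ~ dnorm(0, 1.0E-8) }", k, k)
    # residual variance
    if (is.null(tr$residual_variance_fixed)) {
      add("  tauR[%d] ~ dgamma(%g, %g)", k, spec$nu_residual / 2,
          spec$nu_residual / 2)
    } else {
      add("  tauR[%d] <- %.10g", k, 1 / tr$residual_variance_fixed)
    }
    add("  VR[%d] <- 1 / tauR[%d]", k, k)
    # year variance (repeated traits only)
    if (tr$repeated) {
      add("  for (t in 1:NY) { yrA[t, %d] ~ dnorm(0, tauY[%d]) }", k, k)
      add("  tauY[%d] ~ dgamma(%g, %g)", k, spec$nu_random / 2,
          spec$nu_random / 2)
      add("  VY[%d] <- 1 / tauY[%d]", k, k)
    }
  }

  if (spec$individual_struct == "idh") {
    for (k in seq_len(K)) {
      tr <- spec$traits[[k]]
      if (!is.null(tr$individual_variance_fixed)) {
        add("  for (i in 1:NI) { a[i, %d] ~ dnorm(0, %.10g) }",
            k, 1 / tr$individual_variance_fixed)
        add("  VI[%d] <- %.10g", k, tr$individual_variance_fixed)
      } else if (px) {
        add("  for (i in 1:NI) { u[i, %d] ~ dnorm(0, tauU[%d])", k, k)
        add("                    a[i, %d] <- xi[%d] * u[i, %d] }", k, k, k)
        add("  xi[%d] ~ dnorm(0, 1.0E-3)", k)
        add("  tauU[%d] ~ dgamma(%g, %g)", k, spec$nu_random / 2,
            spec$nu_random / 2)
        add("  VI[%d] <- xi[%d] * xi[%d] / tauU[%d]", k, k, k, k)
      } else {
        add("  for (i in 1:NI) { a[i, %d] ~ dnorm(0, tauI[%d]) }", k, k)
        add("  tauI[%d] ~ dgamma(%g, %g)", k, spec$nu_random / 2,
            spec$nu_random / 2)
        add("  VI[%d] <- 1 / tauI[%d]", k, k)
      }
    }
  } else {
    # corgh: unit variances, free correlations. The correlation matrix is
    # parametrized by its unit-row Cholesky factor L: each subdiagonal slot
    # carries a free coefficient in (-1, 1) scaled so every row of L has
    # unit norm, which yields a valid correlation matrix Omega = L L' for
    # any draw (for two traits the correlation prior is exactly uniform).
    # Individual effects are a[i, ] = L z[i, ] with standard normal z, so
    # marginal variances are 1 by construction and only correlations are
    # estimated.
    ncc <- K * (K - 1) / 2
    add("  for (q in 1:%d) { cc[q] ~ dunif(-1, 1) }", ncc)
    add("  L[1, 1] <- 1")
    q <- 0
    for (r in 2:K) {
      q <- q + 1
      add("  L[%d, 1] <- cc[%d]", r, q)
      add("  ssq%d_1 <- L[%d, 1] * L[%d, 1]", r, r, r)
      if (r > 2) for (cl in 2:(r - 1)) {
        q <- q + 1
        add("  L[%d, %d] <- cc[%d] * sqrt(1 - ssq%d_%d)", r, cl, q, r, cl - 1)
        add("  ssq%d_%d <- ssq%d_%d + L[%d, %d] * L[%d, %d]",
            r, cl, r, cl - 1, r, cl, r, cl)
      }
      add("  L[%d, %d] <- sqrt(1 - ssq%d_%d)", r, r, r, r - 1)
    }
    for (r in seq_len(K)) for (cl in seq_len(K)) {
      if (cl > r) add("  L[%d, %d] <- 0", r, cl)
      m <- min(r, cl)
      add("  Omega[%d, %d] <- inprod(L[%d, 1:%d], L[%d, 1:%d])",
          r, cl, r, m, cl, m)
    }
    add("  for (i in 1:NI) {")
    add("    for (k in 1:K) { z[i, k] ~ dnorm(0, 1) }")
    for (k in seq_len(K)) {
      add("    a[i, %d] <- inprod(L[%d, 1:%d], z[i, 1:%d])", k, k, k, k)
    }
    add("  }")
    for (k in seq_len(K)) add("  VI[%d] <- 1", k)
  }
  c(lines, "}")
}

# JAGS data list for a design (internal).
jags_data <- function(design) {
  spec <- design$spec
  K <- length(spec$traits)
  dat <- list(NI = design$n_ind)
  if (any(vapply(spec$traits, `[[`, logical(1), "repeated"))) {
    dat$NY <- max(design$n_year, 1L)
  }
  for (k in seq_len(K)) {
    td <- design$traits[[k]]
    dat[[sprintf("N%d", k)]] <- length(td$y)
    dat[[sprintf("y%d", k)]] <- as.numeric(td$y)
    dat[[sprintf("X%d", k)]] <- td$X
    dat[[sprintf("P%d", k)]] <- ncol(td$X)
    dat[[sprintf("ind%d", k)]] <- td$ind
    if (td$spec$repeated) dat[[sprintf("yr%d", k)]] <- td$yr
  }
  if (spec$individual_struct == "corgh") dat$K <- K
  dat
}

# Initial values (internal): latent Poisson residuals at log(y + 0.5) scale,
# variances near sample variances, fixed RNG for reproducibility.
jags_inits <- function(design, seed) {
  spec <- design$spec
  inits <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed))
  for (k in seq_along(spec$traits)) {
    tr <- spec$traits[[k]]
    td <- design$traits[[k]]
    beta0 <- rep(0, ncol(td$X))
    if (tr$distribution == "gaussian") {
      beta0[1] <- mean(td$y)
    } else {
      ly <- log(td$y + 0.5)
      beta0[1] <- mean(ly)
      inits[[sprintf("e%d", k)]] <- ly - mean(ly)
    }
    inits[[sprintf("beta%d", k)]] <- beta0
  }
  # free residual precisions start at 1 / pooled variance
  tauR <- rep(NA_real_, length(spec$traits))
  anyfree <- FALSE
  for (k in seq_along(spec$traits)) {
    tr <- spec$traits[[k]]
    if (is.null(tr$residual_variance_fixed)) {
      anyfree <- TRUE
      v <- if (tr$distribution == "gaussian") stats::var(design$traits[[k]]$y) else 1
      if (!is.finite(v) || v <= 0) v <- 1
      tauR[k] <- 1 / v
    }
  }
  if (anyfree) inits$tauR <- tauR
  if (spec$individual_struct == "corgh") {
    K <- length(spec$traits)
    inits$cc <- rep(0, K * (K - 1) / 2)   # start at Omega = identity
  }
  inits
}

#' Fit a multivariate mixed model by MCMC
#'
#' Samples the declared model with a Gibbs/slice sampler (JAGS backend):
#' Gaussian traits enter the likelihood directly; Poisson traits through a
#' latent log-rate with an observation-level Gaussian residual. Returns
#' thinned posterior draws of variance components, correlation matrices
#' (`corgh`), fixed effects, and optionally the per-individual effects.
#'
#' @param design An [build_design()] object.
#' @param monitor_individual Also monitor the individual random effects
#'   (needed by [extract_individual_effects()]).
#' @param quiet Suppress sampler progress output.
#' @return Object of class `mvmm_chain`: `samples` (a `coda::mcmc` matrix
#'   with descriptive parameter names), `spec`, `ind_levels`, `mcmc`
#'   settings.
#' @export
fit_mvmm <- function(design, monitor_individual = FALSE, quiet = TRUE) {
  stopifnot(inherits(design, "mvmm_design"))
  spec <- design$spec
  K <- length(spec$traits)
  model_txt <- paste(jags_model_string(design), collapse = "\n")
  monitors <- character()
  for (k in seq_len(K)) {
    tr <- spec$traits[[k]]
    monitors <- c(monitors, sprintf("beta%d", k))
  }
  free_vi <- spec$individual_struct == "idh" &&
    any(vapply(spec$traits, function(t) is.null(t$individual_variance_fixed),
               logical(1)))
  monitors <- c(monitors, "VR",
                if (any(vapply(spec$traits, `[[`, logical(1), "repeated"))) "VY",
                "VI",
                if (spec$individual_struct == "corgh") "Omega",
                if (monitor_individual) "a")
  jm <- rjags::jags.model(textConnection(model_txt), data = jags_data(design),
                          inits = jags_inits(design, spec$mcmc$seed),
                          n.chains = 1, n.adapt = min(1000, spec$mcmc$burn_in),
                          quiet = quiet)
  if (spec$mcmc$burn_in > 0) update(jm, spec$mcmc$burn_in,
                                    progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = unique(monitors),
                              n.iter = spec$mcmc$iterations,
                              thin = spec$mcmc$thinning,
                              progress.bar = "none")[[1]]
  colnames(samp) <- rename_jags_params(colnames(samp), design)
  structure(list(samples = samp, spec = spec,
                 ind_levels = design$ind_levels,
                 year_levels = design$year_levels,
                 design_log = design$log,
                 mcmc = spec$mcmc),
            class = "mvmm_chain")
}

# Map raw JAGS parameter names to descriptive ones (internal).
rename_jags_params <- function(nm, design) {
  spec <- design$spec
  tn <- spec$trait_names
  out <- nm
  for (k in seq_along(tn)) {
    td <- design$traits[[k]]
    cn <- colnames(td$X)
    idx <- grep(sprintf("^beta%d\\[", k), nm)
    for (i in idx) {
      p <- as.integer(sub(sprintf("^beta%d\\[(\\d+)\\]$", k), "\\1", nm[i]))
      out[i] <- sprintf("beta[%s:%s]", tn[k], cn[p])
    }
    # scalar form when the trait has a single coefficient
    out[nm == sprintf("beta%d", k)] <- sprintf("beta[%s:%s]", tn[k], cn[1])
  }
  for (pref in c("VI", "VY", "VR")) {
    lab <- c(VI = "V_I", VY = "V_year", VR = "V_R")[[pref]]
    idx <- grep(sprintf("^%s\\[", pref), nm)
    for (i in idx) {
      k <- as.integer(sub(sprintf("^%s\\[(\\d+)\\]$", pref), "\\1", nm[i]))
      out[i] <- sprintf("%s[%s]", lab, tn[k])
    }
    out[nm == pref] <- sprintf("%s[%s]", lab, tn[1])
  }
  idx <- grep("^Omega\\[", nm)
  for (i in idx) {
    rc <- as.integer(strsplit(sub("^Omega\\[(\\d+),(\\d+)\\]$", "\\1 \\2",
                                  nm[i]), " ")[[1]])
    out[i] <- sprintf("r_I[%s,%s]", tn[rc[1]], tn[rc[2]])
  }
  idx <- grep("^a\\[", nm)
  for (i in idx) {
    rc <- as.integer(strsplit(sub("^a\\[(\\d+),(\\d+)\\]$", "\\1 \\2",
                                  nm[i]), " ")[[1]])
    out[i] <- sprintf("a[%s,%s]", design$ind_levels[rc[1]], tn[rc[2]])
  }
  out
}

#' Extract posterior draws of one parameter
#'
#' @param chain An [fit_mvmm()] chain.
#' @param parameter Descriptive parameter name (e.g. `"V_I[tendency]"`,
#'   `"r_I[tendency,degree]"`).
#' @return Numeric vector of thinned draws.
#' @export
chain_draws <- function(chain, parameter) {
  stopifnot(inherits(chain, "mvmm_chain"))
  if (!parameter %in% colnames(chain$samples)) {
    stop("unknown parameter '", parameter, "'; available: ",
         paste(utils::head(colnames(chain$samples), 30), collapse = ", "))
  }
  as.numeric(chain$samples[, parameter])
}

#' Effective sample size of a chain parameter
#'
#' Standard autocorrelation-time effective sample size. A constant
#' (zero-variance) chain has undefined autocorrelation and returns `NA`.
#'
#' @param x Numeric vector of draws, or an `mvmm_chain`.
#' @param parameter Parameter name when `x` is a chain.
#' @return Effective sample size (scalar).
#' @export
effective_sample_size <- function(x, parameter = NULL) {
  if (inherits(x, "mvmm_chain")) x <- chain_draws(x, parameter)
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x))) return(NA_real_)
  as.numeric(coda::effectiveSize(coda::mcmc(x)))
}

#' Lag autocorrelation of a chain parameter
#'
#' @inheritParams effective_sample_size
#' @param lag Lag (default 1).
#' @return Autocorrelation at the given lag; `NA` for a constant chain.
#' @export
lag_autocorrelation <- function(x, parameter = NULL, lag = 1) {
  if (inherits(x, "mvmm_chain")) x <- chain_draws(x, parameter)
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x))) return(NA_real_)
  as.numeric(stats::acf(x, lag.max = lag, plot = FALSE)$acf[lag + 1])
}

#' Convergence gates: effective sample size and sampling autocorrelation
#'
#' Applies the study's gates (effective sample size above a floor, lag-1
#' autocorrelation below a ceiling) to every monitored structural parameter
#' (variances, correlations, fixed effects). Constant chains (e.g. fixed
#' variances) are excluded.
#'
#' @param chain An [fit_mvmm()] chain.
#' @param min_ess ESS floor (study convention 1000).
#' @param max_lag1 Lag-1 autocorrelation ceiling (study convention 0.1).
#' @return Tibble `parameter`, `ess`, `lag1`, `pass`; attribute `converged`
#'   gives the overall flag.
#' @export
check_convergence <- function(chain, min_ess = 1000, max_lag1 = 0.1) {
  stopifnot(inherits(chain, "mvmm_chain"))
  nm <- colnames(chain$samples)
  nm <- nm[!startsWith(nm, "a[")]
  res <- lapply(nm, function(p) {
    d <- chain_draws(chain, p)
    if (stats::sd(d) == 0) return(NULL)   # fixed / degenerate: not gated
    tibble::tibble(parameter = p,
                   ess = effective_sample_size(d),
                   lag1 = lag_autocorrelation(d))
  })
  res <- dplyr::bind_rows(res)
  res$pass <- res$ess >= min_ess & abs(res$lag1) <= max_lag1
  structure(res, converged = all(res$pass))
}

#' Per-individual random-effect summaries (BLUP analogues)
#'
#' Marginal posterior means, density-based modes and 95% HPD intervals of the
#' individual effects. Intended for visualization; the retained uncertainty
#' must not be discarded in downstream inference.
#'
#' @param chain A chain fitted with `monitor_individual = TRUE`.
#' @return Tibble `individual_id`, `trait`, `post_mean`, `post_mode`,
#'   `lower`, `upper`.
#' @export
extract_individual_effects <- function(chain) {
  stopifnot(inherits(chain, "mvmm_chain"))
  nm <- grep("^a\\[", colnames(chain$samples), value = TRUE)
  if (!length(nm)) stop("chain was not fitted with monitor_individual = TRUE")
  parts <- sub("^a\\[(.*)\\]$", "\\1", nm)
  sp <- strsplit(parts, ",")
  res <- lapply(seq_along(nm), function(i) {
    d <- as.numeric(chain$samples[, nm[i]])
    dens <- stats::density(d)
    ci <- hpd_interval(d)
    tibble::tibble(individual_id = sp[[i]][1], trait = sp[[i]][2],
                   post_mean = mean(d), post_mode = dens$x[which.max(dens$y)],
                   lower = ci[1], upper = ci[2])
  })
  dplyr::bind_rows(res)
}

#' Summarize a fitted chain
#'
#' @param object An `mvmm_chain`.
#' @param prob Interval mass (default 0.95, HPD).
#' @param ... Unused.
#' @return Tibble `parameter`, `mean`, `lower`, `upper`, `ess`, `lag1`.
#' @export
summary.mvmm_chain <- function(object, prob = 0.95, ...) {
  nm <- colnames(object$samples)
  nm <- nm[!startsWith(nm, "a[")]
  res <- lapply(nm, function(p) {
    d <- as.numeric(object$samples[, p])
    ci <- hpd_interval(d, prob)
    tibble::tibble(parameter = p, mean = mean(d), lower = ci[1], upper = ci[2],
                   ess = effective_sample_size(d),
                   lag1 = lag_autocorrelation(d))
  })
  dplyr::bind_rows(res)
}

#' @export
print.mvmm_chain <- function(x, ...) {
  cat("Multivariate mixed-model chain:",
      nrow(x$samples), "retained draws,",
      length(x$spec$traits), "trait(s),",
      x$spec$individual_struct, "individual structure\n")
  invisible(x)
}

#' Persist a chain to disk
#'
#' Writes the thinned draws as CSV (one row per retained draw) and a JSON
#' summary (posterior mean, 95% interval, ESS, lag-1 autocorrelation and the
#' convergence flag per parameter).
#'
#' @param chain An `mvmm_chain`.
#' @param path_csv,path_json Output paths.
#' @param min_ess,max_lag1 Gates recorded in the summary.
#' @return `path_csv`, invisibly.
#' @export
write_chain <- function(chain, path_csv, path_json = NULL,
                        min_ess = 1000, max_lag1 = 0.1) {
  readr::write_csv(tibble::as_tibble(as.data.frame(unclass(chain$samples))),
                   path_csv)
  if (!is.null(path_json)) {
    s <- summary(chain)
    s$pass <- s$ess >= min_ess & abs(s$lag1) <= max_lag1
    jsonlite::write_json(s, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_csv)
}
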