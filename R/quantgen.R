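#' Latent-scale repeatability from variance draws
#'
#' `R = V_I / (V_I + V_R)`, applied draw-wise. The denominator deliberately
#' excludes the year variance: this is repeatability adjusted for
#' (conditional on) year. Draws with non-positive total variance are
#' discarded and counted.
#'
#' @param V_I,V_R Numeric vectors of posterior draws (recycled to equal
#'   length).
#' @return Numeric vector of R draws; attribute `n_dropped` counts discarded
#'   draws.
#' @export
repeatability_latent <- function(V_I, V_R) {
  n <- max(length(V_I), length(V_R))
  V_I <- rep_len(V_I, n); V_R <- rep_len(V_R, n)
  tot <- V_I + V_R
  bad <- !(tot > 0) | !is.finite(tot)
  structure((V_I / tot)[!bad], n_dropped = sum(bad))
}

#' Observed-scale repeatability for a Poisson log-link trait
#'
#' Transforms latent-scale variance components of a log-link Poisson trait
#' to the observed (count) scale, draw-wise, using the log-normal–Poisson
#' moments: with `lambda = exp(mu + (V_I + V_R) / 2)`,
#' `V_I_obs = lambda^2 (exp(V_I) - 1)`,
#' `V_P_obs = lambda^2 (exp(V_I + V_R) - 1) + lambda`, and
#' `R_obs = V_I_obs / V_P_obs`. The additive `lambda` term is the Poisson
#' sampling variance, which only ever adds phenotypic variance, so
#' `R_obs <= R_latent` at the same variances.
#'
#' @param mu Latent intercept draw(s) (covariates are centred, so the
#'   intercept is the population latent mean).
#' @param V_I,V_R Latent-scale variance draws.
#' @return Numeric vector of observed-scale R draws.
#' @export
repeatability_observed_poisson <- function(mu, V_I, V_R) {
  n <- max(length(mu), length(V_I), length(V_R))
  mu <- rep_len(mu, n); V_I <- rep_len(V_I, n); V_R <- rep_len(V_R, n)
  stopifnot(all(is.finite(mu)), all(is.finite(V_I)), all(is.finite(V_R)))
  lam <- exp(mu + (V_I + V_R) / 2)
  vi_obs <- lam^2 * (exp(V_I) - 1)
  vp_obs <- lam^2 * (exp(V_I + V_R) - 1) + lam
  vi_obs / vp_obs
}

#' Highest-posterior-density interval
#'
#' Narrowest interval containing the requested posterior mass (the
#' convention used throughout); a quantile (equal-tail) interval is
#' available by flag.
#'
#' @param draws Numeric vector.
#' @param prob Interval mass (default 0.95).
#' @param method `"hpd"` or `"quantile"`.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95, method = c("hpd", "quantile")) {
  method <- match.arg(method)
  stopifnot(length(draws) >= 1, prob > 0, prob <= 1)
  if (method == "quantile") {
    q <- stats::quantile(draws, c((1 - prob) / 2, 1 - (1 - prob) / 2),
                         names = FALSE)
    return(q)
  }
  if (prob == 1 || length(unique(draws)) == 1L) {
    return(range(draws))
  }
  iv <- coda::HPDinterval(coda::mcmc(as.numeric(draws)), prob = prob)
  c(iv[1, "lower"], iv[1, "upper"])
}

#' Does a credible interval exclude zero?
#'
#' The study's significance convention: an effect is significantly different
#' from zero when its 95% credible interval does not overlap zero. A
#' degenerate `[0, 0]` interval touches zero and is not significant.
#'
#' @param interval Length-2 numeric `c(lower, upper)`.
#' @return Logical flag.
#' @export
significant_nonzero <- function(interval) {
  stopifnot(length(interval) == 2, interval[1] <= interval[2])
  interval[1] > 0 || interval[2] < 0
}

#' Convert probability of direction to a two-sided p-value
#'
#' `p = 2 * (1 - pd)`, where pd is the posterior probability that the
#' parameter has its majority sign.
#'
#' @param pd Probability of direction, in `[0.5, 1]`.
#' @return Two-sided p-value.
#' @export
pd_to_p <- function(pd) {
  stopifnot(all(pd >= 0.5 - 1e-12), all(pd <= 1 + 1e-12))
  2 * (1 - pd)
}

#' Probability of direction of a draw vector
#'
#' @param draws Numeric vector.
#' @return `max(P(draws > 0), P(draws < 0))` with ties at zero split toward
#'   the majority side excluded from neither count's denominator.
#' @export
prob_direction <- function(draws) {
  stopifnot(length(draws) >= 1)
  max(mean(draws > 0), mean(draws < 0))
}

#' Sex-difference test on a posterior parameter
#'
#' Forms the distribution of the female-minus-male difference by pairing
#' draws from the two (independent) chains, and converts its probability of
#' direction to a two-sided p-value.
#'
#' @param draws_f,draws_m Posterior draws of the same parameter from the
#'   female and male models (truncated to the shorter length).
#' @return List `diff_mean`, `interval`, `pd`, `p`.
#' @export
sex_difference <- function(draws_f, draws_m) {
  n <- min(length(draws_f), length(draws_m))
  stopifnot(n >= 1)
  d <- draws_f[seq_len(n)] - draws_m[seq_len(n)]
  pd <- prob_direction(d)
  list(diff_mean = mean(d), interval = hpd_interval(d), pd = pd,
       p = pd_to_p(pd))
}

#' Repeatability table from a fitted multivariate model
#'
#' Summarizes, per trait, the latent-scale repeatability (posterior mean and
#' 95% HPD interval) and, for Poisson log-link traits, the observed-scale
#' repeatability obtained by draw-wise transformation with the trait's
#' intercept.
#'
#' @param chain An [fit_mvmm()] chain from an `idh` model.
#' @param sex Optional label column.
#' @return Tibble `trait`, `sex`, `distribution`, `latent_R`,
#'   `latent_lower`, `latent_upper`, `data_R`, `data_lower`, `data_upper`,
#'   `significant` (among-individual variance interval excludes zero).
#' @export
repeatability_table <- function(chain, sex = NA_character_) {
  stopifnot(inherits(chain, "mvmm_chain"))
  rows <- lapply(seq_along(chain$spec$traits), function(k) {
    tr <- chain$spec$traits[[k]]
    vi <- chain_draws(chain, sprintf("V_I[%s]", tr$name))
    vr <- chain_draws(chain, sprintf("V_R[%s]", tr$name))
    rl <- repeatability_latent(vi, vr)
    ci <- hpd_interval(rl)
    vici <- hpd_interval(vi)
    row <- tibble::tibble(trait = tr$name, sex = sex,
                          distribution = tr$distribution,
                          latent_R = mean(rl), latent_lower = ci[1],
                          latent_upper = ci[2],
                          data_R = NA_real_, data_lower = NA_real_,
                          data_upper = NA_real_,
                          significant = significant_nonzero(vici))
    if (tr$distribution == "poisson_log") {
      mu <- chain_draws(chain, sprintf("beta[%s:(Intercept)]", tr$name))
      rd <- repeatability_observed_poisson(mu, vi, vr)
      cid <- hpd_interval(rd)
      row$data_R <- mean(rd); row$data_lower <- cid[1]; row$data_upper <- cid[2]
    } else {
      # identity link: latent scale and data scale coincide
      row$data_R <- row$latent_R
      row$data_lower <- ci[1]; row$data_upper <- ci[2]
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Among-individual correlation table from a corgh model
#'
#' @param chain An [fit_mvmm()] chain from a `corgh` model.
#' @param sex Optional label column.
#' @param pairs Optional two-column matrix of trait-name pairs to report
#'   (default: all unordered pairs).
#' @return Tibble `trait_1`, `trait_2`, `sex`, `correlation`, `lower`,
#'   `upper`, `significant`.
#' @export
correlation_table <- function(chain, sex = NA_character_, pairs = NULL) {
  stopifnot(inherits(chain, "mvmm_chain"),
            chain$spec$individual_struct == "corgh")
  tn <- chain$spec$trait_names
  if (is.null(pairs)) {
    pairs <- t(utils::combn(tn, 2))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- chain_draws(chain, sprintf("r_I[%s,%s]", pairs[i, 1], pairs[i, 2]))
    ci <- hpd_interval(d)
    tibble::tibble(trait_1 = pairs[i, 1], trait_2 = pairs[i, 2], sex = sex,
                   correlation = mean(d), lower = ci[1], upper = ci[2],
                   significant = significant_nonzero(ci))
  })
  dplyr::bind_rows(rows)
}
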