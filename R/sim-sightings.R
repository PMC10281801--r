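#' Configuration for sighting-level simulation
#'
#' Emulates half-day transect surveys of a habituated population: each
#' individual holds a fixed home-range centre, is detected per survey with a
#' fixed probability, and detected fixes scatter around the centre with a
#' bivariate-normal movement scale. Social structure is injected by
#' relocating a detected individual next to a concurrently detected
#' neighbour with probability increasing in the dyad's mean latent
#' gregariousness.
#'
#' Home-range centres default to a jittered square grid with spacing
#' `3 * hr_sd`, so that chance (non-social) co-proximity at the association
#' radius is rare and association structure is attributable to
#' `gregariousness`.
#'
#' @param n_individuals Number of individuals.
#' @param sex_ratio Fraction female.
#' @param n_years Number of seasons simulated.
#' @param n_surveys_per_year Surveys (half-day sessions) per year.
#' @param hr_center Optional n x 2 matrix of centres (metres); default
#'   jittered grid.
#' @param hr_sd Movement scale around the centre (metres).
#' @param gregariousness Per-individual latent propensity (logit scale) to be
#'   placed near others; scalar recycled. `-Inf` disables placement.
#' @param association_radius Metres; associates are placed within this
#'   distance (default 1.85).
#' @param detection_prob Per-survey detection probability.
#' @param neighbour_radius Metres; only concurrently detected individuals
#'   whose centres lie within this distance are candidate associates.
#' @param aggression_prob Per-individual probability that a sighting's
#'   behaviour code is `aggressive`; scalar recycled.
#' @param seed Integer seed.
#' @return Object of class `sighting_sim_config`.
#' @export
sighting_sim_config <- function(n_individuals = 30,
                                sex_ratio = 0.5,
                                n_years = 4,
                                n_surveys_per_year = 60,
                                hr_center = NULL,
                                hr_sd = 12,
                                gregariousness = 0,
                                association_radius = 1.85,
                                detection_prob = 0.8,
                                neighbour_radius = 60,
                                aggression_prob = 0.1,
                                seed = 1L) {
  stopifnot(n_individuals >= 1, hr_sd > 0, association_radius > 0,
            detection_prob > 0, detection_prob <= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  n <- as.integer(n_individuals)
  if (is.null(hr_center)) {
    side <- ceiling(sqrt(n))
    gx <- (seq_len(side) - 1) * 3 * hr_sd
    grid <- as.matrix(expand.grid(x = gx, y = gx))[seq_len(n), , drop = FALSE]
    set.seed(as.integer(seed) + 7L)   # jitter independent of survey stream
    hr_center <- grid + matrix(stats::runif(2 * n, -hr_sd / 2, hr_sd / 2), n, 2)
  }
  hr_center <- as.matrix(hr_center)
  stopifnot(nrow(hr_center) == n, ncol(hr_center) == 2)
  rec <- function(x) if (length(x) == 1L) rep(x, n) else {stopifnot(length(x) == n); x}
  structure(
    list(n_individuals = n, sex_ratio = sex_ratio,
         n_years = as.integer(n_years),
         n_surveys_per_year = as.integer(n_surveys_per_year),
         hr_center = hr_center, hr_sd = hr_sd,
         gregariousness = rec(gregariousness),
         association_radius = association_radius,
         detection_prob = detection_prob,
         neighbour_radius = neighbour_radius,
         aggression_prob = rec(aggression_prob),
         seed = as.integer(seed)),
    class = "sighting_sim_config"
  )
}

#' Simulate georeferenced sighting records
#'
#' Produces one row per detected individual per survey in the standard
#' sighting schema: `individual_id`, `sex` (F/M), `year`, `survey_id`,
#' `x_m`, `y_m`, `behaviour` (rest / aggressive / other).
#'
#' Within a survey, detected individuals are visited in random order; with
#' probability `plogis(mean gregariousness of the dyad)` an individual's fix
#' is relocated to a uniform point within 90% of the association radius of a
#' randomly chosen concurrently detected neighbour (centres within
#' `neighbour_radius`), generating proximity-based associations.
#'
#' @param cfg A [sighting_sim_config()].
#' @return Tibble of sightings.
#' @export
simulate_sightings <- function(cfg) {
  stopifnot(inherits(cfg, "sighting_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  ids <- sprintf("ind%03d", seq_len(n))
  sex <- c("F", "M")[1L + (stats::runif(n) >= cfg$sex_ratio)]

  # candidate neighbours by home-range centre distance
  cdist <- as.matrix(stats::dist(cfg$hr_center))
  nbr <- lapply(seq_len(n), function(i) {
    j <- which(cdist[i, ] <= cfg$neighbour_radius & seq_len(n) != i)
    j
  })

  out <- vector("list", cfg$n_years * cfg$n_surveys_per_year)
  s_global <- 0L
  for (yr in seq_len(cfg$n_years)) {
    year <- 2013L + yr
    for (s in seq_len(cfg$n_surveys_per_year)) {
      s_global <- s_global + 1L
      det <- which(stats::runif(n) < cfg$detection_prob)
      if (!length(det)) next
      pos <- cfg$hr_center[det, , drop = FALSE] +
        matrix(stats::rnorm(2 * length(det), 0, cfg$hr_sd), ncol = 2)
      rownames(pos) <- as.character(det)
      # social placement pass
      for (i in sample(seq_along(det))) {
        cand <- intersect(nbr[[det[i]]], det[-i])
        if (!length(cand)) next
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        p <- stats::plogis(mean(c(cfg$gregariousness[det[i]],
                                  cfg$gregariousness[j])))
        if (stats::runif(1) < p) {
          ang <- stats::runif(1, 0, 2 * pi)
          r <- sqrt(stats::runif(1)) * 0.9 * cfg$association_radius
          pos[i, ] <- pos[as.character(j) == rownames(pos), , drop = FALSE][1, ] +
            r * c(cos(ang), sin(ang))
        }
      }
      beh <- ifelse(stats::runif(length(det)) < cfg$aggression_prob[det],
                    "aggressive",
                    sample(c("rest", "other"), length(det), replace = TRUE))
      out[[s_global]] <- tibble::tibble(
        individual_id = ids[det], sex = sex[det], year = year,
        survey_id = sprintf("S%05d", s_global),
        x_m = pos[, 1], y_m = pos[, 2], behaviour = beh)
    }
  }
  sightings <- dplyr::bind_rows(out)
  attr(sightings, "sex_table") <- tibble::tibble(individual_id = ids, sex = sex)
  sightings
}

#' Write sightings and ground truth to disk
#'
#' @param sightings Tibble from [simulate_sightings()].
#' @param truth Optional truth record (list); written as JSON alongside.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(sightings, path, truth = NULL) {
  readr::write_csv(sightings, path)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, sub("\\.csv$", "_truth.json", path),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

#' Read a sighting CSV in the standard schema
#'
#' @param path CSV with columns `individual_id`, `sex`, `year`, `survey_id`,
#'   `x_m`, `y_m`, `behaviour`.
#' @return Tibble of sightings.
#' @export
read_sightings <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         individual_id = readr::col_character(),
                         sex = readr::col_character(),
                         year = readr::col_integer(),
                         survey_id = readr::col_character(),
                         x_m = readr::col_double(),
                         y_m = readr::col_double(),
                         behaviour = readr::col_character()))
  need <- c("individual_id", "sex", "year", "survey_id", "x_m", "y_m", "behaviour")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("sighting file missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(x$x_m)) || any(!is.finite(x$y_m))) {
    stop("non-finite coordinates in sighting file")
  }
  x
}
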