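#' Collapse repeated fixes to one presence per individual per survey
#'
#' A survey is a half-day session; multiple fixes of one individual within a
#' survey collapse to a single presence carrying the first fix's coordinates
#' and behaviour code (first in file order).
#'
#' @param sightings Sighting tibble (standard schema).
#' @return Collapsed tibble, one row per individual per survey.
#' @export
collapse_fixes <- function(sightings) {
  dplyr::distinct(sightings, .data$individual_id, .data$survey_id,
                  .keep_all = TRUE)
}

#' Detect proximity associations within one survey
#'
#' For every ordered focal-partner pair whose Euclidean distance is within
#' the association radius (closed boundary, `<=`), an event is recorded for
#' the focal if and only if the focal's own fix lies inside the focal's 50%
#' core home range for that year. No transitive closure is applied: A-B and
#' B-C within radius does not imply A-C. Focals without an available core
#' range are skipped and reported in the `skipped` attribute.
#'
#' @param survey_sightings Collapsed sightings of a single survey.
#' @param radius Association radius in metres (default 1.85).
#' @param ranges Named list of [core_contour()] ranges keyed `"id.year"`.
#' @return Tibble `focal`, `associate`, `associate_sex`, `survey_id`, with a
#'   `skipped` attribute listing focals lacking a core range.
#' @export
detect_associations <- function(survey_sightings, radius = 1.85, ranges) {
  s <- survey_sightings
  if (length(unique(s$survey_id)) > 1) stop("sightings span multiple surveys")
  n <- nrow(s)
  empty <- tibble::tibble(focal = character(), associate = character(),
                          associate_sex = character(), survey_id = character())
  if (n < 2) return(structure(empty, skipped = character()))
  d <- as.matrix(stats::dist(cbind(s$x_m, s$y_m)))
  key <- paste(s$individual_id, s$year, sep = ".")
  in_core <- vapply(seq_len(n), function(i) {
    hr <- ranges[[key[i]]]
    if (is.null(hr)) NA else in_core_range(hr, s$x_m[i], s$y_m[i])
  }, logical(1))
  skipped <- unique(s$individual_id[is.na(in_core)])
  pairs <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
  rows <- list()
  if (nrow(pairs)) {
    # ordered events: one per focal whose fix is in-core
    for (dir in 1:2) {
      f <- pairs[, dir]; a <- pairs[, 3 - dir]
      ok <- !is.na(in_core[f]) & in_core[f]
      rows[[dir]] <- tibble::tibble(focal = s$individual_id[f][ok],
                                    associate = s$individual_id[a][ok],
                                    associate_sex = s$sex[a][ok],
                                    survey_id = s$survey_id[f][ok])
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty
  structure(out, skipped = skipped)
}

#' Half-weight association index
#'
#' `HWI = x / (x + yAB + 0.5 * (yA + yB))` where `x` counts sampling periods
#' with both individuals seen and associated, `yA`/`yB` periods with only one
#' seen, and `yAB` periods with both seen but not associated. Vectorized.
#'
#' @param x,yA,yB,yAB Non-negative counts.
#' @return HWI in `[0, 1]`; `NA` where all four counts are zero.
#' @export
half_weight_index <- function(x, yA, yB, yAB) {
  if (any(c(x, yA, yB, yAB) < 0, na.rm = TRUE)) stop("counts must be >= 0")
  den <- x + yAB + 0.5 * (yA + yB)
  ifelse(den == 0, NA_real_, x / den)
}

#' Dyadic association counts and HWI per year
#'
#' For each focal and each partner associated with it at least once in a
#' year: `x` = surveys with a focal-sided association event, `yAB` = surveys
#' with both detected minus `x`, `yA`/`yB` = surveys with only the
#' focal/partner detected. Because events are focal-sided (they require the
#' focal's fix inside its own core range), `x` and hence HWI may differ
#' between the two members of a dyad.
#'
#' @param collapsed Collapsed sightings (all surveys, one year or more).
#' @param events Association events from [detect_associations()] over the
#'   same surveys.
#' @return Tibble `focal_id`, `associate_id`, `associate_sex`, `year`, `x`,
#'   `yA`, `yB`, `yAB`, `hwi`.
#' @export
dyad_counts <- function(collapsed, events) {
  out <- list()
  for (yr in sort(unique(collapsed$year))) {
    cs <- collapsed[collapsed$year == yr, ]
    ev <- events[events$survey_id %in% unique(cs$survey_id), ]
    if (!nrow(ev)) next
    ids <- sort(unique(cs$individual_id))
    svs <- sort(unique(cs$survey_id))
    M <- matrix(0L, length(ids), length(svs), dimnames = list(ids, svs))
    M[cbind(match(cs$individual_id, ids), match(cs$survey_id, svs))] <- 1L
    seen <- rowSums(M)
    co <- M %*% t(M)
    exy <- dplyr::distinct(ev, .data$focal, .data$associate,
                           .data$associate_sex, .data$survey_id)
    xc <- dplyr::count(exy, .data$focal, .data$associate,
                       .data$associate_sex, name = "x")
    i <- match(xc$focal, ids); j <- match(xc$associate, ids)
    out[[as.character(yr)]] <- tibble::tibble(
      focal_id = xc$focal, associate_id = xc$associate,
      associate_sex = xc$associate_sex, year = yr, x = as.integer(xc$x),
      yA = as.integer(unname(seen[i] - co[cbind(i, j)])),
      yB = as.integer(unname(seen[j] - co[cbind(i, j)])),
      yAB = as.integer(unname(co[cbind(i, j)] - xc$x)))
  }
  if (!length(out)) {
    return(tibble::tibble(focal_id = character(), associate_id = character(),
                          associate_sex = character(), year = integer(),
                          x = integer(), yA = integer(), yB = integer(),
                          yAB = integer(), hwi = double()))
  }
  res <- dplyr::bind_rows(out)
  res$hwi <- half_weight_index(res$x, res$yA, res$yB, res$yAB)
  res
}

#' Social tendency of one individual-year
#'
#' Proportion of the focal's in-core sightings having at least one
#' association event with the given associate sex class.
#'
#' @param n_incore Number of the focal's sightings inside its core range.
#' @param assoc_surveys Survey ids of the focal's events (for the sex class).
#' @return Proportion in `[0, 1]`; `NA` if `n_incore` is zero.
#' @export
social_tendency <- function(n_incore, assoc_surveys) {
  if (n_incore == 0) return(NA_real_)
  length(unique(assoc_surveys)) / n_incore
}

#' Degree: distinct associates in a sex class
#'
#' @param dyads The focal's rows of a [dyad_counts()] table (x >= 1).
#' @param associate_sex `"F"` or `"M"`.
#' @return Integer count.
#' @export
assoc_degree <- function(dyads, associate_sex) {
  length(unique(dyads$associate_id[dyads$associate_sex == associate_sex]))
}

#' Mean half-weight index over a focal's associates
#'
#' Arithmetic mean of dyadic HWI over the focal's associates in the sex
#' class; 0 when the focal has no associates in that class (degree 0).
#'
#' @inheritParams assoc_degree
#' @return Mean HWI in `[0, 1]`.
#' @export
mean_hwi <- function(dyads, associate_sex) {
  v <- dyads$hwi[dyads$associate_sex == associate_sex & dyads$x >= 1]
  v <- v[!is.na(v)]
  if (!length(v)) 0 else mean(v)
}

#' Social dominance: proportion of aggressive displays per year
#'
#' @param behaviours Character vector of the focal's behaviour codes that
#'   year.
#' @return Proportion in `[0, 1]`; `NA` for an empty vector.
#' @export
social_dominance <- function(behaviours) {
  if (!length(behaviours)) return(NA_real_)
  mean(behaviours == "aggressive")
}

#' Build the yearly social-measures table from sightings
#'
#' End-to-end aggregation: collapses fixes, estimates core home ranges and
#' conspecific densities, detects proximity associations inside core ranges,
#' and assembles per individual-year the eight sex-partitioned social traits
#' (tendency / degree / mean HWI / density, each opposite-sex and same-sex),
#' social dominance, and the sighting count. Individual-years without an
#' eligible core range (fewer than `min_sightings_hr` sightings) carry
#' missing social metrics.
#'
#' @param sightings Sighting tibble (standard schema).
#' @param covariates Optional per-individual tibble (`individual_id`,
#'   `maturity_year`, `heterozygosity`, `offspring`); joined, with
#'   `age = year - maturity_year`.
#' @param radius Association radius in metres.
#' @param h Kernel smoothing parameter (metres).
#' @param cell_size Utilization grid cell side (metres).
#' @param min_sightings_hr Home-range/density eligibility threshold
#'   (default 25).
#' @return List: `measures` (tibble, one row per individual-year), `dyads`
#'   (dyadic HWI table), `home_ranges` (per individual-year table), `log`
#'   (character vector of processing notes).
#' @export
yearly_social_measures <- function(sightings, covariates = NULL,
                                   radius = 1.85, h = 7, cell_size = 1,
                                   min_sightings_hr = 25) {
  log <- character()
  cs <- collapse_fixes(sightings)
  log <- c(log, sprintf("collapsed %d fixes to %d survey presences",
                        nrow(sightings), nrow(cs)))
  hr <- home_ranges(cs, h = h, cell_size = cell_size,
                    min_sightings = min_sightings_hr)
  log <- c(log, sprintf("home ranges: %d eligible of %d individual-years",
                        sum(hr$table$eligible), nrow(hr$table)))
  ev <- dplyr::bind_rows(lapply(split(cs, cs$survey_id), detect_associations,
                                radius = radius, ranges = hr$ranges))
  dy <- dyad_counts(cs, ev)

  key <- paste(cs$individual_id, cs$year, sep = ".")
  incore <- vapply(seq_len(nrow(cs)), function(i) {
    r <- hr$ranges[[key[i]]]
    !is.null(r) && in_core_range(r, cs$x_m[i], cs$y_m[i])
  }, logical(1))

  ev_sex <- ev   # associate sex per event for OS/SS split
  rows <- lapply(seq_len(nrow(hr$table)), function(r) {
    id <- hr$table$individual_id[r]; yr <- hr$table$year[r]
    sx <- hr$table$sex[r]
    own <- cs$individual_id == id & cs$year == yr
    beh <- cs$behaviour[own]
    base <- tibble::tibble(
      individual_id = id, sex = sx, year = yr,
      n_sightings = hr$table$n_sightings[r],
      dominance = social_dominance(beh))
    if (!hr$table$eligible[r]) {
      return(dplyr::bind_cols(base, tibble::tibble(
        tendency_os = NA_real_, tendency_ss = NA_real_,
        degree_os = NA_integer_, degree_ss = NA_integer_,
        hwi_os = NA_real_, hwi_ss = NA_real_,
        density_os = NA_real_, density_ss = NA_real_,
        area_m2 = NA_real_)))
    }
    n_in <- sum(incore & own)
    myev <- ev_sex[ev_sex$focal == id &
                     ev_sex$survey_id %in% cs$survey_id[own], ]
    os_sex <- setdiff(c("F", "M"), sx); ss_sex <- sx
    mydy <- dy[dy$focal_id == id & dy$year == yr, ]
    dplyr::bind_cols(base, tibble::tibble(
      tendency_os = social_tendency(n_in, myev$survey_id[myev$associate_sex == os_sex]),
      tendency_ss = social_tendency(n_in, myev$survey_id[myev$associate_sex == ss_sex]),
      degree_os = assoc_degree(mydy, os_sex),
      degree_ss = assoc_degree(mydy, ss_sex),
      hwi_os = mean_hwi(mydy, os_sex),
      hwi_ss = mean_hwi(mydy, ss_sex),
      density_os = hr$table$density_os[r],
      density_ss = hr$table$density_ss[r],
      area_m2 = hr$table$area_m2[r]))
  })
  measures <- dplyr::bind_rows(rows)
  if (!is.null(covariates)) {
    measures <- dplyr::left_join(measures, covariates, by = "individual_id")
    if ("maturity_year" %in% names(measures)) {
      measures$age <- measures$year - measures$maturity_year
    }
  }
  list(measures = measures, dyads = dy, home_ranges = hr$table, log = log)
}

#' Filter yearly measures to a minimum sighting count
#'
#' @param measures Yearly measures tibble with `n_sightings`.
#' @param min_sightings Threshold (default 30, the conservative inclusion
#'   criterion for social analyses).
#' @return Filtered tibble; attribute `filter_log` records rows in/out.
#' @export
filter_min_sightings <- function(measures, min_sightings = 30) {
  out <- measures[measures$n_sightings >= min_sightings, , drop = FALSE]
  structure(out, filter_log = sprintf(
    "min_sightings >= %d: %d rows in, %d rows out",
    min_sightings, nrow(measures), nrow(out)))
}

#' Centre and scale Gaussian-modelled traits
#'
#' Transforms the named columns to mean 0, SD 1 over the supplied rows
#' (count traits such as degree and offspring stay untransformed for Poisson
#' modelling).
#'
#' @param df Data frame.
#' @param cols Columns to standardize.
#' @return `df` with standardized columns; scaling attributes
#'   `standardize_center` / `standardize_scale`.
#' @export
standardize_traits <- function(df, cols) {
  ctr <- scl <- stats::setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    v <- df[[cl]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("cannot standardize constant column: ", cl)
    m <- mean(v, na.rm = TRUE)
    df[[cl]] <- (v - m) / s
    ctr[cl] <- m; scl[cl] <- s
  }
  structure(df, standardize_center = ctr, standardize_scale = scl)
}
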