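#' Gaussian-kernel utilization distribution on a regular grid
#'
#' Product-Gaussian kernel density estimate of an individual's space use,
#' evaluated at cell centres of a square grid padded at least `3 * h` beyond
#' the data extent and normalized to unit probability mass.
#'
#' @param points Matrix or data frame with two columns (x, y) in metres.
#' @param h Kernel smoothing parameter in metres (standard deviation of the
#'   Gaussian kernel; the field default for this study system is 7 m).
#' @param cell_size Grid cell side in metres (default 1).
#' @param min_points Minimum number of sightings required for a usable
#'   estimate (default 25). With fewer points the individual-year is
#'   ineligible and `NULL` is returned rather than an error, so callers can
#'   flag and continue.
#' @return An object of class `utilization_grid`: list with `xs`, `ys` (cell
#'   centre coordinates), `values` (matrix, rows = x cells), `cell_size`; or
#'   `NULL` when ineligible.
#' @export
estimate_ud <- function(points, h = 7, cell_size = 1, min_points = 25) {
  stopifnot(h > 0, cell_size > 0)
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("non-finite coordinates")
  if (nrow(points) < min_points) return(NULL)
  pad <- 3 * h
  x0 <- floor((min(points[, 1]) - pad) / cell_size) * cell_size
  y0 <- floor((min(points[, 2]) - pad) / cell_size) * cell_size
  x1 <- ceiling((max(points[, 1]) + pad) / cell_size) * cell_size
  y1 <- ceiling((max(points[, 2]) + pad) / cell_size) * cell_size
  xs <- seq(x0 + cell_size / 2, x1, by = cell_size)
  ys <- seq(y0 + cell_size / 2, y1, by = cell_size)
  # f(gx, gy) = mean_i k(gx - xi) k(gy - yi): separable -> two matrices
  Kx <- outer(xs, points[, 1], function(g, p) stats::dnorm(g - p, sd = h))
  Ky <- outer(ys, points[, 2], function(g, p) stats::dnorm(g - p, sd = h))
  vals <- (Kx %*% t(Ky)) / nrow(points)
  vals <- vals / (sum(vals) * cell_size^2)
  structure(list(xs = xs, ys = ys, values = vals, cell_size = cell_size),
            class = "utilization_grid")
}

#' Extract a core home range as a probability contour
#'
#' Accumulates grid cells in descending density order until the cumulative
#' probability mass reaches `level` (default 0.50, the core home range HR50).
#' The region's area is the number of included cells times the cell area, so
#' the region's mass lies in `[level, level + one cell's mass]`.
#'
#' @param grid A normalized [estimate_ud()] grid.
#' @param level Probability mass of the contour, in (0, 1].
#' @return Object of class `core_home_range`: list with `cells` (two-column
#'   integer matrix of x/y cell indices), `area_m2`, `mass`, `level`, and the
#'   grid geometry (`xs`, `ys`, `cell_size`, and a logical membership matrix
#'   `member`).
#' @export
core_contour <- function(grid, level = 0.50) {
  stopifnot(inherits(grid, "utilization_grid"), level > 0, level <= 1)
  ca <- grid$cell_size^2
  total <- sum(grid$values) * ca
  if (abs(total - 1) > 1e-6) stop("utilization grid is not normalized (mass ",
                                  signif(total, 6), ")")
  v <- as.vector(grid$values)
  # deterministic tie-break: by density desc, then cell index
  ord <- order(v, seq_along(v), decreasing = c(TRUE, FALSE), method = "radix")
  cum <- cumsum(v[ord]) * ca
  n_in <- if (level >= 1) length(v) else which(cum >= level - 1e-12)[1]
  if (is.na(n_in)) n_in <- length(v)
  keep <- ord[seq_len(n_in)]
  member <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  member[keep] <- TRUE
  cells <- which(member, arr.ind = TRUE)
  structure(list(cells = cells, area_m2 = n_in * ca, mass = cum[n_in],
                 level = level, xs = grid$xs, ys = grid$ys,
                 cell_size = grid$cell_size, member = member),
            class = "core_home_range")
}

#' Test whether points fall inside a core home range
#'
#' Membership is decided by the containing grid cell of each point (no
#' sub-cell interpolation), so results are bit-reproducible.
#'
#' @param hr A [core_contour()] object.
#' @param x,y Coordinate vectors in metres.
#' @return Logical vector.
#' @export
in_core_range <- function(hr, x, y) {
  stopifnot(inherits(hr, "core_home_range"))
  cs <- hr$cell_size
  ix <- floor((x - (hr$xs[1] - cs / 2)) / cs) + 1L
  iy <- floor((y - (hr$ys[1] - cs / 2)) / cs) + 1L
  ok <- ix >= 1L & ix <= length(hr$xs) & iy >= 1L & iy <= length(hr$ys)
  res <- logical(length(x))
  res[ok] <- hr$member[cbind(ix[ok], iy[ok])]
  res
}

#' Conspecific density within a core home range
#'
#' Counts distinct conspecifics of the requested sex class having at least
#' one sighting located inside the focal's core range in that year, divided
#' by the range area. Duplicated sightings of one conspecific do not change
#' the count.
#'
#' @param focal_hr The focal's [core_contour()] region.
#' @param others Sightings of all other individuals in the same year
#'   (columns `individual_id`, `sex`, `x_m`, `y_m`).
#' @param sex_filter `"opposite"` or `"same"`.
#' @param focal_sex `"F"` or `"M"`.
#' @return Density in individuals per square metre.
#' @export
conspecific_density <- function(focal_hr, others, sex_filter = c("opposite", "same"),
                                focal_sex) {
  sex_filter <- match.arg(sex_filter)
  stopifnot(inherits(focal_hr, "core_home_range"), focal_sex %in% c("F", "M"))
  if (nrow(others) == 0) return(0)
  inside <- in_core_range(focal_hr, others$x_m, others$y_m)
  cand <- others[inside, , drop = FALSE]
  if (nrow(cand) == 0) return(0)
  bad <- unique(cand$individual_id[is.na(cand$sex) | !(cand$sex %in% c("F", "M"))])
  if (length(bad)) stop("missing or invalid sex for individual(s): ",
                        paste(bad, collapse = ", "))
  want <- if (sex_filter == "opposite") setdiff(c("F", "M"), focal_sex) else focal_sex
  length(unique(cand$individual_id[cand$sex == want])) / focal_hr$area_m2
}

#' Per-individual-year home ranges and conspecific densities
#'
#' Estimates the kernel utilization distribution and 50% core contour for
#' every individual-year with at least `min_sightings` collapsed sightings,
#' then computes opposite- and same-sex conspecific densities inside each
#' core range. Ineligible individual-years are retained with `eligible =
#' FALSE` and missing area/densities.
#'
#' @param sightings Collapsed sightings (one row per individual per survey;
#'   see [collapse_fixes()]).
#' @param h Kernel smoothing parameter (metres).
#' @param cell_size Grid cell side (metres).
#' @param min_sightings Eligibility threshold (default 25).
#' @param level Contour mass (default 0.5).
#' @return List with `table` (tibble: `individual_id`, `year`, `n_sightings`,
#'   `eligible`, `area_m2`, `density_os`, `density_ss`) and `ranges` (named
#'   list of `core_home_range` objects keyed `"id.year"`).
#' @export
home_ranges <- function(sightings, h = 7, cell_size = 1, min_sightings = 25,
                        level = 0.5) {
  keys <- dplyr::distinct(sightings, .data$individual_id, .data$year, .data$sex)
  ranges <- list()
  rows <- vector("list", nrow(keys))
  for (r in seq_len(nrow(keys))) {
    id <- keys$individual_id[r]; yr <- keys$year[r]
    own <- sightings[sightings$individual_id == id & sightings$year == yr, ]
    ud <- estimate_ud(cbind(own$x_m, own$y_m), h = h, cell_size = cell_size,
                      min_points = min_sightings)
    if (is.null(ud)) {
      rows[[r]] <- tibble::tibble(individual_id = id, year = yr,
                                  sex = keys$sex[r], n_sightings = nrow(own),
                                  eligible = FALSE, area_m2 = NA_real_,
                                  density_os = NA_real_, density_ss = NA_real_)
      next
    }
    hr <- core_contour(ud, level = level)
    others <- sightings[sightings$individual_id != id & sightings$year == yr, ]
    rows[[r]] <- tibble::tibble(
      individual_id = id, year = yr, sex = keys$sex[r], n_sightings = nrow(own),
      eligible = TRUE, area_m2 = hr$area_m2,
      density_os = conspecific_density(hr, others, "opposite", keys$sex[r]),
      density_ss = conspecific_density(hr, others, "same", keys$sex[r]))
    ranges[[paste(id, yr, sep = ".")]] <- hr
  }
  list(table = dplyr::bind_rows(rows), ranges = ranges)
}
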