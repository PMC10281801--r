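# Hand counts for the toy fixture (5 individuals, 8 surveys, year 2014):
#   surveys 1-4: A(F) at (0,0), B(M) at (1,0)      -> A-B associated
#   survey  5:   A at (0,0), C(M) at (0,1)          -> A-C associated
#   survey  6:   A alone
#   surveys 7-8: B at (10,10), D(F) at (11,10)      -> B-D associated
#   E(F) at (50,50) in all 8 surveys, never near anyone
# Dyad A-B: x=4, yA=2 (surveys 5,6), yB=2 (7,8), yAB=0 -> HWI 2/3
# Dyad A-C: x=1, yA=5, yB=0, yAB=0                      -> HWI 2/7
# Dyad B-D: x=2, yA=4, yB=0, yAB=0                      -> HWI 1/2

test_that("toy network: tendency, degree and every dyadic HWI match hand counts", {
  s <- toy_sightings()
  ranges <- toy_ranges()
  ev <- dplyr::bind_rows(lapply(split(s, s$survey_id), detect_associations,
                                radius = 1.85, ranges = ranges))
  dy <- dyad_counts(s, ev)

  get <- function(f, a) dy[dy$focal_id == f & dy$associate_id == a, ]
  ab <- get("A", "B")
  expect_equal(c(ab$x, ab$yA, ab$yB, ab$yAB), c(4, 2, 2, 0))
  expect_equal(ab$hwi, 2 / 3)
  expect_equal(get("A", "C")$hwi, 2 / 7)
  expect_equal(get("B", "D")$hwi, 1 / 2)
  expect_equal(get("B", "A")$hwi, 2 / 3)   # symmetric counts for this dyad

  # degree and mean HWI per focal
  a_dy <- dy[dy$focal_id == "A", ]
  expect_equal(assoc_degree(a_dy, "M"), 2)
  expect_equal(assoc_degree(a_dy, "F"), 0)
  expect_equal(mean_hwi(a_dy, "M"), (2 / 3 + 2 / 7) / 2)
  expect_equal(mean_hwi(a_dy, "F"), 0)
  b_dy <- dy[dy$focal_id == "B", ]
  expect_equal(assoc_degree(b_dy, "F"), 2)
  expect_equal(mean_hwi(b_dy, "F"), (2 / 3 + 1 / 2) / 2)

  # tendency: A has 6 sightings, 5 with an opposite-(M)-sex event
  a_ev <- ev[ev$focal == "A", ]
  expect_equal(social_tendency(6, a_ev$survey_id[a_ev$associate_sex == "M"]),
               5 / 6)
  expect_equal(social_tendency(6, a_ev$survey_id[a_ev$associate_sex == "F"]), 0)
  expect_equal(social_tendency(8, ev$survey_id[ev$focal == "E"]), 0)
})

test_that("association boundary is closed at the radius and non-transitive", {
  mk <- function(xs) tibble::tibble(
    individual_id = c("A", "B", "C")[seq_along(xs)], sex = "F", year = 2014L,
    survey_id = "S1", x_m = xs, y_m = 0, behaviour = "rest")
  ranges <- toy_ranges()
  ev <- detect_associations(mk(c(0, 1.85)), radius = 1.85, ranges = ranges)
  expect_equal(nrow(ev), 2)   # both directions, exactly at the boundary
  ev2 <- detect_associations(mk(c(0, 1.86)), radius = 1.85, ranges = ranges)
  expect_equal(nrow(ev2), 0)
  # chain A-B-C: A-B and B-C within radius, A-C beyond -> no A-C event
  ev3 <- detect_associations(mk(c(0, 1.5, 3.0)), radius = 1.85, ranges = ranges)
  pairs <- paste(ev3$focal, ev3$associate)
  expect_setequal(pairs, c("A B", "B A", "B C", "C B"))
})

test_that("focal-sided core restriction drops out-of-range focals and logs them", {
  s <- tibble::tibble(
    individual_id = c("A", "Z"), sex = c("F", "M"), year = 2014L,
    survey_id = "S1", x_m = c(0, 1), y_m = 0, behaviour = "rest")
  ranges <- toy_ranges()["A.2014"]   # Z has no core range
  ev <- detect_associations(s, radius = 1.85, ranges = ranges)
  expect_equal(ev$focal, "A")        # Z's event skipped
  expect_equal(attr(ev, "skipped"), "Z")
})

test_that("HWI algebra: symmetry in yA/yB, bounds, degenerate input", {
  expect_equal(half_weight_index(4, 2, 2, 0), 2 / 3)
  expect_equal(half_weight_index(4, 5, 1, 0), half_weight_index(4, 1, 5, 0))
  expect_equal(half_weight_index(0, 3, 2, 1), 0)
  expect_equal(half_weight_index(7, 0, 0, 0), 1)
  expect_true(is.na(half_weight_index(0, 0, 0, 0)))
  expect_error(half_weight_index(-1, 0, 0, 0), ">= 0")
  set.seed(1)
  x <- rpois(50, 3); yA <- rpois(50, 2); yB <- rpois(50, 2); yAB <- rpois(50, 1)
  h <- half_weight_index(x, yA, yB, yAB)
  expect_true(all(h >= 0 & h <= 1, na.rm = TRUE))
})

test_that("fixes collapse to one presence per survey with first coordinates", {
  s <- tibble::tibble(
    individual_id = c("A", "A", "A"), sex = "F", year = 2014L,
    survey_id = c("S1", "S1", "S2"), x_m = c(1, 9, 5), y_m = 0,
    behaviour = c("rest", "aggressive", "rest"))
  cs <- collapse_fixes(s)
  expect_equal(nrow(cs), 2)
  expect_equal(cs$x_m[cs$survey_id == "S1"], 1)
})

test_that("social dominance is the yearly proportion of aggressive codes", {
  expect_equal(social_dominance(rep("rest", 10)), 0)
  expect_equal(social_dominance(rep("aggressive", 4)), 1)
  expect_equal(social_dominance(c(rep("aggressive", 3), rep("rest", 27))), 0.1)
  expect_true(is.na(social_dominance(character())))
})

test_that("standardization gives exact zero mean, unit scale, and fails on constants", {
  df <- tibble::tibble(a = c(0, 1, 0, 1), b = 1:4, k = rep(2, 4))
  out <- standardize_traits(df, c("a", "b"))
  expect_lt(abs(mean(out$a)), 1e-12)
  expect_equal(stats::sd(out$b), 1)
  # balanced two-point column: deviations are +/- half the range
  expect_equal(sort(unique(out$a)), c(-0.5, 0.5) / stats::sd(df$a))
  expect_error(standardize_traits(df, "k"), "constant")
})

test_that("sighting-count filter never adds rows and keeps only eligible ones", {
  m <- tibble::tibble(individual_id = letters[1:6], n_sightings = c(10, 25, 30, 31, 40, 29))
  out <- filter_min_sightings(m, 30)
  expect_lte(nrow(out), nrow(m))
  expect_true(all(out$n_sightings >= 30))
  expect_match(attr(out, "filter_log"), "6 rows in, 3 rows out")
})
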