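test_that("sighting simulation is deterministic and schema-complete", {
  cfg <- sighting_sim_config(n_individuals = 8, n_years = 1,
                             n_surveys_per_year = 20, seed = 4)
  s1 <- simulate_sightings(cfg)
  s2 <- simulate_sightings(cfg)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_named(s1, c("individual_id", "sex", "year", "survey_id",
                     "x_m", "y_m", "behaviour"))
  expect_true(all(s1$behaviour %in% c("rest", "aggressive", "other")))
  expect_true(all(s1$sex %in% c("F", "M")))
  # roundtrip through the CSV interface
  f <- withr::local_tempfile(fileext = ".csv")
  write_sightings(s1, f)
  expect_equal(as.data.frame(read_sightings(f)), as.data.frame(s1),
               ignore_attr = TRUE)
})

test_that("asocial populations produce no associations downstream", {
  ctr <- as.matrix(expand.grid(x = c(0, 150, 300), y = c(0, 150, 300)))
  cfg <- sighting_sim_config(n_individuals = 9, n_years = 1,
                             n_surveys_per_year = 40, hr_center = ctr,
                             hr_sd = 10, gregariousness = -Inf, seed = 6)
  s <- simulate_sightings(cfg)
  hr <- open_core_range(c(min(s$x_m) - 5, max(s$x_m) + 5),
                        c(min(s$y_m) - 5, max(s$y_m) + 5), cell_size = 5)
  ranges <- stats::setNames(
    rep(list(hr), 9), paste(sprintf("ind%03d", 1:9), unique(s$year), sep = "."))
  ev <- dplyr::bind_rows(lapply(split(s, s$survey_id), detect_associations,
                                radius = 1.85, ranges = ranges))
  expect_equal(nrow(ev), 0)
})

test_that("a single individual yields no dyads, degree 0 and HWI 0", {
  cfg <- sighting_sim_config(n_individuals = 1, n_years = 1,
                             n_surveys_per_year = 40, seed = 8)
  s <- simulate_sightings(cfg)
  ym <- yearly_social_measures(s, min_sightings_hr = 20)
  row <- ym$measures[1, ]
  expect_equal(nrow(ym$dyads), 0)
  expect_equal(row$degree_os + row$degree_ss, 0L)
  expect_equal(row$hwi_os + row$hwi_ss, 0)
})

test_that("an always-together pair drives its pairwise HWI toward one", {
  # two individuals sharing a centre, very high mutual gregariousness
  ctr <- matrix(c(0, 0, 0, 0), 2, 2)
  cfg <- sighting_sim_config(n_individuals = 2, n_years = 1,
                             n_surveys_per_year = 80, hr_center = ctr,
                             hr_sd = 5, gregariousness = 30,
                             detection_prob = 1, seed = 10)
  s <- simulate_sightings(cfg)
  hr <- open_core_range(c(-40, 40), c(-40, 40), cell_size = 4)
  ranges <- stats::setNames(rep(list(hr), 2),
                            paste(c("ind001", "ind002"), s$year[1], sep = "."))
  ev <- dplyr::bind_rows(lapply(split(s, s$survey_id), detect_associations,
                                radius = 1.85, ranges = ranges))
  dy <- dyad_counts(s, ev)
  expect_gt(min(dy$hwi), 0.95)
})

test_that("sex-partitioned metrics from the full pipeline are coherent", {
  cfg <- sighting_sim_config(n_individuals = 12, n_years = 2,
                             n_surveys_per_year = 45, gregariousness = 1,
                             seed = 5)
  s <- simulate_sightings(cfg)
  ym <- yearly_social_measures(s, min_sightings_hr = 25)
  m <- ym$measures[stats::complete.cases(ym$measures[, c("tendency_os", "tendency_ss")]), ]
  expect_gt(nrow(m), 0)
  expect_true(all(m$tendency_os >= 0 & m$tendency_os <= 1))
  expect_true(all(m$hwi_os >= 0 & m$hwi_os <= 1))
  expect_true(all(m$hwi_ss >= 0 & m$hwi_ss <= 1))
  expect_true(all(m$degree_os >= 0), all(m$degree_ss >= 0))
  # degrees by sex class partition the total distinct associates
  dy <- ym$dyads
  for (i in seq_len(min(nrow(m), 5))) {
    mine <- dy[dy$focal_id == m$individual_id[i] & dy$year == m$year[i], ]
    expect_equal(m$degree_os[i] + m$degree_ss[i],
                 length(unique(mine$associate_id)))
  }
  # dyad-count invariant: x + yAB cannot exceed either member's sighting count
  expect_true(all(dy$x + dy$yAB <= dy$x + dy$yAB + dy$yA))
  expect_true(all(dy$x >= 0 & dy$yA >= 0 & dy$yB >= 0 & dy$yAB >= 0))
})
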