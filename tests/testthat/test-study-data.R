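test_that("long CSV round-trips through read/write bit-exactly", {
  d <- tiny_data()
  f <- withr::local_tempfile(fileext = ".csv")
  write_dta(d, f)
  d2 <- read_dta(f)
  expect_identical(d2$counts, d$counts)

  # a 7-threshold study survives the round trip too
  sim <- simulate_dta(scenario_spec(n_studies = 3,
                                    thresholds_per_study = c(7, 7)),
                      seed = 21)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dta(sim$data, f2)
  expect_identical(read_dta(f2)$counts, sim$data$counts)
  expect_equal(sum(read_dta(f2)$counts$study_id == "study01" &
                     read_dta(f2)$counts$group == 1), 7)
})

test_that("group labels in all accepted codings normalise identically", {
  base <- tiny_counts()
  for (coding in list(c("0", "1"), c("disease_free", "diseased"),
                      c("control", "case"))) {
    cc <- base
    cc$group <- coding[base$group]
    expect_identical(dta_data(cc)$counts, dta_data(base)$counts)
  }
  bad <- base
  bad$group <- c("healthy", "sick")[base$group]
  expect_error(dta_data(bad), "group labels")
})

test_that("validation rejects malformed datasets and names the study", {
  cc <- tiny_counts()
  cc$count_above[1:2] <- c(3, 5)  # increasing with threshold
  expect_error(dta_data(cc), "s1.*non-increasing")

  dup <- tiny_counts()
  dup$threshold[1:2] <- c(50, 50)
  expect_error(dta_data(dup), "s1.*[Dd]uplicated")

  over <- tiny_counts()
  over$count_above[5] <- 150  # > N
  expect_error(dta_data(over), "s2.*\\[0, N\\]")

  onegrp <- tiny_counts()[1:4, ]
  onegrp$group <- 1
  onegrp$N <- 100
  onegrp$threshold <- c(50, 200, 300, 400)
  onegrp$count_above <- c(40, 30, 20, 10)
  expect_error(dta_data(onegrp), "both disease groups")

  expect_error(dta_data(tiny_counts()[, -3]), "missing column")
})

test_that("covariate table must reference known studies, one row each", {
  cc <- tiny_counts()
  expect_silent(d <- dta_data(cc, data.frame(study_id = c("s1", "s2"),
                                             age = c(60, 70))))
  expect_equal(d$covariates$age, c(60, 70))
  expect_error(dta_data(cc, data.frame(study_id = c("s1", "sX"), age = 1:2)),
               "unknown study")
  expect_error(dta_data(cc, data.frame(study_id = c("s1", "s1"), age = 1:2)),
               "one row per study")
  expect_error(dta_data(cc, data.frame(study_id = c("s1", "s2"),
                                       age = c(60, Inf))), "finite")
})

test_that("accuracy fractions convert to counts by rounding", {
  d <- dta_from_accuracy(100, 100, thresholds = c(1, 2),
                         sens = c(0.9, 0.6), spec = c(0.7, 0.9))
  cts <- d$counts
  expect_equal(cts$count_above[cts$group == 2], c(90, 60))
  expect_equal(cts$count_above[cts$group == 1], c(30, 10))

  d2 <- dta_from_accuracy(10, 10, 1, sens = 0.5, spec = 0.5)
  expect_equal(sort(d2$counts$count_above), c(5, 5))

  d3 <- dta_from_accuracy(100, 1000, c(1, 2), sens = c(0.905, 0.904),
                          spec = c(0.5, 0.6))
  expect_equal(d3$counts$count_above[d3$counts$group == 2], c(905, 904))

  # rounding that breaks monotonicity is an error, not silently repaired
  expect_error(dta_from_accuracy(100, 1000, c(1, 2),
                                 sens = c(0.9044, 0.9046),
                                 spec = c(0.5, 0.6)),
               "non-increasing")
  expect_error(dta_from_accuracy(10, 10, 1, sens = 1.2, spec = 0.5),
               "\\[0, 1\\]")
})

test_that("conditional binomial decomposition chains trials correctly", {
  expect_equal(conditional_counts(10, c(8, 5)),
               data.frame(trials = c(10, 8), successes = c(8, 5)))
  expect_equal(conditional_counts(10, c(0, 0)),
               data.frame(trials = c(10, 0), successes = c(0, 0)))
  expect_equal(conditional_counts(20, c(15, 10, 2)),
               data.frame(trials = c(20, 15, 10), successes = c(15, 10, 2)))

  # totals are preserved: successes at t are the trials at t + 1
  set.seed(101)
  for (k in 1:25) {
    inst <- random_instance()
    cc <- conditional_counts(inst$N, inst$counts)
    if (nrow(cc) > 1)
      expect_identical(cc$successes[-nrow(cc)], cc$trials[-1])
  }
})

test_that("generated datasets always pass validation", {
  for (s in 1:5) {
    sim <- simulate_dta(scenario_spec(n_studies = 8, missingness = 0.3),
                        seed = 300 + s)
    expect_silent(validate_dta(sim$data))
  }
})
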