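test_that("day-count rules follow the state definitions, including boundaries", {
  # >350 days full-year; 30-350 closed interval mid/low; <30 jobless
  days <- c(365, 351, 350, 200, 30, 29, 1, 0)
  got <- classify_states(days)
  expect_equal(as.character(got),
               c("full_year", "full_year", "mid_low", "mid_low", "mid_low",
                 "unemp_inactive", "unemp_inactive", "unemp_inactive"))
})

test_that("death dominates every other rule regardless of precedence order", {
  for (prec in list(default_precedence(),
                    c("days", "retired", "disability", "dead"),
                    c("retired", "dead", "disability", "days"))) {
    got <- classify_states(300, disability_pension = TRUE,
                           old_age_pension = TRUE, died_in_year = TRUE,
                           precedence = prec)
    expect_equal(as.character(got), "dead")
  }
})

test_that("pension flags beat day counts under the default precedence", {
  expect_equal(as.character(classify_states(200, disability_pension = TRUE)),
               "disability")
  expect_equal(as.character(classify_states(340, old_age_pension = TRUE)),
               "retired")
  # retired beats disability when both flags are present
  expect_equal(as.character(classify_states(0, disability_pension = TRUE,
                                            old_age_pension = TRUE)),
               "retired")
  # a precedence that puts day counts first lets employment win instead
  got <- classify_states(200, disability_pension = TRUE,
                         precedence = c("dead", "days", "retired", "disability"))
  expect_equal(as.character(got), "mid_low")
})

test_that("the three day-count intervals partition [0, 366]", {
  got <- classify_states(0:366)
  expect_false(anyNA(got))
  expect_equal(sum(got == "unemp_inactive"), 30L)  # 0..29
  expect_equal(sum(got == "mid_low"), 321L)        # 30..350
  expect_equal(sum(got == "full_year"), 16L)       # 351..366
})

test_that("malformed records are rejected with the offending field named", {
  expect_error(classify_states(c(100, 400)), "days_employed")
  base <- ten_row_fixture()
  bad_age <- base; bad_age$age[3] <- 25
  expect_error(classify_dataset(bad_age), "age")
  bad_flags <- base
  bad_flags$died_in_year[2] <- TRUE
  bad_flags$censored_in_year[2] <- TRUE
  expect_error(classify_dataset(bad_flags), "died_in_year/censored_in_year")
  dup <- rbind(base, base[4, ])
  expect_error(classify_dataset(dup), "\\(4, 2005\\)")
  after_death <- rbind(person_year_row(1, year = 2005, died = TRUE),
                       person_year_row(1, year = 2006))
  expect_error(classify_dataset(after_death), "after a death record")
})

test_that("the ten-row fixture reproduces its hand-derived state counts", {
  cl <- classify_dataset(ten_row_fixture())
  expect_equal(nrow(cl), 10L)
  counts <- table(cl$state)
  expect_equal(as.integer(counts[names(ten_row_expected_counts)]),
               unname(ten_row_expected_counts))
})

test_that("classification is total, deterministic, and permutation-equivariant", {
  pop <- cached_population(500, seed = 4)
  cl <- classify_dataset(pop)
  expect_equal(nrow(cl), nrow(pop))
  expect_false(anyNA(cl$state))
  # dead iff died_in_year
  expect_equal(cl$state == "dead", as.logical(cl$died_in_year))
  set.seed(99)
  perm <- sample.int(nrow(pop))
  cl2 <- classify_dataset(pop[perm, ])
  expect_equal(as.character(cl2$state), as.character(cl$state)[perm])
})

test_that("person-year CSV round-trips through the I/O layer", {
  path <- tempfile(fileext = ".csv")
  pop <- cached_population(50, seed = 8)
  write_person_years(pop, path)
  back <- read_person_years(path)
  expect_equal(back$days_employed, pop$days_employed)
  expect_equal(back$died_in_year, pop$died_in_year)
  expect_equal(classify_dataset(back)$state, classify_dataset(pop)$state)
})
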