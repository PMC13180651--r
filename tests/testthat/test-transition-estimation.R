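make_obs <- function(origin, destination, age, education = "mid",
                     gender = "men", weight = 1) {
  data.frame(origin = state_factor(origin), destination = state_factor(destination),
             age = age, gender = gender, education = education, weight = weight)
}

test_that("consecutive person-years pair into transition observations", {
  d <- rbind(person_year_row(1, 2005, 40, days = 360),
             person_year_row(1, 2006, 41, days = 355),
             person_year_row(1, 2007, 42, died = TRUE))
  obs <- build_transition_observations(classify_dataset(d))
  expect_equal(nrow(obs), 2L)
  expect_equal(as.character(obs$destination), c("full_year", "dead"))
  expect_equal(obs$age, c(40, 41))
})

test_that("censoring contributes a destination but never an origin", {
  d <- rbind(person_year_row(1, 2005, 40, days = 360),
             person_year_row(1, 2006, 41, days = 100, censored = TRUE))
  obs <- build_transition_observations(classify_dataset(d))
  expect_equal(nrow(obs), 1L)
  expect_equal(as.character(obs$destination), "mid_low")
  # gaps in years produce no observation
  d2 <- rbind(person_year_row(2, 2005, 40, days = 360),
              person_year_row(2, 2008, 43, days = 360))
  expect_equal(nrow(build_transition_observations(classify_dataset(d2))), 0L)
  # inconsistent age increments are rejected
  d3 <- rbind(person_year_row(3, 2005, 40, days = 360),
              person_year_row(3, 2006, 44, days = 360))
  expect_error(build_transition_observations(classify_dataset(d3)),
               "age does not increment")
})

test_that("observation count matches a brute-force pair count", {
  pop <- cached_population(2000, seed = 5)
  cl <- classify_dataset(pop)
  obs <- build_transition_observations(cl)
  brute <- 0L
  for (d in split(cl, cl$person_id)) {
    d <- d[order(d$year), ]
    if (nrow(d) < 2L) next
    for (i in seq_len(nrow(d) - 1L)) {
      if (d$year[i + 1L] == d$year[i] + 1L && d$state[i] != "dead" &&
          !d$censored_in_year[i])
        brute <- brute + 1L
    }
  }
  expect_equal(nrow(obs), brute)
  expect_false(any(obs$origin == "dead"))
})

test_that("with covariates saturated, fitted probabilities equal empirical frequencies", {
  # one origin, one covariate cell: the MLE is the count ratio
  obs <- make_obs("full_year",
                  rep(c("full_year", "mid_low", "unemp_inactive"), c(70, 20, 10)),
                  age = 50)
  model <- suppressWarnings(
    fit_transition_model(obs, "men", origins = "full_year",
                         ridge_lambda = 1e-10))
  P <- predict_matrix(model, 50, "mid")
  expect_equal(unname(P["full_year", c("full_year", "mid_low", "unemp_inactive")]),
               c(0.70, 0.20, 0.10), tolerance = 1e-6)
})

test_that("weighting an observation by k equals duplicating it k times", {
  pop <- cached_population(500, seed = 4)
  obs <- build_transition_observations(classify_dataset(pop))
  obs_m <- obs[as.character(obs$gender) == "men" &
                 as.character(obs$origin) == "full_year", ]
  dup <- rbind(obs_m, obs_m[seq(1, nrow(obs_m), 2), ])
  wts <- obs_m
  wts$weight <- ifelse(seq_len(nrow(obs_m)) %% 2 == 1, 2, 1)
  f_dup <- fit_transition_model(dup, "men", origins = "full_year",
                                ridge_lambda = 1e-8)
  f_wts <- fit_transition_model(wts, "men", origins = "full_year",
                                ridge_lambda = 1e-8)
  expect_equal(f_dup$fits$full_year$coef, f_wts$fits$full_year$coef,
               tolerance = 1e-7)
})

test_that("the Newton log-likelihood trace is non-decreasing", {
  pop <- cached_population(2000, seed = 5)
  fit <- suppressWarnings(wle(pop, ridge_lambda = 1e-6))
  for (g in names(fit$models)) for (f in fit$models[[g]]$fits) {
    expect_true(all(diff(f$diagnostics$loglik_trace) >= -1e-9))
    expect_true(f$diagnostics$converged)
  }
})

test_that("shifting the age centering leaves predicted matrices unchanged", {
  pop <- cached_population(2000, seed = 5)
  obs <- build_transition_observations(classify_dataset(pop))
  origins <- c("full_year", "unemp_inactive", "retired")
  m1 <- suppressWarnings(fit_transition_model(obs, "women", origins = origins))
  m2 <- suppressWarnings(fit_transition_model(obs, "women", origins = origins,
                                              age_center = 60, age_scale = 10))
  for (a in c(35, 60, 85))
    for (o in origins)
      expect_equal(predict_matrix(m1, a, "high")[o, ],
                   predict_matrix(m2, a, "high")[o, ], tolerance = 1e-8)
})

test_that("predicted matrices are row-stochastic with an absorbing dead row", {
  pop <- cached_population(2000, seed = 5)
  fit <- suppressWarnings(wle(pop, ridge_lambda = 1e-6))
  for (a in c(30, 57, 109)) for (e in education_levels()) {
    P <- predict(fit, age = a, gender = "men", education = e)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_identical(unname(P["dead", ]), c(0, 0, 0, 0, 0, 1))
  }
  expect_error(predict(fit, age = 110, gender = "men", education = "mid"),
               "outside the model grid")
})

test_that("masked transitions have probability exactly zero after renormalization", {
  pop <- cached_population(2000, seed = 5)
  obs <- build_transition_observations(classify_dataset(pop))
  mask <- worklife:::default_allowed_transitions()
  mask["retired", c("full_year", "mid_low")] <- FALSE
  obs <- obs[!(as.character(obs$origin) == "retired" &
                 as.character(obs$destination) %in% c("full_year", "mid_low")), ]
  model <- suppressWarnings(fit_transition_model(obs, "men", mask = mask,
                                                 ridge_lambda = 1e-6))
  P <- predict_matrix(model, 70, "mid")
  expect_identical(unname(P["retired", c("full_year", "mid_low")]), c(0, 0))
  expect_equal(sum(P["retired", ]), 1, tolerance = 1e-12)
})

test_that("never-observed destinations trigger a separation warning and zero probability", {
  obs <- make_obs("retired", rep(c("retired", "dead"), c(90, 10)),
                  age = rep(70:79, 10))
  expect_warning(
    model <- fit_transition_model(obs, "men", origins = "retired"),
    "separation")
  P <- predict_matrix(model, 75, "mid")
  expect_identical(unname(P["retired", "full_year"]), 0)
})

test_that("the fit agrees with an independent multinomial-logit implementation", {
  skip_if_not_installed("nnet")
  pop <- cached_population(2000, seed = 5)
  obs <- build_transition_observations(classify_dataset(pop))
  sub <- obs[as.character(obs$gender) == "men" &
               as.character(obs$origin) == "full_year", ]
  model <- fit_transition_model(sub, "men", origins = "full_year")
  z <- (sub$age - 70) / 10
  df <- data.frame(dest = factor(as.character(sub$destination)),
                   z = z, z2 = z^2, z3 = z^3,
                   edu = factor(as.character(sub$education),
                                levels = education_levels()))
  df$dest <- stats::relevel(df$dest, "full_year")
  ref <- nnet::multinom(dest ~ z + z2 + z3 + edu, df, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  newdata <- data.frame(z = (c(40, 55, 70) - 70) / 10)
  newdata$z2 <- newdata$z^2; newdata$z3 <- newdata$z^3
  newdata$edu <- factor("high", levels = education_levels())
  p_ref <- stats::predict(ref, newdata, type = "probs")
  for (k in 1:3) {
    P <- predict_matrix(model, c(40, 55, 70)[k], "high")
    for (d in colnames(p_ref))
      expect_equal(unname(P["full_year", d]), unname(p_ref[k, d]),
                   tolerance = 2e-4)
  }
})

test_that("transition models serialize to JSON and back without loss", {
  pop <- cached_population(2000, seed = 5)
  fit <- suppressWarnings(wle(pop, ridge_lambda = 1e-6))
  path <- tempfile(fileext = ".json")
  write_transition_model(fit$models$men, path)
  back <- read_transition_model(path)
  for (a in c(40, 70, 100))
    expect_equal(predict_matrix(back, a, "low"),
                 predict_matrix(fit$models$men, a, "low"), tolerance = 1e-12)
})
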