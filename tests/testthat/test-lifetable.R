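test_that("occupancy propagates the chain and conserves probability", {
  # identity living block with death only at terminal closure
  arr <- array(0, c(6, 6, 10))
  for (k in 1:10) arr[, , k] <- diag(6)
  mats <- transition_matrix_set(arr, 30:39)
  init <- c(0.4, 0.3, 0.2, 0.1, 0)
  occ <- occupancy(mats, init)
  expect_true(all(abs(sweep(occ$occupancy[, 1:5], 2, c(init), "-")) < 1e-12))
  # hand-iterated two-state chain: alive occupancy halves each year
  toy <- single_state_matrices(0.5, 30:32)
  occ2 <- occupancy(toy, c(1, 0, 0, 0, 0))
  expect_equal(unname(occ2$occupancy[, "full_year"]), c(1, 0.5, 0.25))
  # conservation and monotone dead mass on random sets
  set.seed(42)
  for (r in 1:10) {
    mats_r <- random_matrix_set(n_ages = sample(5:25, 1))
    init_r <- stats::rexp(5); init_r <- init_r / sum(init_r)
    occ_r <- occupancy(mats_r, init_r)
    expect_lt(max(abs(rowSums(occ_r$occupancy) - 1)), 1e-10)
    expect_true(all(diff(occ_r$occupancy[, "dead"]) >= -1e-12))
  }
})

test_that("invalid initial distributions and matrices are rejected", {
  toy <- single_state_matrices(0.5, 30:32)
  expect_error(occupancy(toy, c(0.5, 0, 0, 0, 0)), "summing to 1")
  expect_error(occupancy(toy, c(0.5, 0, 0, 0, 0, 0.5)), "dead")
  arr <- array(0, c(6, 6, 2))
  arr[, , 1] <- diag(6); arr[, , 2] <- diag(6)
  arr[2, 2, 2] <- 0.7  # break stochasticity for one row
  expect_error(transition_matrix_set(arr, 30:31), "mid_low")
})

test_that("the toy chain yields 1.75 expected years under interval-start exposure", {
  toy <- single_state_matrices(0.5, 30:32)
  et <- state_expectancies(toy, c(1, 0, 0, 0, 0))
  expect_equal(et$le_total, 1.75, tolerance = 1e-12)
  expect_equal(unname(et$e_state[["full_year"]]), 1.75, tolerance = 1e-12)
  # half-year death credit: each year's exposure shrinks by half the deaths
  et_half <- state_expectancies(toy, c(1, 0, 0, 0, 0), death_year_credit = 0.5)
  expect_equal(et_half$le_total, 0.75 * 1.75, tolerance = 1e-12)
})

test_that("constant-hazard chains match the closed-form geometric sum", {
  for (q in c(0.01, 0.1, 0.5)) {
    ages <- 30:109
    mats <- single_state_matrices(q, ages)
    et <- state_expectancies(mats, c(1, 0, 0, 0, 0))
    expect_equal(et$le_total, sum((1 - q)^(0:(length(ages) - 1L))),
                 tolerance = 1e-12)
  }
  # zero mortality: the full 80-year grid
  mats0 <- single_state_matrices(0, 30:109)
  expect_equal(state_expectancies(mats0, c(1, 0, 0, 0, 0))$le_total, 80,
               tolerance = 1e-12)
})

test_that("state expectancies are non-negative and sum to total LE", {
  set.seed(7)
  for (r in 1:10) {
    mats <- random_matrix_set(n_ages = sample(5:30, 1))
    init <- stats::rexp(5); init <- init / sum(init)
    et <- state_expectancies(mats, init)
    expect_true(all(et$e_state >= 0))
    expect_lt(abs(sum(et$e_state) - et$le_total), 1e-10)
    expect_lte(et$le_total, length(mats$ages) + 1e-12)
  }
})

test_that("raising death probabilities never increases total LE", {
  set.seed(11)
  for (r in 1:5) {
    mats <- random_matrix_set(n_ages = 20)
    worse <- mats$matrices
    for (k in seq_along(mats$ages)) {
      P <- worse[, , k]
      for (s in 1:5) {
        extra <- 0.5 * (1 - P[s, 6])
        P[s, 1:5] <- P[s, 1:5] * (1 - (P[s, 6] + extra)) / (1 - P[s, 6])
        P[s, 6] <- P[s, 6] + extra
      }
      worse[, , k] <- P
    }
    mats_w <- transition_matrix_set(worse, mats$ages)
    init <- rep(0.2, 5)
    expect_lte(state_expectancies(mats_w, init)$le_total,
               state_expectancies(mats, init)$le_total + 1e-10)
  }
})

test_that("a deterministic one-path Monte Carlo reproduces the exact path", {
  # forced cycle full_year -> mid_low -> full_year ... for 6 ages, then death
  arr <- array(0, c(6, 6, 6))
  for (k in 1:6) {
    P <- matrix(0, 6, 6)
    P[1, 2] <- 1; P[2, 1] <- 1
    for (s in 3:5) P[s, 6] <- 1
    P[6, 6] <- 1
    arr[, , k] <- P
  }
  mats <- transition_matrix_set(arr, 30:35)
  mc <- monte_carlo_expectancies(mats, c(1, 0, 0, 0, 0), n_paths = 1, seed = 1)
  expect_equal(unname(mc$e_state[["full_year"]]), 3)
  expect_equal(unname(mc$e_state[["mid_low"]]), 3)
  expect_equal(mc$le_total, 6)
})

test_that("Monte-Carlo expectancies agree with the closed form within 3 SE", {
  toy <- single_state_matrices(0.5, 30:32)
  mc <- monte_carlo_expectancies(toy, c(1, 0, 0, 0, 0), n_paths = 100000,
                                 seed = 9)
  expect_lt(abs(mc$e_state[["full_year"]] - 1.75),
            3 * max(mc$se[["full_year"]], 1e-6))
  # CLT scaling: doubling the paths shrinks the SE by about 1/sqrt(2)
  mc2 <- monte_carlo_expectancies(toy, c(1, 0, 0, 0, 0), n_paths = 200000,
                                  seed = 10)
  ratio <- mc2$se[["full_year"]] / mc$se[["full_year"]]
  expect_gt(ratio, (1 / sqrt(2)) * 0.8)
  expect_lt(ratio, (1 / sqrt(2)) * 1.2)
})

test_that("the observed starting-state mix is an empirical distribution", {
  d <- rbind(person_year_row(1:6, age = 30, days = 360),
             person_year_row(7:10, age = 30, days = 0))
  d$person_id <- 1:10
  cl <- classify_dataset(d)
  p <- unconditional_init_distribution(cl, "men", "mid", 30)
  expect_equal(unname(p), c(0.6, 0, 0.4, 0, 0))
  # no observations at the start age: explicit failure suggesting the window
  expect_error(unconditional_init_distribution(cl, "women", "mid", 30),
               "age_window")
  # pooled window picks up nearby ages
  d2 <- d; d2$age <- 31
  cl2 <- classify_dataset(d2)
  expect_error(unconditional_init_distribution(cl2, "men", "mid", 30))
  p2 <- unconditional_init_distribution(cl2, "men", "mid", 30, age_window = 2)
  expect_equal(unname(p2), c(0.6, 0, 0.4, 0, 0))
})

test_that("bootstrap with identity resampling reproduces the point estimate", {
  pop <- cached_population(2000, seed = 5)
  pop_m <- pop[pop$gender == "men", ]
  bt <- suppressWarnings(
    bootstrap_expectancies(pop_m, "men", "mid", B = 1, seed = 3,
                           identity_resample = TRUE, ridge_lambda = 1e-6))
  expect_equal(unname(bt$replicates[1, 1:5]), unname(bt$e_state),
               tolerance = 1e-6)
  expect_equal(unname(bt$replicates[1, 6]), bt$le_total, tolerance = 1e-6)
})

test_that("bootstrap intervals are reproducible under the same seed", {
  pop <- cached_population(2000, seed = 5)
  pop_m <- pop[pop$gender == "men", ]
  b1 <- suppressWarnings(bootstrap_expectancies(pop_m, "men", "mid", B = 15,
                                                seed = 7, ridge_lambda = 1e-6))
  b2 <- suppressWarnings(bootstrap_expectancies(pop_m, "men", "mid", B = 15,
                                                seed = 7, ridge_lambda = 1e-6))
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_identical(b1$replicates, b2$replicates)
})
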