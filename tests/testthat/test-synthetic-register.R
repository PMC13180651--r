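test_that("the packaged ground truth is deterministic and demographically sane", {
  t1 <- default_ground_truth()
  t2 <- default_ground_truth()
  expect_identical(t1, t2)
  # mortality rises with age from every origin, for every profile
  for (g in genders()) for (e in education_levels()) {
    m40 <- truth_matrices(t1, g, e, ages = 40)[40]
    m100 <- truth_matrices(t1, g, e, ages = 100)[100]
    expect_true(all(m100[1:5, "dead"] > m40[1:5, "dead"]))
  }
  # all implied rows are stochastic across the grid
  mats <- truth_matrices(t1, "men", "low")
  sums <- apply(mats$matrices, 3L, rowSums)
  expect_true(max(abs(sums - 1)) < 1e-12)
})

test_that("identical seeds give byte-identical simulated registers", {
  cfg <- sim_config(100, seed = 7)
  truth <- default_ground_truth()
  expect_identical(simulate_population(truth, cfg),
                   simulate_population(truth, cfg))
  # different seed gives different data
  expect_false(identical(simulate_population(truth, cfg),
                         simulate_population(truth, cfg, seed = 8)))
})

test_that("immediate absorption yields one living record plus one death record", {
  truth <- default_ground_truth()
  for (g in genders()) for (o in living_states()) {
    B <- truth$coef[[g]][[o]]
    B[, "intercept"] <- ifelse(rownames(B) == "dead", 40, -40)
    B[, 2:6] <- 0
    truth$coef[[g]][[o]] <- B
  }
  pop <- simulate_population(truth, sim_config(200, seed = 2))
  counts <- table(pop$person_id)
  expect_true(all(counts <= 2L))
  # everyone observed twice ends with the death record
  last <- pop[!duplicated(pop$person_id, fromLast = TRUE), ]
  expect_true(all(last$died_in_year[counts[as.character(last$person_id)] == 2L]))
})

test_that("generated panels satisfy the person-year invariants under random configs", {
  truth <- default_ground_truth()
  set.seed(31)
  for (r in 1:4) {
    cfg <- sim_config(300, seed = 30 + r,
                      gender_mix = as.vector(stats::rmultinom(1, 20, c(.5, .5))) / 20,
                      education_mix = as.vector(stats::rmultinom(1, 30, rep(1/3, 3))) / 30,
                      annual_censoring_probability = stats::runif(1, 0, 0.05),
                      staggered_entry = r %% 2 == 0)
    pop <- simulate_population(truth, cfg)
    expect_silent(validate_person_years(pop))
    cl <- classify_dataset(pop)
    # no gaps in years within an uncensored spell, no records after death
    ok_gap <- TRUE; ok_death <- TRUE
    for (idx in split(seq_len(nrow(cl)), cl$person_id)) {
      ok_gap <- ok_gap && all(diff(cl$year[idx]) == 1L)
      died <- which(cl$died_in_year[idx])
      if (length(died)) ok_death <- ok_death && identical(died, length(idx))
    }
    expect_true(ok_gap)
    expect_true(ok_death)
  }
})

test_that("empirical transition frequencies at age 50 match the truth matrices", {
  pop <- cached_population(20000, seed = 7)
  cl <- classify_dataset(pop)
  obs <- build_transition_observations(cl)
  truth <- default_ground_truth()
  sel <- obs$age == 50 & as.character(obs$gender) == "men" &
    as.character(obs$education) == "mid"
  sub <- obs[sel, ]
  P <- truth_matrices(truth, "men", "mid", ages = 50)[50]
  for (o in c("full_year", "unemp_inactive")) {
    rows <- sub[as.character(sub$origin) == o, ]
    n <- nrow(rows)
    expect_gt(n, 100)
    for (d in labor_states()) {
      phat <- mean(as.character(rows$destination) == d)
      p <- P[o, d]
      se <- sqrt(max(p * (1 - p), 1e-12) / n)
      expect_lt(abs(phat - p), 3 * se + 1e-9)
    }
  }
})

test_that("state prevalence by age converges to the chain's occupancy among the living", {
  pop <- cached_population(20000, seed = 7)
  cl <- classify_dataset(pop)
  truth <- default_ground_truth()
  occ <- occupancy(truth_matrices(truth, "women", "mid"),
                   truth$init30["women", "mid", ])
  l50 <- occ$occupancy["50", 1:5]
  l50 <- l50 / sum(l50)
  sel <- cl$age == 50 & cl$gender == "women" & cl$education == "mid" &
    cl$state != "dead"
  n <- sum(sel)
  expect_gt(n, 300)
  for (s in living_states()) {
    phat <- mean(cl$state[sel] == s)
    se <- sqrt(max(l50[s] * (1 - l50[s]), 1e-12) / n)
    expect_lt(abs(phat - l50[s]), 3 * se + 1e-9)
  }
})

test_that("truth-implied expectancies obey conservation and known limits", {
  truth <- default_ground_truth()
  # zero mortality until terminal closure: LE is the full grid length
  no_death <- truth
  for (g in genders()) for (o in living_states()) {
    B <- no_death$coef[[g]][[o]]
    B[rownames(B) == "dead", ] <- c(-60, 0, 0, 0, 0, 0)
    no_death$coef[[g]][[o]] <- B
  }
  et <- true_expectancies(no_death, "men", "mid")
  expect_equal(et$le_total, 80, tolerance = 1e-9)
  # conservation and the education gradient of the packaged defaults
  for (g in genders()) {
    lo <- true_expectancies(truth, g, "low")
    hi <- true_expectancies(truth, g, "high")
    expect_lt(abs(sum(lo$e_state) - lo$le_total), 1e-10)
    expect_gt(hi$le_total, lo$le_total)
    expect_gt(hi$e_state[["full_year"]], lo$e_state[["full_year"]])
  }
})

test_that("zeroing education effects removes the truth's education gaps", {
  null_truth <- default_ground_truth(education_effects = FALSE)
  lo <- true_expectancies(null_truth, "men", "low")
  hi <- true_expectancies(null_truth, "men", "high")
  expect_equal(lo$e_state, hi$e_state, tolerance = 1e-12)
})
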