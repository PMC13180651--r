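# Fixtures built in code: a ten-row person-year table spanning every
# classification rule (hand-derived expected states), toy transition-matrix
# sets, and cached synthetic populations shared across tests.

person_year_row <- function(person_id, year = 2005, age = 40, gender = "men",
                            education = "mid", days = 0, disability = FALSE,
                            old_age = FALSE, died = FALSE, censored = FALSE) {
  data.frame(person_id = person_id, year = year, age = age, gender = gender,
             education = education, days_employed = days,
             disability_pension = disability, old_age_pension = old_age,
             died_in_year = died, censored_in_year = censored)
}

# hand-classified: 2 full_year, 2 mid_low, 2 unemp_inactive, 2 disability,
# 1 retired, 1 dead; includes both day-count boundaries and death precedence
ten_row_fixture <- function() {
  rbind(
    person_year_row(1, days = 360),                       # full_year
    person_year_row(2, days = 351),                       # full_year (boundary)
    person_year_row(3, days = 350),                       # mid_low (boundary)
    person_year_row(4, days = 30),                        # mid_low (boundary)
    person_year_row(5, days = 29),                        # unemp_inactive
    person_year_row(6, days = 0),                         # unemp_inactive
    person_year_row(7, days = 200, disability = TRUE),    # disability
    person_year_row(8, days = 0, disability = TRUE),      # disability
    person_year_row(9, days = 340, old_age = TRUE),       # retired
    person_year_row(10, days = 300, died = TRUE))         # dead
}

ten_row_expected_counts <- c(full_year = 2L, mid_low = 2L,
                             unemp_inactive = 2L, disability = 2L,
                             retired = 1L, dead = 1L)

# single-living-state chain: full_year with constant death probability q;
# the other living states are emptied into death so rows stay stochastic
single_state_matrices <- function(q, ages) {
  P <- matrix(0, 6, 6, dimnames = list(labor_states(), labor_states()))
  P["full_year", "full_year"] <- 1 - q
  P["full_year", "dead"] <- q
  for (s in living_states()[-1]) P[s, "dead"] <- 1
  P["dead", "dead"] <- 1
  transition_matrix_set(array(rep(P, length(ages)), c(6, 6, length(ages))),
                        ages)
}

# random row-stochastic matrix set with all-positive living rows and a
# death probability bounded away from 0 so chains absorb
random_matrix_set <- function(n_ages = 15L, start_age = 30L,
                              min_death = 0.02) {
  arr <- array(0, c(6, 6, n_ages))
  for (k in seq_len(n_ages)) {
    M <- matrix(stats::rexp(30), 5, 6)
    M <- M / rowSums(M)
    M[, 6] <- min_death + (1 - min_death) * M[, 6]
    M <- M / rowSums(M)
    arr[1:5, , k] <- M
    arr[6, 6, k] <- 1
  }
  transition_matrix_set(arr, seq(start_age, start_age + n_ages - 1L))
}

# simulate once per (n, seed, preset) and reuse across tests
.pop_cache <- new.env(parent = emptyenv())
cached_population <- function(n, seed = 1L, preset = "default", ...) {
  key <- paste(n, seed, preset, ...)
  if (is.null(.pop_cache[[key]]))
    .pop_cache[[key]] <- simulate_population(
      default_ground_truth(preset), sim_config(n, seed = seed, ...))
  .pop_cache[[key]]
}
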