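#' Configuration of the synthetic register generator
#'
#' Bundles the population-level parameters of the generator. Defaults emulate
#' a register extract: a cross-section of adults aged 30-80 first observed in
#' 2005, followed through 2018, with a small annual outmigration (censoring)
#' hazard. Persons alive at the end of the window are administratively
#' truncated without a censoring flag.
#'
#' @param n_persons Number of persons to simulate.
#' @param seed Integer seed; can be overridden in [simulate_population()].
#' @param entry_year_range Observation window (calendar years).
#' @param entry_ages Range of ages at first observation (uniform draw).
#' @param gender_mix,education_mix Probability vectors (must sum to 1 within
#'   1e-12) over `genders()` and `education_levels()`.
#' @param initial_state_distribution Either `NULL` (default: the ground
#'   truth's baseline age-30 mix propagated to the entry age by the truth
#'   chain, conditional on being alive — so sample prevalence matches the
#'   chain's occupancy at every age) or a fixed probability vector over the
#'   five living states applied at entry regardless of age.
#' @param annual_censoring_probability Per-year outmigration probability.
#' @param return_probability Per-year probability that an outmigrated person
#'   re-enters observation (their state keeps evolving while unobserved, so
#'   re-entry produces a gap in years). Default 0.
#' @param staggered_entry If `TRUE`, entry years are drawn uniformly over the
#'   window instead of everyone entering at its start.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons, seed = 1L,
                       entry_year_range = c(2005L, 2018L),
                       entry_ages = c(30L, 80L),
                       gender_mix = c(men = 0.5, women = 0.5),
                       education_mix = c(low = 0.3, mid = 0.4, high = 0.3),
                       initial_state_distribution = NULL,
                       annual_censoring_probability = 0.005,
                       return_probability = 0,
                       staggered_entry = FALSE) {
  stopifnot(length(n_persons) == 1L)
  if (is.na(n_persons) || n_persons < 1) stop("n_persons must be >= 1", call. = FALSE)
  check_prob_vec <- function(p, k, what) {
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop(what, " must be a length-", k, " probability vector summing to 1",
           call. = FALSE)
  }
  check_prob_vec(gender_mix, 2L, "gender_mix")
  check_prob_vec(education_mix, 3L, "education_mix")
  if (!is.null(initial_state_distribution))
    check_prob_vec(initial_state_distribution, 5L, "initial_state_distribution")
  stopifnot(annual_censoring_probability >= 0, annual_censoring_probability <= 1,
            return_probability >= 0, return_probability <= 1,
            entry_year_range[1L] <= entry_year_range[2L],
            entry_ages[1L] >= 30L, entry_ages[1L] <= entry_ages[2L])
  structure(list(n_persons = as.integer(n_persons), seed = as.integer(seed),
                 entry_year_range = as.integer(entry_year_range),
                 entry_ages = as.integer(entry_ages),
                 gender_mix = gender_mix, education_mix = education_mix,
                 initial_state_distribution = initial_state_distribution,
                 annual_censoring_probability = annual_censoring_probability,
                 return_probability = return_probability,
                 staggered_entry = staggered_entry),
            class = "sim_config")
}

# occupancy of the truth chain conditional on being alive, per profile;
# rows = ages start_age..terminal_age-1, cols = living states
living_occupancy_profile <- function(truth, gender, education) {
  g <- genders()[as_gender_code(gender)]
  e <- education_levels()[as_education_code(education)]
  occ <- occupancy(truth_matrices(truth, g, e), truth$init30[g, e, ])
  L <- occ$occupancy[, 1:5, drop = FALSE]
  sw <- rowSums(L)
  sweep(L, 1L, sw, "/")
}

#' Simulate a register-like person-year panel
#'
#' Draws a synthetic longitudinal panel from a known ground-truth transition
#' model: per person a gender, education, entry age and initial living state,
#' then yearly state transitions from the truth's age-specific matrices until
#' death, outmigration, the terminal age, or the end of the observation
#' window. Each observed person-year is mapped back to raw register fields
#' (employment days drawn uniformly within the state's day interval, pension
#' flags, death/censoring indicators), so that [classify_dataset()] recovers
#' the generating state exactly. The year in which a person dies is emitted
#' as a final record with `died_in_year = TRUE`.
#'
#' @param truth A [default_ground_truth()] object.
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`. Identical seed and
#'   config give identical output.
#' @return A data frame of person-year records (see [classify_dataset()] for
#'   the schema).
#' @export
#' @examples
#' pop <- simulate_population(default_ground_truth(), sim_config(50, seed = 7))
#' head(pop)
simulate_population <- function(truth, config, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n_persons
  ages_grid <- seq(truth$start_age, truth$terminal_age - 1L)

  gender <- sample.int(2L, n, replace = TRUE, prob = config$gender_mix)
  education <- sample.int(3L, n, replace = TRUE, prob = config$education_mix)
  y0 <- config$entry_year_range[1L]
  y1 <- config$entry_year_range[2L]
  entry_year <- if (config$staggered_entry)
    y0 + sample.int(y1 - y0 + 1L, n, replace = TRUE) - 1L else rep(y0, n)
  entry_age <- config$entry_ages[1L] +
    sample.int(config$entry_ages[2L] - config$entry_ages[1L] + 1L, n,
               replace = TRUE) - 1L

  # per-profile transition arrays and entry-state distributions
  P <- vector("list", 6L)
  occ_alive <- vector("list", 6L)
  prof_id <- function(g, e) (g - 1L) * 3L + e
  for (g in 1:2) for (e in 1:3) {
    id <- prof_id(g, e)
    P[[id]] <- truth_matrices(truth, genders()[g], education_levels()[e])$matrices
    occ_alive[[id]] <- living_occupancy_profile(truth, g, e)
  }

  state <- integer(n)
  pid6 <- prof_id(gender, education)
  for (id in unique(pid6)) {
    idx <- which(pid6 == id)
    if (!is.null(config$initial_state_distribution)) {
      state[idx] <- sample.int(5L, length(idx), replace = TRUE,
                               prob = config$initial_state_distribution)
    } else {
      # inverse-cdf draw against each person's age-specific occupancy row
      OA <- occ_alive[[id]]
      u <- stats::runif(length(idx))
      arow <- match(entry_age[idx], ages_grid)
      s <- rep(5L, length(idx))
      acc <- rep(0, length(idx))
      remaining <- rep(TRUE, length(idx))
      for (k in 1:5) {
        acc <- acc + OA[cbind(arow, k)]
        hit <- remaining & (u <= acc + 1e-15)
        s[hit] <- k
        remaining <- remaining & !hit
      }
      state[idx] <- s
    }
  }

  alive <- rep(TRUE, n)
  observed <- rep(TRUE, n)   # FALSE after censoring (unless return migration)
  rows <- list()
  p_cens <- config$annual_censoring_probability
  p_ret <- config$return_probability

  for (year in y0:y1) {
    active <- alive & entry_year <= year
    age <- entry_age + (year - entry_year)
    # death/censor flags for this year's records
    died_now <- active & state == .DEAD
    emit <- active & observed
    cens_now <- rep(FALSE, n)
    if (p_cens > 0) {
      cand <- which(emit & !died_now)
      cens_now[cand] <- stats::runif(length(cand)) < p_cens
    }
    take <- which(emit)
    if (length(take)) {
      s <- state[take]
      days <- integer(length(take))
      for (k in 1:3) {
        idx <- which(s == k)
        if (!length(idx)) next
        rng <- switch(k, c(351L, 365L), c(30L, 350L), c(0L, 29L))
        days[idx] <- rng[1L] +
          sample.int(rng[2L] - rng[1L] + 1L, length(idx), replace = TRUE) - 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = take, year = year, age = age[take],
        gender = genders()[gender[take]],
        education = education_levels()[education[take]],
        days_employed = days,
        disability_pension = s == 4L, old_age_pension = s == 5L,
        died_in_year = s == .DEAD, censored_in_year = cens_now[take])
    }
    alive[died_now] <- FALSE
    observed[cens_now] <- FALSE
    if (p_ret > 0) {
      back <- which(active & !observed & !cens_now & alive)
      if (length(back))
        observed[back[stats::runif(length(back)) < p_ret]] <- TRUE
    }
    # evolve the chain for everyone still alive (observed or not)
    mov <- which(alive & entry_year <= year)
    if (length(mov) && year < y1) {
      nxt_dead <- mov[age[mov] + 1L >= truth$terminal_age]
      mov_ok <- setdiff(mov, nxt_dead)
      for (id in unique(pid6[mov_ok])) {
        idx <- mov_ok[pid6[mov_ok] == id]
        arr <- P[[id]]
        arow <- match(age[idx], ages_grid)
        probs <- matrix(0, length(idx), .N_STATES)
        flat <- as.vector(arr)
        base <- (arow - 1L) * .N_STATES * .N_STATES + state[idx]
        for (j in seq_len(.N_STATES))
          probs[, j] <- flat[base + (j - 1L) * .N_STATES]
        cum <- probs
        for (j in 2:.N_STATES) cum[, j] <- cum[, j - 1L] + cum[, j]
        u <- stats::runif(length(idx))
        nxt <- 1L + as.integer(rowSums(cum < u))
        state[idx] <- pmin(nxt, .N_STATES)
      }
      state[nxt_dead] <- .DEAD
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$person_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
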