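#' Marginal state occupancy of the discrete-time chain
#'
#' Propagates an initial distribution over the living states through the
#' age-indexed transition matrices: `l(x+1) = l(x) P(x)`. Occupancy is
#' reported at every grid age `start_age .. terminal_age - 1`; at
#' `terminal_age` the chain is closed (all remaining living mass absorbed)
#' and no exposure is credited.
#'
#' @param matrices A [transition_matrix_set()].
#' @param init_dist Probability vector over the five living states (or over
#'   all six with zero mass on dead) at `start_age`.
#' @param start_age First age of the trajectory; defaults to the grid start.
#' @return An object of class `occupancy_trajectory`: list with `ages` and
#'   an ages x 6 matrix `occupancy`, each row summing to 1.
#' @export
occupancy <- function(matrices, init_dist, start_age = matrices$start_age) {
  stopifnot(inherits(matrices, "transition_matrix_set"))
  l0 <- expand_init(init_dist)
  start_age <- as.integer(start_age)
  if (!start_age %in% matrices$ages)
    stop("start_age ", start_age, " not on the age grid", call. = FALSE)
  ages <- matrices$ages[matrices$ages >= start_age]
  occ <- matrix(0, length(ages), .N_STATES,
                dimnames = list(ages, labor_states()))
  l <- l0
  for (k in seq_along(ages)) {
    occ[k, ] <- l
    l <- as.vector(l %*% matrices[ages[k]])
  }
  structure(list(ages = ages, occupancy = occ,
                 terminal_age = matrices$terminal_age,
                 profile = matrices$profile),
            class = "occupancy_trajectory")
}

expand_init <- function(init_dist) {
  init_dist <- as.numeric(init_dist)
  if (length(init_dist) == 5L) init_dist <- c(init_dist, 0)
  if (length(init_dist) != .N_STATES)
    stop("init_dist must have length 5 (living states) or 6", call. = FALSE)
  if (any(init_dist < 0) || abs(sum(init_dist) - 1) > 1e-9)
    stop("init_dist must be a probability vector summing to 1", call. = FALSE)
  if (init_dist[.DEAD] != 0)
    stop("init_dist must place no mass on the dead state", call. = FALSE)
  init_dist / sum(init_dist)
}

#' @export
print.occupancy_trajectory <- function(x, digits = 4, ...) {
  cat("State occupancy over ages", x$ages[1L], "-", x$ages[length(x$ages)], "\n")
  print(round(utils::head(x$occupancy, 5L), digits))
  if (nrow(x$occupancy) > 5L) cat("... (", nrow(x$occupancy) - 5L, " more ages)\n")
  invisible(x)
}

new_expectancy_table <- function(e_state, start_age, profile = NULL,
                                 se = NULL, lower = NULL, upper = NULL,
                                 extra = list()) {
  stopifnot(length(e_state) == 5L)
  names(e_state) <- living_states()
  out <- c(list(e_state = e_state, le_total = sum(e_state),
                start_age = start_age, profile = profile,
                se = se, lower = lower, upper = upper), extra)
  structure(out, class = "expectancy_table")
}

#' State-specific expectancies from transition matrices
#'
#' Total life expectancy at `start_age` and its partition into expected years
#' in each living state, via the discrete-time Markov-chain approach: the
#' expectancy for state s is the sum over grid ages of the chain's occupancy
#' probability in s. One full year of exposure is credited to the state
#' occupied at the start of each yearly interval; `death_year_credit = 0.5`
#' instead credits half a year to intervals in which the occupant dies.
#'
#' @inheritParams occupancy
#' @param death_year_credit Exposure credited for person-years that end in
#'   death: `1` (default, interval-start convention) or `0.5`.
#' @return An object of class `expectancy_table`: per-state expectancies
#'   `e_state` (years), their sum `le_total`, plus metadata.
#' @export
#' @examples
#' # two-state toy chain: constant half-yearly survival over three ages
#' P <- diag(6); P["full_year", "full_year"] <- 0.5; P["full_year", "dead"] <- 0.5
#' for (s in living_states()[-1]) { P[s, s] <- 0; P[s, "dead"] <- 1 }
#' mats <- transition_matrix_set(array(rep(P, 3), c(6, 6, 3)), 30:32)
#' state_expectancies(mats, c(1, 0, 0, 0, 0))$le_total  # 1 + 0.5 + 0.25
state_expectancies <- function(matrices, init_dist,
                               start_age = matrices$start_age,
                               death_year_credit = 1) {
  stopifnot(death_year_credit %in% c(1, 0.5))
  occ <- occupancy(matrices, init_dist, start_age)
  L <- occ$occupancy[, 1:5, drop = FALSE]
  if (death_year_credit == 0.5) {
    # subtract half the exposure of intervals ending in death
    for (k in seq_along(occ$ages)) {
      P <- matrices[occ$ages[k]]
      L[k, ] <- L[k, ] * (1 - 0.5 * P[1:5, .DEAD])
    }
  }
  e_state <- colSums(L)
  new_expectancy_table(e_state, start_age, profile = matrices$profile)
}

#' @export
print.expectancy_table <- function(x, digits = 2, ...) {
  hdr <- paste0("Expectancies at age ", x$start_age)
  if (!is.null(x$profile))
    hdr <- paste0(hdr, " (", x$profile$gender, ", ", x$profile$education,
                  " education)")
  cat(hdr, "\n")
  tab <- data.frame(years = round(x$e_state, digits))
  if (!is.null(x$se)) tab$se <- round(x$se, digits)
  if (!is.null(x$lower)) { tab$lower <- round(x$lower, digits)
                           tab$upper <- round(x$upper, digits) }
  print(tab)
  cat("Total life expectancy:", round(x$le_total, digits), "years\n")
  invisible(x)
}

#' @export
as.data.frame.expectancy_table <- function(x, ...) {
  out <- data.frame(
    gender = if (is.null(x$profile)) NA_character_ else x$profile$gender,
    education = if (is.null(x$profile)) NA_character_ else x$profile$education,
    state = c(living_states(), "total"),
    years = c(unname(x$e_state), x$le_total))
  if (!is.null(x$se)) out$se <- c(unname(x$se), x$se_total %||% NA_real_)
  if (!is.null(x$lower)) {
    out$lower <- c(unname(x$lower), unname(x$lower_total %||% NA_real_))
    out$upper <- c(unname(x$upper), unname(x$upper_total %||% NA_real_))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo trajectory oracle for state expectancies
#'
#' Estimates the same expectancies as [state_expectancies()] by simulating
#' independent state trajectories through the transition matrices and
#' averaging the years each path spends in each state (same exposure
#' convention). Serves as an independent stochastic check on the matrix
#' computation; standard errors are across paths.
#'
#' @inheritParams state_expectancies
#' @param n_paths Number of simulated trajectories.
#' @param seed Integer seed for reproducibility.
#' @return An `expectancy_table` with Monte-Carlo standard errors (`se` per
#'   state, `se_total` for total LE).
#' @export
monte_carlo_expectancies <- function(matrices, init_dist,
                                     start_age = matrices$start_age,
                                     n_paths, seed = NULL,
                                     death_year_credit = 1) {
  stopifnot(n_paths >= 1, death_year_credit %in% c(1, 0.5))
  if (!is.null(seed)) set.seed(seed)
  l0 <- expand_init(init_dist)
  ages <- matrices$ages[matrices$ages >= as.integer(start_age)]
  state <- sample.int(.N_STATES, n_paths, replace = TRUE, prob = l0)
  years <- matrix(0, n_paths, 5L, dimnames = list(NULL, living_states()))
  for (age in ages) {
    P <- matrices[age]
    cum <- t(apply(P, 1L, cumsum))
    nxt <- state
    u <- stats::runif(n_paths)
    for (s in seq_len(.N_STATES - 1L)) {
      idx <- which(state == s)
      if (!length(idx)) next
      dest <- 1L + findInterval(u[idx], cum[s, ], left.open = TRUE)
      dest[dest > .N_STATES] <- .N_STATES
      nxt[idx] <- dest
      credit <- if (death_year_credit == 0.5)
        ifelse(dest == .DEAD, 0.5, 1) else 1
      years[idx, s] <- years[idx, s] + credit
    }
    state <- nxt
  }
  e_state <- colMeans(years)
  se <- apply(years, 2L, stats::sd) / sqrt(n_paths)
  tot <- rowSums(years)
  new_expectancy_table(e_state, as.integer(start_age),
                       profile = matrices$profile, se = se,
                       extra = list(se_total = stats::sd(tot) / sqrt(n_paths),
                                    n_paths = n_paths))
}

#' Observed starting-state distribution at the baseline age
#'
#' The unconditional expectancies average over the observed mix of living
#' states at the baseline age rather than conditioning on one starting state.
#' This returns that empirical distribution for one gender x education
#' profile.
#'
#' @param classified Classified person-year table (see [classify_dataset()]).
#' @param gender,education Profile selectors.
#' @param start_age Baseline age (default 30).
#' @param age_window Half-width of the pooling window around `start_age`;
#'   `0` uses the exact age only. If no rows fall in the window an error
#'   suggests widening it.
#' @return Named probability vector over the five living states.
#' @export
unconditional_init_distribution <- function(classified, gender, education,
                                            start_age = 30L, age_window = 0L) {
  stopifnot("state" %in% names(classified))
  g <- genders()[as_gender_code(gender)]
  e <- education_levels()[as_education_code(education)]
  sel <- as_gender_code(classified$gender) == as_gender_code(g) &
    as_education_code(classified$education) == as_education_code(e) &
    abs(classified$age - start_age) <= age_window &
    classified$state != "dead"
  if (!any(sel))
    stop("no living person-years at age ", start_age, " for profile (", g,
         ", ", e, "); consider a pooled-age fallback via age_window",
         call. = FALSE)
  tab <- table(factor(classified$state[sel], levels = living_states()))
  p <- as.numeric(tab) / sum(tab)
  names(p) <- living_states()
  p
}
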