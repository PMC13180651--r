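#' Labor-market state space
#'
#' The analysis distinguishes five mutually exclusive living states plus an
#' absorbing death state, assessed once per person per calendar year:
#'
#' * `full_year` — employed more than 350 days in the year;
#' * `mid_low` — employed between 30 and 350 days (closed interval);
#' * `unemp_inactive` — unemployed, inactive, or employed fewer than 30 days;
#' * `disability` — receiving a disability pension;
#' * `retired` — receiving an old-age pension;
#' * `dead` — died at any time during the year (absorbing).
#'
#' `labor_states()` returns all six state labels in their canonical order;
#' `living_states()` the five non-absorbing ones.
#'
#' @return Character vector of state labels.
#' @export
#' @examples
#' labor_states()
labor_states <- function() {
  c("full_year", "mid_low", "unemp_inactive", "disability", "retired", "dead")
}

#' @rdname labor_states
#' @export
living_states <- function() labor_states()[1:5]

# canonical integer codes; DEAD is always the last index
.STATES <- c(full_year = 1L, mid_low = 2L, unemp_inactive = 3L,
             disability = 4L, retired = 5L, dead = 6L)
.N_STATES <- 6L
.DEAD <- 6L

#' Education levels
#'
#' Highest degree obtained, time-invariant per person, in three groups
#' following the ISCED 2011 classification: `low` (ISCED 0-2), `mid`
#' (ISCED 3-4), `high` (ISCED 5-8).
#'
#' @return Character vector `c("low", "mid", "high")`.
#' @export
education_levels <- function() c("low", "mid", "high")

#' @rdname education_levels
#' @export
genders <- function() c("men", "women")

state_factor <- function(x) {
  factor(x, levels = labor_states())
}

as_state_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L | x > .N_STATES))
      stop("state codes must be integers in 1..6", call. = FALSE)
    return(x)
  }
  code <- .STATES[match(as.character(x), names(.STATES))]
  if (any(is.na(code)))
    stop("unknown state label(s): ",
         paste(unique(setdiff(as.character(x), names(.STATES))), collapse = ", "),
         call. = FALSE)
  unname(code)
}

as_education_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L | x > 3L))
      stop("education codes must be integers in 1..3", call. = FALSE)
    return(x)
  }
  code <- match(as.character(x), education_levels())
  if (any(is.na(code)))
    stop("unknown education level(s): ",
         paste(unique(setdiff(as.character(x), education_levels())), collapse = ", "),
         call. = FALSE)
  code
}

as_gender_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L | x > 2L))
      stop("gender codes must be integers in 1..2", call. = FALSE)
    return(x)
  }
  code <- match(as.character(x), genders())
  if (any(is.na(code)))
    stop("unknown gender label(s): ",
         paste(unique(setdiff(as.character(x), genders())), collapse = ", "),
         call. = FALSE)
  code
}
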