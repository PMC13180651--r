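#' Build one-step transition observations from classified person-years
#'
#' Pairs consecutive person-years of the same person (year t and t+1, ages x
#' and x+1) into origin -> destination transition observations. Pairs broken
#' by censoring, the end of the observation window, or gaps in years yield no
#' observation; a censored year still serves as a destination but never as an
#' origin, and the dead state is never an origin.
#'
#' @param classified Classified person-year table from [classify_dataset()].
#' @param keep_person If `TRUE`, the output carries a `person_id` column
#'   (used by the clustered bootstrap).
#' @return Data frame with columns `origin`, `destination` (factors over
#'   [labor_states()]), `age` (origin age), `gender`, `education`, `weight`.
#' @export
build_transition_observations <- function(classified, keep_person = FALSE) {
  stopifnot(is.data.frame(classified), "state" %in% names(classified))
  d <- classified[order(classified$person_id, classified$year), , drop = FALSE]
  n <- nrow(d)
  if (n < 2L) {
    out <- data.frame(origin = state_factor(character()),
                      destination = state_factor(character()),
                      age = integer(), gender = character(),
                      education = character(), weight = numeric())
    if (keep_person) out$person_id <- d$person_id[0]
    return(out)
  }
  i <- seq_len(n - 1L)
  j <- i + 1L
  pair <- d$person_id[i] == d$person_id[j] & d$year[j] - d$year[i] == 1L
  bad_age <- pair & (d$age[j] - d$age[i] != 1L)
  if (any(bad_age))
    stop("age does not increment by 1 across a consecutive-year pair ",
         "(person ", d$person_id[i][which(bad_age)[1L]], ", year ",
         d$year[i][which(bad_age)[1L]], ")", call. = FALSE)
  keep <- pair & d$state[i] != "dead" & !as.logical(d$censored_in_year[i])
  i <- i[keep]; j <- j[keep]
  out <- data.frame(origin = d$state[i], destination = d$state[j],
                    age = d$age[i], gender = d$gender[i],
                    education = d$education[i], weight = rep(1, length(i)))
  if (keep_person) out$person_id <- d$person_id[i]
  out
}
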