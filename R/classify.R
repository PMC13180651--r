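#' Default precedence of classification rules
#'
#' Death always dominates. Among living states the source definitions call the
#' states "mutually exclusive" but do not fix which rule wins when a pension
#' flag co-occurs with 30+ employment days; here pension receipt defines the
#' exit states, so the default order is death, then old-age pension, then
#' disability pension, then the employment-day rules.
#'
#' @return Character vector of rule labels in decreasing precedence.
#' @export
default_precedence <- function() c("dead", "retired", "disability", "days")

#' Classify person-years into labor-market states
#'
#' Applies the deterministic state-assignment rules to raw person-year fields.
#' A person-year is `dead` whenever the death indicator is set (regardless of
#' precedence); otherwise the first matching rule under `precedence` wins.
#' The employment-day rules are: more than 350 days -> `full_year`;
#' 30 to 350 days (closed interval) -> `mid_low`; fewer than 30 days ->
#' `unemp_inactive`.
#'
#' @param days_employed Integer vector, days employed in the year, in 0..366.
#' @param disability_pension,old_age_pension,died_in_year Logical vectors.
#' @param precedence Rule ordering, see [default_precedence()]. `"dead"` is
#'   always promoted to the front if misplaced.
#' @return Factor of states with levels [labor_states()].
#' @seealso [classify_dataset()] for the table-level interface with schema
#'   validation.
#' @export
#' @examples
#' classify_states(c(360, 350, 10), FALSE, FALSE, FALSE)
classify_states <- function(days_employed, disability_pension = FALSE,
                            old_age_pension = FALSE, died_in_year = FALSE,
                            precedence = default_precedence()) {
  n <- length(days_employed)
  disability_pension <- rep_len(as.logical(disability_pension), n)
  old_age_pension <- rep_len(as.logical(old_age_pension), n)
  died_in_year <- rep_len(as.logical(died_in_year), n)
  if (any(is.na(days_employed)) || any(days_employed < 0) || any(days_employed > 366))
    stop("days_employed must lie in [0, 366]", call. = FALSE)
  precedence <- match.arg(precedence, default_precedence(), several.ok = TRUE)
  if (!"dead" %in% precedence || precedence[1L] != "dead")
    precedence <- c("dead", setdiff(precedence, "dead"))
  if (!all(c("retired", "disability", "days") %in% precedence))
    stop("precedence must contain rules 'dead', 'retired', 'disability', 'days'",
         call. = FALSE)

  out <- integer(n)
  unassigned <- rep(TRUE, n)
  for (rule in precedence) {
    hit <- switch(rule,
      dead = died_in_year,
      retired = old_age_pension,
      disability = disability_pension,
      days = rep(TRUE, n))
    take <- unassigned & hit
    if (rule == "days") {
      d <- days_employed[take]
      out[take] <- ifelse(d > 350, .STATES[["full_year"]],
                   ifelse(d >= 30, .STATES[["mid_low"]],
                          .STATES[["unemp_inactive"]]))
    } else {
      out[take] <- .STATES[[switch(rule, dead = "dead", retired = "retired",
                                   disability = "disability")]]
    }
    unassigned <- unassigned & !take
  }
  factor(labor_states()[out], levels = labor_states())
}

person_year_columns <- function() {
  c("person_id", "year", "age", "gender", "education", "days_employed",
    "disability_pension", "old_age_pension", "died_in_year", "censored_in_year")
}

#' Validate a person-year table
#'
#' Checks the schema and row-level invariants of raw person-year records:
#' required columns present, `days_employed` in 0..366, `age >= 30`, death and
#' censoring not flagged together, no duplicate (person, year) pairs, and no
#' records after a death record.
#'
#' @param data A data frame of person-year records.
#' @return Invisibly, a validation report: a list with `n_rows`, `n_persons`,
#'   and a data frame `rejected` (row index, field, reason); empty when the
#'   table is valid.
#' @param strict If `TRUE` (default) any violation is an error; otherwise the
#'   report is returned with the offending rows listed.
#' @export
validate_person_years <- function(data, strict = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(person_year_columns(), names(data))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  bad <- list()
  note <- function(idx, field, reason) {
    if (length(idx))
      bad[[length(bad) + 1L]] <<- data.frame(row = idx, field = field,
                                             reason = reason)
  }
  note(which(is.na(data$days_employed) | data$days_employed < 0 |
               data$days_employed > 366),
       "days_employed", "outside [0, 366]")
  note(which(is.na(data$age) | data$age < 30), "age", "below start age 30")
  note(which(as.logical(data$died_in_year) & as.logical(data$censored_in_year)),
       "died_in_year/censored_in_year", "both flagged in the same record")

  key <- paste(data$person_id, data$year, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    offenders <- unique(paste0("(", data$person_id[dup], ", ", data$year[dup], ")"))
    note(which(dup), "person_id/year",
         paste0("duplicate person-year pair ",
                paste(offenders, collapse = ", ")))
  }

  ord <- order(data$person_id, data$year)
  pid <- data$person_id[ord]
  died <- as.logical(data$died_in_year)[ord]
  same <- pid[-1L] == pid[-length(pid)]
  if (length(pid) > 1L) {
    after_death <- which(same & died[-length(died)])
    note(ord[after_death + 1L], "died_in_year", "record after a death record")
  }

  rejected <- if (length(bad)) do.call(rbind, bad) else
    data.frame(row = integer(), field = character(), reason = character())
  report <- list(n_rows = nrow(data),
                 n_persons = length(unique(data$person_id)),
                 rejected = rejected)
  if (strict && nrow(rejected))
    stop("invalid person-year records (", nrow(rejected), " violation(s)); ",
         "first: row ", rejected$row[1L], ", field ", rejected$field[1L], ": ",
         rejected$reason[1L], call. = FALSE)
  invisible(report)
}

#' Classify a person-year table
#'
#' Validates `data` against the person-year schema and appends the classified
#' labor-market `state` column. Row count and per-person chronological order
#' are preserved.
#'
#' @inheritParams validate_person_years
#' @inheritParams classify_states
#' @return `data` with an added factor column `state`.
#' @export
#' @examples
#' df <- data.frame(person_id = 1, year = 2005:2006, age = 40:41,
#'                  gender = "men", education = "mid",
#'                  days_employed = c(365, 100), disability_pension = FALSE,
#'                  old_age_pension = FALSE, died_in_year = FALSE,
#'                  censored_in_year = FALSE)
#' classify_dataset(df)$state
classify_dataset <- function(data, precedence = default_precedence()) {
  validate_person_years(data, strict = TRUE)
  data$state <- classify_states(data$days_employed, data$disability_pension,
                                data$old_age_pension, data$died_in_year,
                                precedence = precedence)
  data
}
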