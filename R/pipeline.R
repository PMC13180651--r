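#' Prevalence of states by age class
#'
#' Cross-sectional percentages of person-years in each living state within
#' age classes, by gender — the layout of published multistate descriptive
#' tables. Death records are events, not occupied years, and are excluded.
#'
#' @param classified Classified person-year table.
#' @param breaks Lower bounds of the age classes (the last class is open).
#' @param by_education If `TRUE`, rows are gender x education x age class.
#' @param digits Rounding for the percentage columns (1 decimal by default;
#'   `NULL` for full precision).
#' @return Data frame with one row per (group, age class): percentage per
#'   state and a `total` column; each row's states sum to 100 within
#'   rounding.
#' @export
prevalence_by_ageclass <- function(classified, breaks = c(30, 50, 65),
                                   by_education = FALSE, digits = 1) {
  stopifnot("state" %in% names(classified))
  d <- classified[classified$state != "dead", , drop = FALSE]
  labs <- paste0(breaks, "-", c(breaks[-1L] - 1L, ""))
  labs[length(labs)] <- paste0(breaks[length(breaks)], "+")
  d$age_class <- labs[findInterval(d$age, breaks)]
  keys <- list(gender = genders()[as_gender_code(d$gender)])
  if (by_education)
    keys$education <- education_levels()[as_education_code(d$education)]
  keys$age_class <- factor(d$age_class, levels = labs)
  groups <- do.call(interaction, c(keys, drop = TRUE, lex.order = TRUE))
  out <- list()
  for (grp in levels(groups)) {
    sel <- groups == grp
    if (!any(sel)) {
      warning("empty prevalence cell: ", grp, call. = FALSE)
      next
    }
    tab <- table(factor(d$state[sel], levels = living_states()))
    pct <- 100 * as.numeric(tab) / sum(tab)
    if (!is.null(digits)) pct <- round_to_sum(pct, digits, 100)
    parts <- strsplit(grp, ".", fixed = TRUE)[[1L]]
    row <- data.frame(gender = parts[1L])
    if (by_education) row$education <- parts[2L]
    row$age_class <- parts[length(parts)]
    row <- cbind(row, as.data.frame(as.list(stats::setNames(pct, living_states()))))
    row$total <- sum(pct)
    out[[length(out) + 1L]] <- row
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# largest-remainder rounding: the rounded values keep their target sum
round_to_sum <- function(x, digits, target) {
  scale <- 10^digits
  v <- floor(x * scale)
  short <- round(target * scale - sum(v))
  if (short > 0) {
    take <- order(x * scale - v, decreasing = TRUE)[seq_len(short)]
    v[take] <- v[take] + 1
  }
  v / scale
}

#' Relative state expectancies
#'
#' Each state's expectancy expressed as a share of total life expectancy.
#'
#' @param table An `expectancy_table`.
#' @return Named numeric vector of shares over the five living states,
#'   summing to 1.
#' @export
relative_expectancies <- function(table) {
  stopifnot(inherits(table, "expectancy_table"))
  if (table$le_total <= 0)
    stop("total life expectancy must be positive", call. = FALSE)
  table$e_state / table$le_total
}

#' Education and gender gaps in expectancies
#'
#' Differences of expectancy-table entries across the educational extremes
#' (high minus low, within gender) and across gender (women minus men,
#' within education), per state and for total LE.
#'
#' @param expectancies Named list of `expectancy_table`s indexed
#'   `"<gender>.<education>"` (as produced by [run_study()]).
#' @return Data frame with columns `contrast`, `within`, state gaps and
#'   `le_total` gap (years).
#' @export
gap_summary <- function(expectancies) {
  get <- function(g, e) expectancies[[paste(g, e, sep = ".")]]
  rows <- list()
  for (g in genders()) {
    hi <- get(g, "high"); lo <- get(g, "low")
    if (is.null(hi) || is.null(lo)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = "education_high_minus_low", within = g,
      as.data.frame(as.list(hi$e_state - lo$e_state)),
      le_total = hi$le_total - lo$le_total)
  }
  for (e in education_levels()) {
    w <- get("women", e); m <- get("men", e)
    if (is.null(w) || is.null(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = "gender_women_minus_men", within = e,
      as.data.frame(as.list(w$e_state - m$e_state)),
      le_total = w$le_total - m$le_total)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for a full multistate study
#'
#' @param input A person-year data frame, a path to a person-year CSV, or
#'   `NULL` to simulate from `truth`/`sim` below.
#' @param truth A [default_ground_truth()] (used when `input` is `NULL`).
#' @param sim A [sim_config()] (used when `input` is `NULL`).
#' @param start_age,terminal_age Life-table age grid.
#' @param precedence Classification precedence.
#' @param mask Structural-zero transition mask or `NULL`.
#' @param ridge_lambda Ridge penalty for the transition fits.
#' @param bootstrap_B Bootstrap replicates for interval estimation
#'   (0 = point estimates only).
#' @param age_window Pooling window for starting-state mixes.
#' @param seed Master seed for simulation and bootstrap.
#' @param output_dir Directory for CSV/JSON outputs, or `NULL` to skip
#'   writing.
#' @return A list of class `study_config`.
#' @export
study_config <- function(input = NULL, truth = default_ground_truth(),
                         sim = sim_config(50000L), start_age = 30L,
                         terminal_age = 110L,
                         precedence = default_precedence(), mask = NULL,
                         ridge_lambda = 0, bootstrap_B = 0L, age_window = 2L,
                         seed = 1L, output_dir = NULL) {
  stopifnot(start_age < terminal_age)
  structure(list(input = input, truth = truth, sim = sim,
                 start_age = as.integer(start_age),
                 terminal_age = as.integer(terminal_age),
                 precedence = precedence, mask = mask,
                 ridge_lambda = ridge_lambda,
                 bootstrap_B = as.integer(bootstrap_B),
                 age_window = as.integer(age_window),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

#' Run the full multistate working-life study
#'
#' Orchestrates the end-to-end analysis: obtain person-year data (given or
#' simulated), classify states, fit gender-stratified transition models,
#' and compute expectancy tables for every gender x education profile,
#' together with the descriptive prevalence table, relative expectancies,
#' gap summaries and a provenance manifest with row counts per stage. Fully
#' deterministic given the configuration seed.
#'
#' @param config A [study_config()].
#' @return An object of class `wle_study`: list with `fit` (the [wle()]
#'   object), `expectancies` (named list per profile), `prevalence`, `gaps`,
#'   `relative` (share matrix), optional `bootstrap`, and `manifest`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("study stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  data <- stage("input", {
    if (is.null(config$input))
      simulate_population(config$truth, config$sim, seed = config$seed)
    else if (is.character(config$input)) read_person_years(config$input)
    else config$input
  })
  classified <- stage("classify",
                      classify_dataset(data, precedence = config$precedence))
  fit <- stage("estimate",
               wle(classified, start_age = config$start_age,
                   terminal_age = config$terminal_age, mask = config$mask,
                   ridge_lambda = config$ridge_lambda))
  expectancies <- list()
  for (g in names(fit$models)) for (e in education_levels()) {
    expectancies[[paste(g, e, sep = ".")]] <- stage(
      paste0("expectancy ", g, ".", e),
      life_expectancy(fit, g, e, age_window = config$age_window))
  }
  prevalence <- stage("prevalence", prevalence_by_ageclass(classified))
  gaps <- stage("gaps", gap_summary(expectancies))
  rel <- t(vapply(expectancies, relative_expectancies, numeric(5L)))
  boot <- NULL
  if (config$bootstrap_B > 0L) {
    boot <- list()
    for (g in names(fit$models)) for (e in education_levels()) {
      boot[[paste(g, e, sep = ".")]] <- stage(
        paste0("bootstrap ", g, ".", e),
        bootstrap_expectancies(classified, g, e, B = config$bootstrap_B,
                               seed = config$seed,
                               age_window = config$age_window,
                               ridge_lambda = config$ridge_lambda))
    }
  }
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("worklife")),
    n_input_rows = nrow(data), n_classified_rows = nrow(classified),
    n_persons = length(unique(classified$person_id)),
    n_transition_observations = fit$n_observations,
    start_age = config$start_age, terminal_age = config$terminal_age,
    precedence = config$precedence, ridge_lambda = config$ridge_lambda,
    simulated = is.null(config$input),
    preset = if (is.null(config$input)) config$truth$preset else NA_character_)
  out <- structure(list(fit = fit, expectancies = expectancies,
                        prevalence = prevalence, gaps = gaps, relative = rel,
                        bootstrap = boot, manifest = manifest,
                        config = config),
                   class = "wle_study")
  if (!is.null(config$output_dir)) write_study(out, config$output_dir)
  out
}

#' @export
print.wle_study <- function(x, ...) {
  cat("Multistate working-life study (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  person-years:", x$manifest$n_classified_rows,
      " transitions:", x$manifest$n_transition_observations, "\n")
  tab <- do.call(rbind, lapply(x$expectancies, function(e)
    round(c(e$e_state, total = e$le_total), 1)))
  print(tab)
  invisible(x)
}

#' Stacked-bar view of a study's expectancy tables: for each gender x
#' education profile, total LE at the baseline age partitioned into the five
#' state expectancies.
#'
#' @param x A [run_study()] result.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.wle_study <- function(x, ...) {
  tab <- vapply(x$expectancies, function(e) e$e_state, numeric(5L))
  cols <- c("#1b9e77", "#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3")
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(tab, col = cols, las = 2,
                    ylab = paste("Years from age", x$manifest$start_age),
                    legend.text = living_states(),
                    args.legend = list(x = "topleft", bg = "white", cex = 0.7),
                    ...)
  invisible(x)
}

#' Write study outputs to disk
#'
#' Expectancies (tidy CSV), prevalence table, gap summary, relative shares,
#' per-gender model JSONs and the provenance manifest.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "wle_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exp_df <- do.call(rbind, lapply(study$expectancies, as.data.frame))
  utils::write.csv(exp_df, file.path(dir, "expectancies.csv"),
                   row.names = FALSE)
  utils::write.csv(study$prevalence, file.path(dir, "prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(study$gaps, file.path(dir, "gaps.csv"), row.names = FALSE)
  utils::write.csv(data.frame(profile = rownames(study$relative),
                              study$relative, check.names = FALSE),
                   file.path(dir, "relative_expectancies.csv"),
                   row.names = FALSE)
  for (g in names(study$fit$models))
    write_transition_model(study$fit$models[[g]],
                           file.path(dir, paste0("model_", g, ".json")))
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Parameter-recovery experiment
#'
#' Simulates from a known ground truth, runs the full pipeline, and
#' tabulates per-profile bias (and RMSE across replicates) of every state
#' expectancy and total LE against the truth-implied values.
#'
#' @param truth A [default_ground_truth()].
#' @param sim A [sim_config()].
#' @param n_replicates Number of simulation replicates.
#' @param seed Master seed (replicate r uses `seed + r - 1`).
#' @param age_window Pooling window for starting-state mixes.
#' @return List with `errors` (long data frame: replicate, profile, state,
#'   error in years) and `summary` (bias and RMSE per profile x state).
#' @export
recovery_experiment <- function(truth = default_ground_truth(),
                                sim = sim_config(50000L), n_replicates = 1L,
                                seed = 1L, age_window = 2L) {
  stopifnot(n_replicates >= 1L)
  truth_tabs <- list()
  for (g in genders()) for (e in education_levels())
    truth_tabs[[paste(g, e, sep = ".")]] <- true_expectancies(truth, g, e)
  errors <- list()
  for (r in seq_len(n_replicates)) {
    study <- run_study(study_config(truth = truth, sim = sim,
                                    seed = as.integer(seed) + r - 1L,
                                    age_window = age_window))
    for (prof in names(truth_tabs)) {
      est <- study$expectancies[[prof]]
      tr <- truth_tabs[[prof]]
      errors[[length(errors) + 1L]] <- data.frame(
        replicate = r, profile = prof,
        state = c(living_states(), "total"),
        error = c(est$e_state - tr$e_state, est$le_total - tr$le_total))
    }
  }
  errors <- do.call(rbind, errors)
  agg_bias <- stats::aggregate(error ~ profile + state, errors, mean)
  agg_rmse <- stats::aggregate(error ~ profile + state, errors,
                               function(x) sqrt(mean(x^2)))
  summary <- merge(agg_bias, agg_rmse, by = c("profile", "state"),
                   suffixes = c("_bias", "_rmse"))
  names(summary)[3:4] <- c("bias", "rmse")
  list(errors = errors, summary = summary)
}
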