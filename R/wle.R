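#' Fit a multistate working-life model
#'
#' The main entry point of the package: takes a long-format person-year table
#' (raw register fields, or already classified with a `state` column),
#' classifies each person-year into one of five living labor-market states or
#' death, builds one-step transition observations, and fits gender-stratified
#' multinomial logistic transition models with a cubic age polynomial and
#' education contrasts. The fitted object supports prediction of
#' age-specific transition matrices, state-occupancy plots, simulation of
#' synthetic registers from the fitted transition model, and downstream life
#' expectancy partitioning via [life_expectancy()].
#'
#' @param data Data frame of person-year records (see
#'   [classify_dataset()] for the schema), or an already classified table.
#' @param precedence Classification rule precedence, see
#'   [default_precedence()].
#' @param start_age,terminal_age Age grid of the life table; transition
#'   matrices are defined for ages `start_age .. terminal_age - 1` and the
#'   table is closed at `terminal_age`.
#' @param age_center,age_scale Centering/scaling of the age covariate.
#' @param ridge_lambda L2 penalty on non-intercept coefficients.
#' @param mask Optional structural-zero transition mask.
#' @param max_iter,tol Newton controls, see [fit_transition_model()].
#' @param genders_fit Genders to fit (default those present in the data).
#' @return An object of class `wle`: list with `models` (one
#'   `transition_model` per gender), the `classified` person-year table,
#'   and the configuration. Methods: `print`, `summary`, `coef`, `predict`,
#'   `simulate`, `residuals`, `logLik`, `plot`.
#' @seealso [life_expectancy()], [run_study()]
#' @export
#' @examples
#' pop <- simulate_population(default_ground_truth(), sim_config(400, seed = 1))
#' fit <- wle(pop, ridge_lambda = 1e-4)
#' fit
wle <- function(data, precedence = default_precedence(),
                start_age = 30L, terminal_age = 110L,
                age_center = 70, age_scale = 10,
                ridge_lambda = 0, mask = NULL,
                max_iter = 200L, tol = 1e-10, genders_fit = NULL) {
  stopifnot(start_age < terminal_age)
  classified <- if ("state" %in% names(data)) data else
    classify_dataset(data, precedence = precedence)
  observations <- build_transition_observations(classified)
  if (is.null(genders_fit))
    genders_fit <- genders()[sort(unique(as_gender_code(classified$gender)))]
  ages <- seq(as.integer(start_age), as.integer(terminal_age) - 1L)
  models <- lapply(genders_fit, function(g)
    fit_transition_model(observations, g, mask = mask, ages = ages,
                         age_center = age_center, age_scale = age_scale,
                         ridge_lambda = ridge_lambda, max_iter = max_iter,
                         tol = tol))
  names(models) <- genders_fit
  structure(list(models = models, classified = classified,
                 n_observations = nrow(observations),
                 start_age = as.integer(start_age),
                 terminal_age = as.integer(terminal_age),
                 age_center = age_center, age_scale = age_scale,
                 ridge_lambda = ridge_lambda, precedence = precedence,
                 call = match.call()),
            class = "wle")
}

#' @export
print.wle <- function(x, ...) {
  cat("Multistate working-life model\n")
  cat("  person-years:", nrow(x$classified),
      " persons:", length(unique(x$classified$person_id)),
      " transitions:", x$n_observations, "\n")
  cat("  age grid:", x$start_age, "-", x$terminal_age - 1L,
      "(closed at", paste0(x$terminal_age, ")"), "\n")
  for (g in names(x$models)) print(x$models[[g]])
  invisible(x)
}

#' @export
summary.wle <- function(object, level = 0.95, ...) {
  tabs <- do.call(rbind, lapply(object$models, coef_table, level = level))
  rownames(tabs) <- NULL
  tabs$z <- tabs$estimate / tabs$se
  tabs$p_value <- 2 * stats::pnorm(-abs(tabs$z))
  structure(list(coefficients = tabs, n_observations = object$n_observations,
                 logLik = as.numeric(logLik(object))),
            class = "summary.wle")
}

#' @export
print.summary.wle <- function(x, ...) {
  cat("Coefficient table (", nrow(x$coefficients), " rows); log-likelihood ",
      format(x$logLik), "\n", sep = "")
  print(utils::head(x$coefficients, 12L), digits = 3)
  if (nrow(x$coefficients) > 12L)
    cat("... (", nrow(x$coefficients) - 12L, " more rows)\n")
  invisible(x)
}

#' @export
coef.wle <- function(object, ...) {
  lapply(object$models, model_coef_list)
}

#' @export
logLik.wle <- function(object, ...) {
  ll <- sum(vapply(object$models, function(m)
    sum(vapply(m$fits, function(f) f$diagnostics$loglik, 0)), 0))
  df <- sum(vapply(object$models, function(m)
    sum(vapply(m$fits, function(f) length(f$coef), 0L)), 0L))
  structure(ll, df = df, class = "logLik")
}

#' Predict transition probabilities from a fitted model
#'
#' @param object A [wle()] fit.
#' @param age Single age (with `type = "matrix"`) or ignored for
#'   `type = "set"`.
#' @param gender,education Covariate profile.
#' @param type `"matrix"` for one 6x6 matrix at `age`; `"set"` for the full
#'   [transition_matrix_set()] over the age grid.
#' @param ... Unused.
#' @return A 6x6 matrix or a `transition_matrix_set`.
#' @export
predict.wle <- function(object, age = NULL, gender, education,
                        type = c("matrix", "set"), ...) {
  type <- match.arg(type)
  g <- genders()[as_gender_code(gender)]
  model <- object$models[[g]]
  if (is.null(model)) stop("no fitted model for gender '", g, "'", call. = FALSE)
  if (type == "matrix") {
    if (is.null(age)) stop("age is required for type = 'matrix'", call. = FALSE)
    predict_matrix(model, age, education)
  } else {
    transition_matrices(model, education)
  }
}

#' @export
residuals.wle <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  obs <- build_transition_observations(object$classified)
  out <- numeric(nrow(obs))
  for (g in names(object$models)) {
    model <- object$models[[g]]
    sel <- which(as_gender_code(obs$gender) == as_gender_code(g))
    for (i in sel) {
      P <- predict_matrix(model, obs$age[i], obs$education[i])
      p <- P[as.character(obs$origin[i]), as.character(obs$destination[i])]
      out[i] <- if (type == "deviance") sqrt(-2 * log(max(p, 1e-300)))
                else (1 - p) / sqrt(p * (1 - p) + 1e-300)
    }
  }
  out
}

# reinterpret a fitted model as a generator ground truth (used by simulate.wle)
as_ground_truth <- function(object) {
  stopifnot(inherits(object, "wle"))
  need <- genders() %in% names(object$models)
  if (!all(need))
    stop("simulating requires fitted models for both genders", call. = FALSE)
  coef <- lapply(object$models, model_coef_list)
  init30 <- array(0, dim = c(2L, 3L, 5L),
                  dimnames = list(genders(), education_levels(), living_states()))
  for (g in genders()) for (e in education_levels()) {
    init30[g, e, ] <- tryCatch(
      unconditional_init_distribution(object$classified, g, e,
                                      object$start_age, age_window = 2L),
      error = function(err) c(1, 0, 0, 0, 0))
  }
  structure(list(coef = coef, age_center = object$age_center,
                 age_scale = object$age_scale,
                 start_age = object$start_age,
                 terminal_age = object$terminal_age,
                 allowed = object$models[[1L]]$eff_mask,
                 init30 = init30, preset = "fitted",
                 education_effects = TRUE),
            class = "ground_truth")
}

#' Simulate person-year panels from a fitted model
#'
#' Draws synthetic register data whose transition dynamics are the fitted
#' transition probabilities (a parametric-bootstrap generator). Requires
#' models for both genders.
#'
#' @param object A [wle()] fit.
#' @param nsim Number of panels to simulate.
#' @param seed Integer seed.
#' @param config A [sim_config()]; its seed is advanced per panel.
#' @param ... Unused.
#' @return A data frame (if `nsim = 1`) or list of data frames.
#' @export
simulate.wle <- function(object, nsim = 1, seed = 1L,
                         config = sim_config(1000L), ...) {
  truth <- as_ground_truth(object)
  out <- lapply(seq_len(nsim), function(k)
    simulate_population(truth, config, seed = as.integer(seed) + k - 1L))
  if (nsim == 1) out[[1L]] else out
}

#' Plot state occupancy implied by a fitted model
#'
#' Stacked occupancy probabilities over age for one gender x education
#' profile, starting from the observed state mix at the baseline age.
#'
#' @param x A [wle()] fit.
#' @param gender,education Profile to display.
#' @param init_dist Optional starting distribution (default the observed mix
#'   at the baseline age, pooled over a +/-2 year window if needed).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.wle <- function(x, gender = "men", education = "mid", init_dist = NULL, ...) {
  g <- genders()[as_gender_code(gender)]
  if (is.null(init_dist))
    init_dist <- unconditional_init_distribution(x$classified, g, education,
                                                 x$start_age, age_window = 2L)
  mats <- transition_matrices(x$models[[g]], education)
  occ <- occupancy(mats, init_dist)
  ages <- occ$ages
  cum <- t(apply(occ$occupancy, 1L, cumsum))
  cols <- c("#1b9e77", "#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3", "grey80")
  graphics::plot(range(ages), c(0, 1), type = "n", xlab = "Age",
                 ylab = "Occupancy probability",
                 main = paste0("State occupancy (", g, ", ", education,
                               " education)"), ...)
  prev <- rep(0, length(ages))
  for (s in seq_len(.N_STATES)) {
    graphics::polygon(c(ages, rev(ages)), c(cum[, s], rev(prev)),
                      col = cols[s], border = NA)
    prev <- cum[, s]
  }
  graphics::legend("left", legend = labor_states(), fill = cols, cex = 0.7,
                   bg = "white")
  invisible(x)
}

#' Partition life expectancy for one profile
#'
#' Computes total life expectancy at the baseline age and its partition into
#' the five state-specific expectancies for one gender x education profile,
#' from a fitted [wle()] model: predicted transition matrices over the age
#' grid, propagated from the observed (unconditional) starting-state mix.
#'
#' @param object A [wle()] fit.
#' @param gender,education Profile.
#' @param init_dist Starting distribution over living states; default the
#'   observed mix at `start_age` ([unconditional_init_distribution()]).
#' @param age_window Pooling window for the default starting mix.
#' @param death_year_credit See [state_expectancies()].
#' @return An `expectancy_table`.
#' @export
life_expectancy <- function(object, gender, education, init_dist = NULL,
                            age_window = 0L, death_year_credit = 1) {
  stopifnot(inherits(object, "wle"))
  g <- genders()[as_gender_code(gender)]
  model <- object$models[[g]]
  if (is.null(model)) stop("no fitted model for gender '", g, "'", call. = FALSE)
  if (is.null(init_dist))
    init_dist <- unconditional_init_distribution(object$classified, g,
                                                 education, object$start_age,
                                                 age_window = age_window)
  mats <- transition_matrices(model, education)
  state_expectancies(mats, init_dist, start_age = object$start_age,
                     death_year_credit = death_year_credit)
}
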