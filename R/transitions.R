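design_matrix <- function(age, education, age_center, age_scale) {
  z <- scale_age(age, age_center, age_scale)
  e <- as_education_code(education)
  cbind(intercept = 1, z = z, z2 = z^2, z3 = z^3,
        edu_mid = as.numeric(e == 2L), edu_high = as.numeric(e == 3L))
}

#' Fit per-origin multinomial transition models for one gender
#'
#' Maximum-likelihood multinomial logistic regression of the destination
#' state on a cubic polynomial in centered age plus education contrasts,
#' fitted separately for each living origin state (reference destination =
#' staying in the origin). Stratifying by origin is equivalent to one fully
#' interacted multinomial model and matches how discrete-time multistate
#' software parameterizes transitions.
#'
#' @param observations Transition observations from
#'   [build_transition_observations()]; rows of other genders are ignored.
#' @param gender `"men"` or `"women"`.
#' @param origins Origin states to fit (default all five living states).
#' @param mask Optional 6x6 logical matrix of structurally allowed
#'   transitions; disallowed destinations get probability exactly 0.
#' @param ages Age grid over which predictions are defined.
#' @param age_center,age_scale Centering and scaling of age, recorded in the
#'   model so predictions are invariant to the choice.
#' @param ridge_lambda Nonnegative L2 penalty on non-intercept coefficients
#'   (0 = plain MLE; a small value such as 1e-6 stabilizes sparse origins).
#' @param max_iter,tol Newton iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param warm_start Optional `transition_model` whose coefficients seed the
#'   Newton iterations (used by the bootstrap).
#' @return Object of class `transition_model`: per-origin coefficient
#'   matrices (destinations x 6), observed-information covariance, and fit
#'   diagnostics (log-likelihood trace, iterations, convergence flag).
#' @export
fit_transition_model <- function(observations, gender,
                                 origins = living_states(), mask = NULL,
                                 ages = 30:109, age_center = 70, age_scale = 10,
                                 ridge_lambda = 0, max_iter = 200L, tol = 1e-10,
                                 warm_start = NULL) {
  g <- genders()[as_gender_code(gender)]
  obs <- observations[as_gender_code(observations$gender) == as_gender_code(g), ,
                      drop = FALSE]
  if (is.null(mask)) mask <- default_allowed_transitions()
  fits <- list()
  for (o in origins) {
    oc <- as_state_code(o)
    olab <- labor_states()[oc]
    sub <- obs[as_state_codes(obs$origin) == oc, , drop = FALSE]
    if (!nrow(sub))
      stop("no transition observations with origin '", olab, "' for ", g,
           call. = FALSE)
    if (length(unique(sub$age)) < 4L && ridge_lambda == 0)
      stop("origin '", olab, "': fewer than 4 distinct ages; the cubic is ",
           "not identifiable without a ridge penalty", call. = FALSE)
    allowed <- which(mask[oc, ])
    observed <- sort(unique(as_state_codes(sub$destination)))
    not_allowed <- setdiff(observed, allowed)
    if (length(not_allowed))
      stop("origin '", olab, "': observed destination(s) excluded by mask: ",
           paste(labor_states()[not_allowed], collapse = ", "), call. = FALSE)
    cats <- sort(unique(c(oc, observed)))   # reference always kept
    dropped <- setdiff(allowed, cats)
    if (length(dropped))
      warning("origin '", olab, "' (", g, "): destination(s) never observed, ",
              "fitted toward probability 0 (separation): ",
              paste(labor_states()[dropped], collapse = ", "), call. = FALSE)
    X <- design_matrix(sub$age, sub$education, age_center, age_scale)
    y <- match(as_state_codes(sub$destination), cats)
    start <- NULL
    if (!is.null(warm_start)) {
      ws <- warm_start$fits[[olab]]
      if (!is.null(ws) && identical(ws$categories, cats))
        start <- t(ws$coef)
    }
    fit <- fit_multinom(X, y, weights = sub$weight, ref = match(oc, cats),
                        lambda = ridge_lambda, max_iter = max_iter, tol = tol,
                        start = start)
    if (!fit$converged)
      stop(errorCondition(
        paste0("multinomial fit for origin '", olab, "' (", g,
               ") did not converge in ", fit$iterations,
               " iterations (last log-likelihood ", format(fit$loglik), ")"),
        class = c("worklife_nonconvergence", "error", "condition"),
        call = NULL, diagnostics = fit[c("loglik_trace", "iterations")]))
    coef <- t(fit$coef)
    rownames(coef) <- labor_states()[cats[fit$nonref]]
    colnames(coef) <- colnames(X)
    fits[[olab]] <- list(coef = coef, vcov = fit$vcov,
                         categories = cats, dropped = dropped,
                         diagnostics = list(loglik = fit$loglik,
                                            loglik_trace = fit$loglik_trace,
                                            iterations = fit$iterations,
                                            converged = fit$converged,
                                            n_obs = fit$n,
                                            sum_weights = fit$sum_weights))
  }
  eff_mask <- mask
  for (olab in names(fits)) {
    d <- fits[[olab]]$dropped
    if (length(d)) eff_mask[as_state_code(olab), d] <- FALSE
  }
  structure(list(gender = g, fits = fits, mask = mask, eff_mask = eff_mask,
                 ages = as.integer(ages), age_center = age_center,
                 age_scale = age_scale, ridge_lambda = ridge_lambda),
            class = "transition_model")
}

as_state_codes <- function(x) {
  if (is.factor(x)) as_state_code(as.character(x)) else as_state_code(x)
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Multinomial transition model —", x$gender, "\n")
  for (olab in names(x$fits)) {
    f <- x$fits[[olab]]
    cat(sprintf("  %-14s n=%8d  logLik=%.1f  iter=%d%s\n", olab,
                f$diagnostics$n_obs, f$diagnostics$loglik,
                f$diagnostics$iterations,
                if (length(f$dropped))
                  paste0("  [separation: ",
                         paste(labor_states()[f$dropped], collapse = ","), "]")
                else ""))
  }
  if (x$ridge_lambda > 0) cat("  ridge lambda:", x$ridge_lambda, "\n")
  invisible(x)
}

model_coef_list <- function(model) {
  lapply(model$fits, `[[`, "coef")
}

#' Predicted transition matrix at one age
#'
#' Evaluates a fitted [fit_transition_model()] at a single age and education
#' level: rows for the living origins via the softmax of the fitted linear
#' predictors, a unit dead row, and exact zeros for masked or
#' separation-dropped destinations.
#'
#' @param model A `transition_model`.
#' @param age Age in years; must lie on the model's age grid (no
#'   extrapolation).
#' @param education `"low"`, `"mid"` or `"high"`.
#' @return A 6x6 row-stochastic matrix.
#' @export
predict_matrix <- function(model, age, education) {
  stopifnot(inherits(model, "transition_model"))
  if (!all(age %in% model$ages))
    stop("age ", age[!age %in% model$ages][1L], " outside the model grid [",
         min(model$ages), ", ", max(model$ages), "]", call. = FALSE)
  build_matrix(model_coef_list(model),
               scale_age(age, model$age_center, model$age_scale),
               as_education_code(education), allowed = model$eff_mask)
}

#' Predicted transition matrices over the age grid
#'
#' @inheritParams predict_matrix
#' @param ages Subset of the model grid (default all of it).
#' @return A [transition_matrix_set()] for the model's gender and the given
#'   education.
#' @export
transition_matrices <- function(model, education, ages = model$ages) {
  stopifnot(inherits(model, "transition_model"))
  if (!all(ages %in% model$ages))
    stop("ages outside the model grid", call. = FALSE)
  e <- education_levels()[as_education_code(education)]
  build_matrix_set(model_coef_list(model), as.integer(ages),
                   model$age_center, model$age_scale, as_education_code(e),
                   allowed = model$eff_mask,
                   profile = list(gender = model$gender, education = e))
}

#' Coefficients and Wald intervals of a transition model
#'
#' @param model A `transition_model`.
#' @param level Confidence level for the Wald intervals.
#' @return Long data frame: origin, destination, term, estimate, se, lower,
#'   upper.
#' @export
coef_table <- function(model, level = 0.95) {
  stopifnot(inherits(model, "transition_model"))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  for (olab in names(model$fits)) {
    f <- model$fits[[olab]]
    p <- ncol(f$coef)
    se <- sqrt(pmax(diag(f$vcov), 0))
    k <- 0L
    for (d in rownames(f$coef)) {
      est <- f$coef[d, ]
      s <- se[k + seq_len(p)]
      k <- k + p
      out[[length(out) + 1L]] <- data.frame(
        gender = model$gender, origin = olab, destination = d,
        term = colnames(f$coef), estimate = unname(est), se = s,
        lower = unname(est) - zq * s, upper = unname(est) + zq * s)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Serialize a transition model to JSON
#'
#' Writes coefficients, age scaling, masks and diagnostics in a
#' machine-readable form; [read_transition_model()] restores the model.
#'
#' @param model A `transition_model`.
#' @param path Output file.
#' @export
write_transition_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  payload <- list(
    gender = model$gender, ages = model$ages,
    age_center = model$age_center, age_scale = model$age_scale,
    ridge_lambda = model$ridge_lambda,
    mask = model$mask, eff_mask = model$eff_mask,
    fits = lapply(model$fits, function(f)
      list(coef = f$coef, destinations = rownames(f$coef),
           terms = colnames(f$coef), vcov = f$vcov,
           categories = f$categories, dropped = f$dropped,
           diagnostics = f$diagnostics[c("loglik", "iterations", "converged",
                                         "n_obs", "sum_weights")])))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_mat <- function(m, rn, cn) {
    m <- as.matrix(m); dimnames(m) <- list(rn, cn); m
  }
  states <- labor_states()
  x$mask <- fix_mat(x$mask, states, states)
  x$eff_mask <- fix_mat(x$eff_mask, states, states)
  x$fits <- lapply(x$fits, function(f) {
    f$coef <- fix_mat(f$coef, f$destinations, f$terms)
    f$vcov <- as.matrix(f$vcov)
    f$dropped <- as.integer(f$dropped)
    f$categories <- as.integer(f$categories)
    f
  })
  x$ages <- as.integer(x$ages)
  structure(x, class = "transition_model")
}
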