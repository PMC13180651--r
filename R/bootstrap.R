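#' Clustered bootstrap intervals for state expectancies
#'
#' Resamples persons (entire observed trajectories, keeping the longitudinal
#' cluster intact) with replacement and re-runs the pipeline —
#' classification, transition-model estimation, starting-state mix, and
#' expectancy computation — on each replicate, returning percentile
#' intervals. A resampled person appearing k times enters the weighted
#' likelihood with weight k, which yields estimates identical to physically
#' duplicating the rows (the weight/duplication equivalence of
#' [fit_transition_model()]); replicate fits reuse the point-estimate design
#' matrices and are warm-started from the point estimates.
#'
#' @param data Person-year records (raw or classified).
#' @param gender,education Profile whose expectancies are summarized.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param level Interval coverage level (default 0.95, percentile method).
#' @param age_window Pooling window for the starting-state mix.
#' @param identity_resample If `TRUE`, every "resample" is the original data
#'   (diagnostic: with `B = 1` the point estimate is reproduced exactly).
#' @param max_failures Maximum tolerated fraction of failed replicate fits
#'   before the whole computation errors.
#' @param replicate_tol Relative log-likelihood tolerance for replicate
#'   refits (looser than the point fit; the induced expectancy error is
#'   orders of magnitude below the interval width).
#' @param ... Passed to [wle()] (e.g. `ridge_lambda`, `mask`).
#' @return An `expectancy_table` with percentile bounds per state (`lower`,
#'   `upper`) and for total LE (`lower_total`, `upper_total`), plus the
#'   replicate draws in `$replicates` and the failed-replicate count.
#' @export
bootstrap_expectancies <- function(data, gender, education, B = 200L,
                                   seed = 1L, level = 0.95, age_window = 2L,
                                   identity_resample = FALSE,
                                   max_failures = 0.1,
                                   replicate_tol = 1e-8, ...) {
  stopifnot(B >= 1L)
  set.seed(as.integer(seed))
  classified <- if ("state" %in% names(data)) data else classify_dataset(data)
  g <- genders()[as_gender_code(gender)]
  point_fit <- wle(classified, genders_fit = g, ...)
  point_model <- point_fit$models[[g]]
  point <- life_expectancy(point_fit, g, education, age_window = age_window)

  persons <- unique(classified$person_id)
  np <- length(persons)
  obs <- build_transition_observations(classified, keep_person = TRUE)
  obs <- obs[as_gender_code(obs$gender) == as_gender_code(g), , drop = FALSE]
  obs_pid <- match(obs$person_id, persons)

  # per-origin grouped designs; only the weights change across replicates
  strata <- lapply(names(point_model$fits), function(olab) {
    f <- point_model$fits[[olab]]
    sel <- which(as_state_codes(obs$origin) == as_state_code(olab))
    sub <- obs[sel, , drop = FALSE]
    X <- design_matrix(sub$age, sub$education, point_fit$age_center,
                       point_fit$age_scale)
    y <- match(as_state_codes(sub$destination), f$categories)
    grp <- group_patterns(X, y, length(f$categories))
    list(olab = olab, grp = grp, K = length(f$categories),
         base_w = sub$weight, pid = obs_pid[sel],
         cats = f$categories, ref = match(as_state_code(olab), f$categories),
         start = t(f$coef))
  })
  names(strata) <- names(point_model$fits)

  init_sel <- as_gender_code(classified$gender) == as_gender_code(g) &
    abs(classified$age - point_fit$start_age) <= age_window &
    classified$state != "dead" &
    as_education_code(classified$education) == as_education_code(education)
  init_pid <- match(classified$person_id[init_sel], persons)
  init_state <- as_state_codes(classified$state[init_sel])

  e_code <- as_education_code(education)
  draws <- matrix(NA_real_, B, 6L,
                  dimnames = list(NULL, c(living_states(), "le_total")))
  failures <- 0L
  for (b in seq_len(B)) {
    mult <- if (identity_resample) rep(1L, np) else
      tabulate(sample.int(np, np, replace = TRUE), nbins = np)
    et <- tryCatch({
      coefs <- lapply(strata, function(st) {
        w <- st$base_w * mult[st$pid]
        Y <- matrix(0, nrow(st$grp$Xu), st$K)
        acc <- rowsum(w, group = st$grp$ind)
        Y[as.integer(rownames(acc))] <- acc
        fit <- fit_multinom_grouped(st$grp$Xu, Y, ref = st$ref,
                                    lambda = point_fit$ridge_lambda,
                                    tol = replicate_tol, start = st$start,
                                    compute_vcov = FALSE)
        if (!fit$converged) stop("replicate fit did not converge")
        coef <- t(fit$coef)
        rownames(coef) <- labor_states()[st$cats[fit$nonref]]
        coef
      })
      wi <- mult[init_pid]
      if (!sum(wi)) stop("empty starting-state cell in replicate")
      tab <- vapply(1:5, function(s) sum(wi[init_state == s]), 0)
      mats <- build_matrix_set(coefs, point_model$ages,
                               point_fit$age_center, point_fit$age_scale,
                               e_code, allowed = point_model$eff_mask)
      state_expectancies(mats, tab / sum(tab), point_fit$start_age)
    }, error = function(e) e)
    if (inherits(et, "error")) {
      failures <- failures + 1L
    } else {
      draws[b, ] <- c(et$e_state, et$le_total)
    }
  }
  if (failures > max_failures * B)
    stop("bootstrap failed in ", failures, " of ", B, " replicates",
         call. = FALSE)
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2L,
              stats::quantile, probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  new_expectancy_table(point$e_state, point$start_age, profile = point$profile,
                       lower = qs[1L, 1:5], upper = qs[2L, 1:5],
                       extra = list(lower_total = qs[1L, 6L],
                                    upper_total = qs[2L, 6L],
                                    replicates = draws[ok, , drop = FALSE],
                                    n_failures = failures, B = B,
                                    level = level))
}
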