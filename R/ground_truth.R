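#' Packaged ground-truth transition model
#'
#' Returns a fixed, fully documented set of multinomial-logit coefficients
#' that drives the synthetic register generator. For each gender and each
#' living origin state, the log-odds of moving to every other state (reference
#' = staying) are a cubic polynomial in centered age, `z = (age - 70) / 10`,
#' plus additive education contrasts (`mid` and `high` vs `low`).
#'
#' The defaults are synthetic: they do not reproduce any country's registers,
#' but encode the qualitative gradients the working-life literature reports —
#' mortality rising with age and steeper for the low educated, women and the
#' low educated spending more years outside full-year work, retirement
#' concentrating in the mid-60s, and re-entry into employment after spells of
#' joblessness. Two variants sharpen the contrasts: `"finland_like"` (larger
#' education gaps, small gender gaps, later and longer retirement) and
#' `"italy_like"` (large gender gaps in joblessness, earlier retirement, more
#' disability years). Both are synthetic presets, not country estimates.
#'
#' @param preset `"default"`, `"finland_like"` or `"italy_like"`.
#' @param education_effects If `FALSE`, all education contrasts are zeroed
#'   (a null model used for gap-recovery experiments).
#' @return An object of class `ground_truth`: list with `coef` (per gender,
#'   per origin, a destinations x 6 coefficient matrix), `age_center`,
#'   `age_scale`, `start_age`, `terminal_age`, `allowed` (transition mask)
#'   and `init30` (baseline state distribution at age 30 per gender x
#'   education).
#' @seealso [simulate_population()], [true_expectancies()]
#' @export
#' @examples
#' truth <- default_ground_truth()
#' truth$coef$men$full_year
default_ground_truth <- function(preset = c("default", "finland_like", "italy_like"),
                                 education_effects = TRUE) {
  preset <- match.arg(preset)
  cn <- c("intercept", "z", "z2", "z3", "edu_mid", "edu_high")
  row <- function(...) {
    v <- c(...)
    stopifnot(length(v) == 6L)
    v
  }
  # men, baseline ("default") — rows are destinations, reference = origin
  men <- list(
    full_year = rbind(
      mid_low        = row(-2.60,  0.05,  0.05,  0.00, -0.15, -0.30),
      unemp_inactive = row(-3.00,  0.05,  0.10,  0.00, -0.35, -0.70),
      disability     = row(-5.20,  0.80,  0.00, -0.10, -0.40, -0.80),
      retired        = row( 1.80,  4.00, -1.40, -0.42,  0.05,  0.10),
      dead           = row(-4.05,  0.90,  0.08,  0.00, -0.20, -0.40)),
    mid_low = rbind(
      full_year      = row( 0.30, -0.15, -0.05,  0.00,  0.20,  0.40),
      unemp_inactive = row(-1.60,  0.05,  0.05,  0.00, -0.30, -0.60),
      disability     = row(-4.80,  0.80,  0.00, -0.10, -0.40, -0.80),
      retired        = row( 1.80,  4.00, -1.40, -0.42,  0.05,  0.10),
      dead           = row(-3.95,  0.90,  0.08,  0.00, -0.20, -0.40)),
    unemp_inactive = rbind(
      full_year      = row(-1.70, -0.25, -0.05,  0.00,  0.35,  0.70),
      mid_low        = row(-1.50, -0.15,  0.00,  0.00,  0.15,  0.30),
      disability     = row(-4.20,  0.80,  0.00, -0.10, -0.40, -0.80),
      retired        = row( 2.00,  4.00, -1.40, -0.42,  0.05,  0.10),
      dead           = row(-3.75,  0.90,  0.08,  0.00, -0.25, -0.50)),
    disability = rbind(
      full_year      = row(-3.60, -0.30,  0.00,  0.00,  0.20,  0.40),
      mid_low        = row(-3.40, -0.20,  0.00,  0.00,  0.15,  0.30),
      unemp_inactive = row(-3.60,  0.00,  0.00,  0.00,  0.00,  0.00),
      retired        = row( 2.00,  3.90, -1.35, -0.40,  0.05,  0.10),
      dead           = row(-3.35,  0.85,  0.08,  0.00, -0.15, -0.30)),
    retired = rbind(
      full_year      = row(-5.80, -0.50,  0.00,  0.00,  0.20,  0.40),
      mid_low        = row(-5.60, -0.50,  0.00,  0.00,  0.10,  0.20),
      unemp_inactive = row(-5.40, -0.50,  0.00,  0.00,  0.00,  0.00),
      disability     = row(-6.00,  0.00,  0.00,  0.00,  0.00,  0.00),
      dead           = row(-3.85,  0.95,  0.08,  0.00, -0.20, -0.40)))
  men <- lapply(men, function(B) { colnames(B) <- cn; B })

  # gender deltas (added to the men coefficients), by preset
  d_unemp <- switch(preset, default = 0.40, finland_like = 0.20, italy_like = 1.00)
  d_reentry <- switch(preset, default = -0.25, finland_like = -0.10, italy_like = -0.60)
  d_midlow <- switch(preset, default = 0.30, finland_like = 0.40, italy_like = 0.10)
  d_dead <- -0.35
  women <- lapply(men, function(B) {
    B[, "intercept"] <- B[, "intercept"] +
      ifelse(rownames(B) == "dead", d_dead,
      ifelse(rownames(B) == "unemp_inactive", d_unemp,
      ifelse(rownames(B) == "full_year", d_reentry,
      ifelse(rownames(B) == "mid_low", d_midlow,
      ifelse(rownames(B) == "retired", 0.10, 0)))))
    B
  })

  coef <- list(men = men, women = women)

  # preset-level adjustments applied to both genders
  if (preset == "italy_like") {
    coef <- lapply(coef, function(g) lapply(g, function(B) {
      B[rownames(B) == "retired", "intercept"] <-
        B[rownames(B) == "retired", "intercept"] + 0.8
      B[rownames(B) == "disability", "intercept"] <-
        B[rownames(B) == "disability", "intercept"] + 0.60
      B[rownames(B) == "dead", "intercept"] <-
        B[rownames(B) == "dead", "intercept"] + 0.20
      B[, c("edu_mid", "edu_high")] <- 0.6 * B[, c("edu_mid", "edu_high")]
      B[rownames(B) == "dead", c("edu_mid", "edu_high")] <- c(-0.08, -0.16)
      B
    }))
  } else if (preset == "finland_like") {
    coef <- lapply(coef, function(g) lapply(g, function(B) {
      B[, c("edu_mid", "edu_high")] <- 1.3 * B[, c("edu_mid", "edu_high")]
      B
    }))
  }
  if (!education_effects) {
    coef <- lapply(coef, function(g) lapply(g, function(B) {
      B[, c("edu_mid", "edu_high")] <- 0
      B
    }))
  }
  coef <- lapply(coef, function(g) lapply(g, function(B) {
    colnames(B) <- cn
    B
  }))

  # baseline state mix at age 30 (full_year, mid_low, unemp_inactive,
  # disability, retired); women shifted toward joblessness
  init30 <- array(0, dim = c(2L, 3L, 5L),
                  dimnames = list(genders(), education_levels(), living_states()))
  init30["men", "low", ] <- c(0.55, 0.18, 0.24, 0.03, 0.00)
  init30["men", "mid", ] <- c(0.65, 0.15, 0.17, 0.03, 0.00)
  init30["men", "high", ] <- c(0.75, 0.12, 0.12, 0.01, 0.00)
  shift <- switch(preset, default = 0.07, finland_like = 0.03, italy_like = 0.15)
  for (e in education_levels()) {
    v <- init30["men", e, ]
    take <- min(shift, v[1L] - 0.05)
    v[1L] <- v[1L] - take
    v[3L] <- v[3L] + take
    init30["women", e, ] <- v
  }
  if (!education_effects) {
    for (g in genders())
      for (e in education_levels())
        init30[g, e, ] <- init30[g, "mid", ]
  }

  structure(list(coef = coef, age_center = 70, age_scale = 10,
                 start_age = 30L, terminal_age = 110L,
                 allowed = default_allowed_transitions(),
                 init30 = init30, preset = preset,
                 education_effects = education_effects),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth transition model (synthetic preset '", x$preset, "')\n",
      sep = "")
  cat("Ages ", x$start_age, "-", x$terminal_age, ", z = (age - ", x$age_center,
      ") / ", x$age_scale, "\n", sep = "")
  if (!x$education_effects) cat("Education effects: zeroed (null model)\n")
  invisible(x)
}

#' Transition matrices implied by a ground truth
#'
#' Evaluates the ground-truth multinomial logits on the age grid for one
#' gender x education profile.
#'
#' @param truth A [default_ground_truth()] object.
#' @param gender `"men"` or `"women"`.
#' @param education `"low"`, `"mid"` or `"high"`.
#' @param ages Age grid; default the truth's full grid
#'   `start_age .. terminal_age - 1`.
#' @return A [transition_matrix_set()].
#' @export
truth_matrices <- function(truth, gender, education, ages = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  g <- genders()[as_gender_code(gender)]
  e_code <- as_education_code(education)
  if (is.null(ages)) ages <- seq(truth$start_age, truth$terminal_age - 1L)
  build_matrix_set(truth$coef[[g]], ages, truth$age_center, truth$age_scale,
                   e_code, allowed = truth$allowed,
                   profile = list(gender = g,
                                  education = education_levels()[e_code]))
}

#' Noiseless expectancies implied by a ground truth
#'
#' The exact state expectancies the estimation pipeline should recover,
#' computed by running the discrete-time chain on the truth's own matrices.
#'
#' @inheritParams truth_matrices
#' @param init_dist Probability vector over the five living states at the
#'   start age; default the truth's baseline age-30 mix for the profile.
#' @return An `expectancy_table` (see [state_expectancies()]).
#' @export
true_expectancies <- function(truth, gender, education, init_dist = NULL) {
  g <- genders()[as_gender_code(gender)]
  e <- education_levels()[as_education_code(education)]
  if (is.null(init_dist)) init_dist <- truth$init30[g, e, ]
  mats <- truth_matrices(truth, g, e)
  state_expectancies(mats, init_dist, start_age = truth$start_age)
}
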