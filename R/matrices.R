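#' Construct an age-indexed set of transition matrices
#'
#' A `transition_matrix_set` holds one row-stochastic 6x6 matrix per single
#' year of age on the grid `start_age .. terminal_age - 1`, for one covariate
#' profile (gender x education). The matrix at age x gives the probabilities
#' of each state at age x+1 conditional on the state at x. The dead row is
#' the unit vector on `dead`; the grid is closed at `terminal_age`, where all
#' remaining living mass is absorbed (no exposure is credited at or beyond
#' `terminal_age`).
#'
#' @param matrices 6 x 6 x n_ages array (or list of 6x6 matrices) of
#'   transition probabilities, dimnames on states.
#' @param ages Integer vector of ages, one per matrix, consecutive.
#' @param profile List with elements `gender` and `education` (labels), or
#'   `NULL` for anonymous sets.
#' @param tol Row-stochasticity tolerance on input validation.
#' @return An object of class `transition_matrix_set`.
#' @export
transition_matrix_set <- function(matrices, ages, profile = NULL, tol = 1e-9) {
  if (is.list(matrices))
    matrices <- array(unlist(matrices), dim = c(.N_STATES, .N_STATES, length(matrices)))
  stopifnot(is.array(matrices), length(dim(matrices)) == 3L,
            dim(matrices)[1L] == .N_STATES, dim(matrices)[2L] == .N_STATES)
  ages <- as.integer(ages)
  if (dim(matrices)[3L] != length(ages))
    stop("need one matrix per age", call. = FALSE)
  if (length(ages) > 1L && any(diff(ages) != 1L))
    stop("ages must be consecutive single years", call. = FALSE)
  dimnames(matrices) <- list(labor_states(), labor_states(), ages)
  for (k in seq_along(ages)) {
    P <- matrices[, , k]
    if (any(P < -tol))
      stop("negative transition probability at age ", ages[k], call. = FALSE)
    rs <- rowSums(P)
    bad <- which(abs(rs - 1) > tol)
    if (length(bad))
      stop("row not stochastic at age ", ages[k], ", origin state '",
           labor_states()[bad[1L]], "' (sum = ", format(rs[bad[1L]]), ")",
           call. = FALSE)
    if (any(abs(P[.DEAD, ] - c(rep(0, 5), 1)) > tol))
      stop("dead row must be the unit vector on dead (age ", ages[k], ")",
           call. = FALSE)
    # exact renormalization so downstream sums hold to 1e-12
    P[.DEAD, ] <- c(rep(0, 5), 1)
    matrices[, , k] <- P / rowSums(P)
  }
  structure(list(matrices = matrices, ages = ages,
                 start_age = ages[1L], terminal_age = ages[length(ages)] + 1L,
                 profile = profile),
            class = "transition_matrix_set")
}

#' @export
print.transition_matrix_set <- function(x, ...) {
  cat("Transition matrix set:", length(x$ages), "ages",
      paste0("[", x$start_age, ", ", x$terminal_age - 1L, "]"),
      "closed at", x$terminal_age, "\n")
  if (!is.null(x$profile))
    cat("Profile:", x$profile$gender, "x", x$profile$education, "\n")
  invisible(x)
}

#' @export
`[.transition_matrix_set` <- function(x, age) {
  k <- match(as.integer(age), x$ages)
  if (any(is.na(k)))
    stop("age ", age[which(is.na(k))[1L]], " outside grid [",
         x$start_age, ", ", x$terminal_age - 1L, "]", call. = FALSE)
  if (length(k) == 1L) x$matrices[, , k] else x$matrices[, , k, drop = FALSE]
}

# centered/scaled age used by both the ground truth and fitted models
scale_age <- function(age, center, scale) (age - center) / scale

# Build one 6x6 matrix from per-origin multinomial coefficients.
# coef: list indexed by origin label; each element a matrix with rows =
# destination labels (reference = origin omitted) and 6 columns
# (intercept, z, z2, z3, edu_mid, edu_high). Destinations absent from the
# rows (and the mask) get probability exactly 0; probabilities arise from a
# softmax over the allowed destinations only.
build_matrix <- function(coef, z, education_code, allowed = NULL) {
  edu_mid <- as.numeric(education_code == 2L)
  edu_high <- as.numeric(education_code == 3L)
  xrow <- c(1, z, z^2, z^3, edu_mid, edu_high)
  P <- matrix(0, .N_STATES, .N_STATES,
              dimnames = list(labor_states(), labor_states()))
  for (o in seq_len(.N_STATES - 1L)) {
    olab <- labor_states()[o]
    B <- coef[[olab]]
    eta <- rep(-Inf, .N_STATES)
    eta[o] <- 0  # reference: staying in the origin state
    if (!is.null(B) && nrow(B)) {
      d <- as_state_code(rownames(B))
      eta[d] <- as.vector(B %*% xrow)
    }
    if (!is.null(allowed)) eta[!allowed[o, ]] <- -Inf
    m <- max(eta)
    w <- exp(eta - m)
    P[o, ] <- w / sum(w)
  }
  P[.DEAD, .DEAD] <- 1
  P
}

build_matrix_set <- function(coef, ages, age_center, age_scale, education_code,
                             allowed = NULL, profile = NULL) {
  arr <- array(0, dim = c(.N_STATES, .N_STATES, length(ages)))
  for (k in seq_along(ages)) {
    arr[, , k] <- build_matrix(coef, scale_age(ages[k], age_center, age_scale),
                               education_code, allowed)
  }
  transition_matrix_set(arr, ages, profile = profile, tol = 1e-9)
}

default_allowed_transitions <- function() {
  A <- matrix(TRUE, .N_STATES, .N_STATES,
              dimnames = list(labor_states(), labor_states()))
  A[.DEAD, ] <- c(rep(FALSE, 5), TRUE)
  A
}
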