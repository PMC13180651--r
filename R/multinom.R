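# Weighted multinomial logistic regression with optional L2 (ridge) penalty
# on non-intercept coefficients, by Newton-Raphson with step-halving (see
# src/multinom.cpp for the compiled core). The likelihood depends on the
# data only through the weighted destination counts per unique covariate
# pattern, so observations are grouped before iterating; estimates,
# log-likelihood and vcov are identical to the ungrouped fit.
#
# X: n x p design (first column the intercept); y: integer in 1..K;
# ref: reference category index (its coefficients are fixed at 0).
# Returns coefficients as a p x (K-1) matrix for the non-reference
# categories, in column order setdiff(1:K, ref).
fit_multinom <- function(X, y, weights = NULL, ref = 1L, lambda = 0,
                         max_iter = 200L, tol = 1e-10, start = NULL,
                         compute_vcov = TRUE) {
  n <- nrow(X); p <- ncol(X)
  K <- max(y)
  stopifnot(length(y) == n, K >= 2L, ref >= 1L, ref <= K)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(all(w >= 0), length(w) == n)
  grp <- group_patterns(X, y, K)
  Y <- matrix(0, nrow(grp$Xu), K)
  acc <- rowsum(w, group = grp$ind)
  Y[as.integer(rownames(acc))] <- acc
  fit <- fit_multinom_grouped(grp$Xu, Y, ref = ref, lambda = lambda,
                              max_iter = max_iter, tol = tol, start = start,
                              compute_vcov = compute_vcov)
  fit$n <- n
  fit
}

# unique covariate patterns and the flat (destination, pattern) index used
# to accumulate grouped counts
group_patterns <- function(X, y, K) {
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  u <- !duplicated(key)
  cell <- match(key, key[u])
  Xu <- X[u, , drop = FALSE]
  list(Xu = Xu, cell = cell, ind = (y - 1L) * nrow(Xu) + cell)
}

fit_multinom_grouped <- function(Xu, Y, ref = 1L, lambda = 0,
                                 max_iter = 200L, tol = 1e-10, start = NULL,
                                 compute_vcov = TRUE) {
  p <- ncol(Xu); K <- ncol(Y)
  if (is.null(start)) start <- matrix(0, p, K - 1L)
  stopifnot(nrow(start) == p, ncol(start) == K - 1L)
  fit <- newton_multinom(Xu, Y, as.integer(ref), lambda,
                         as.integer(max_iter), tol, start, compute_vcov)
  fit$nonref <- as.integer(fit$nonref)
  fit$loglik_trace <- as.numeric(fit$loglik_trace)
  fit
}
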