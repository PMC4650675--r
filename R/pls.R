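# PLS2 core: latent-variable regression of a multivariate response on
# mean-centered predictors, NIPALS-style with X-deflation only. For each
# component the NIPALS inner loop's fixed point (w proportional to X'Yq,
# q proportional to Y'Xw) is computed by power iteration on the K x K
# matrix (Y'X)(X'Y), which converges to the identical weight vector at a
# fraction of the cost when K is small (K = 5 soil classes here).

#' Fit a PLS2 regression model
#'
#' Both `X` and `Y` are mean-centered before extraction; no variance
#' scaling is applied (absorbance features share a common magnitude scale,
#' so scaling is treated as unnecessary pretreatment). Components are
#' extracted sequentially with deflation of `X` only.
#'
#' @param X Numeric n x p predictor matrix.
#' @param Y Numeric n x K response matrix (a vector is treated as K = 1).
#' @param n_components Number of latent variables A, `1 <= A <= min(n-1, p)`.
#' @param tol Relative convergence tolerance of the weight iteration.
#' @param max_iter Iteration cap per component.
#' @return An object of class `pls2_model` with elements `x_mean`, `y_mean`,
#'   `weights` (p x A, unit columns), `x_scores` (n x A, mutually orthogonal),
#'   `x_loadings` (p x A), `y_loadings` (K x A), `score_ssq` (length A,
#'   the t'_c t_c), and `n_components`.
#' @export
fit_pls2 <- function(X, Y, n_components, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); K <- ncol(Y)
  if (nrow(Y) != n) stopf("X has %d rows but Y has %d", n, nrow(Y))
  if (n < 2L) stopf("need at least 2 samples, got %d", n)
  A <- as.integer(n_components)
  if (A < 1L || A > min(n - 1L, p))
    stopf("n_components = %d outside [1, min(n-1, p)] = [1, %d]", A, min(n - 1L, p))
  if (any(!is.finite(X)) || any(!is.finite(Y))) stopf("non-finite values in X or Y")
  fit <- cpp_pls2_fit(X, Y, A, tol, max_iter)
  fit$x_mean <- drop(fit$x_mean); fit$y_mean <- drop(fit$y_mean)
  fit$score_ssq <- drop(fit$score_ssq)
  structure(c(fit, list(n_components = A, n = n, p = p, K = K)),
            class = "pls2_model")
}

#' Regression coefficients of a fitted PLS2 model
#'
#' Returns the affine map (coefficient matrix and intercept) equivalent to
#' prediction with the first `a` latent variables:
#' `Y_hat = X %*% coefficients + intercept`.
#'
#' @param model A `pls2_model`.
#' @param a Number of components to use, `1 <= a <= n_components`.
#' @return A list with `coefficients` (p x K) and `intercept` (length K).
#' @export
pls2_coefficients <- function(model, a = model$n_components) {
  a <- as.integer(a)
  if (a < 1L || a > model$n_components)
    stopf("a = %d outside [1, %d]", a, model$n_components)
  Wa <- model$weights[, seq_len(a), drop = FALSE]
  Pa <- model$x_loadings[, seq_len(a), drop = FALSE]
  Qa <- model$y_loadings[, seq_len(a), drop = FALSE]
  # P'W is unit upper triangular in exact arithmetic; solve is cheap at a <= 30
  B <- Wa %*% solve(crossprod(Pa, Wa), t(Qa))
  intercept <- model$y_mean - drop(crossprod(B, model$x_mean))
  list(coefficients = B, intercept = intercept)
}

#' Predict responses from a fitted PLS2 model
#'
#' @param model A `pls2_model`.
#' @param X_new m x p matrix on the training grid.
#' @param a Number of components to use.
#' @return m x K matrix of predictions on the original response scale.
#' @export
predict_pls2 <- function(model, X_new, a = model$n_components) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1L)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != model$p)
    stopf("X_new has %d columns; model was trained on %d", ncol(X_new), model$p)
  cf <- pls2_coefficients(model, a)
  sweep(X_new %*% cf$coefficients, 2L, cf$intercept, `+`)
}

#' Variable importance in projection (VIP) scores
#'
#' Per-class VIP at `a` components:
#' `VIP_jk = sqrt(p * sum_c SSY_ck (w_jc / ||w_c||)^2 / sum_c SSY_ck)` with
#' `SSY_ck = q_ck^2 t'_c t_c`, the response variance of class k captured by
#' component c. Each class column satisfies `sum_j VIP_jk^2 = p`.
#'
#' @param model A `pls2_model`.
#' @param a Number of components at which to evaluate VIP.
#' @return An object of class `vip_table`: list with `scores` (p x K
#'   nonnegative matrix) and `component_count`.
#' @export
vip_scores <- function(model, a = model$n_components) {
  a <- as.integer(a)
  if (a < 1L || a > model$n_components)
    stopf("a = %d outside [1, %d]", a, model$n_components)
  W2 <- model$weights[, seq_len(a), drop = FALSE]^2      # columns unit norm
  ssy <- model$y_loadings[, seq_len(a), drop = FALSE]^2 *
    matrix(model$score_ssq[seq_len(a)], model$K, a, byrow = TRUE)  # K x a
  tot <- rowSums(ssy)
  if (any(tot <= 0))
    stopf("class %d has zero explained response variance at a = %d",
          which(tot <= 0)[1L], a)
  scores <- sqrt(model$p * sweep(W2 %*% t(ssy), 2L, tot, `/`))
  structure(list(scores = scores, component_count = a), class = "vip_table")
}

#' Features with high VIP per class, and their cross-class intersection
#'
#' @param table A `vip_table`.
#' @param threshold VIP cutoff (default 1, the conventional importance rule).
#' @return List with `per_class` (list of integer feature-index vectors, one
#'   per class column) and `intersection` (indices high for every class).
#' @export
high_vip_features <- function(table, threshold = 1.0) {
  per_class <- lapply(seq_len(ncol(table$scores)),
                      function(k) which(table$scores[, k] >= threshold))
  list(per_class = per_class, intersection = Reduce(intersect, per_class))
}
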