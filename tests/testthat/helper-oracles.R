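# Independent oracles and fixture builders. Everything here is coded from
# first principles (textbook algorithms, closed forms, literal loops) and
# shares no code path with the package implementation it checks.

# Literal textbook NIPALS PLS2: sample-space inner loop alternating between
# X-side and Y-side score vectors, X-deflation only, mean centering.
oracle_nipals_pls2 <- function(X, Y, A, tol = 1e-12, max_iter = 2000) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  p <- ncol(X); K <- ncol(Y); n <- nrow(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, K, A)
  Tm <- matrix(0, n, A)
  for (a in seq_len(A)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u)) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_vec <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, t_vec)) / sum(t_vec^2)
      u <- drop(Yc %*% q) / sum(q^2)
      if (sqrt(sum((t_vec - t_old)^2)) < tol * sqrt(sum(t_vec^2))) break
      t_old <- t_vec
    }
    p_vec <- drop(crossprod(Xc, t_vec)) / sum(t_vec^2)
    Xc <- Xc - tcrossprod(t_vec, p_vec)
    W[, a] <- w; P[, a] <- p_vec; Q[, a] <- q; Tm[, a] <- t_vec
  }
  list(x_mean = x_mean, y_mean = y_mean, weights = W, x_scores = Tm,
       x_loadings = P, y_loadings = Q)
}

# Prediction from the oracle decomposition at all A components.
oracle_nipals_predict <- function(fit, X_new) {
  B <- fit$weights %*% solve(crossprod(fit$x_loadings, fit$weights),
                             t(fit$y_loadings))
  sweep(sweep(as.matrix(X_new), 2, fit$x_mean) %*% B, 2, fit$y_mean, `+`)
}

# Multiresponse ordinary least squares via the normal equations.
oracle_ols_predict <- function(X, Y, X_new) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  B <- solve(crossprod(Xc), crossprod(Xc, sweep(as.matrix(Y), 2, colMeans(Y))))
  sweep(sweep(as.matrix(X_new), 2, colMeans(X)) %*% B, 2, colMeans(Y), `+`)
}

# Compare two score/loading matrices up to independent per-column signs.
expect_equal_up_to_sign <- function(got, want, tol) {
  for (a in seq_len(ncol(want))) {
    d <- min(max(abs(got[, a] - want[, a])), max(abs(got[, a] + want[, a])))
    expect_lt(d, tol)
  }
}

# A small random spectra set with an arbitrary declared class list.
random_set <- function(n_per_class, p, seed, classes = NULL) {
  classes <- classes %||% LETTERS[seq_along(n_per_class)]
  n <- sum(n_per_class)
  labels <- rep(classes, n_per_class)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p) +
    outer(as.numeric(factor(labels, levels = classes)), rnorm(p))
  spectra_set(seq(7500, 4000, length.out = p), X,
              sprintf("s%03d", seq_len(n)), labels, classes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_helper <- function(seed, code) {
  set.seed(seed)
  code
}

# Two-class synthetic fixture with a handful of informative grid points
# (narrow class bands centered on grid nodes) and pure noise elsewhere;
# used by the GA enrichment and scheme-ordering checks.
enrichment_config <- function(n_per_class = c(15L, 15L), noise_sd = 0.05) {
  wn <- seq(7500, 4000, length.out = 200)
  synthetic_config(
    class_names = c("A", "B"), n_per_class = n_per_class,
    grid_points = 200L, grid_range = c(7500, 4000),
    shared_bands = data.frame(center = 5750, width = 400,
                              amplitude = 0.05, amplitude_sd = 0.01),
    class_bands = list(
      A = data.frame(center = wn[c(30, 80)], width = 18,
                     amplitude = c(0.30, 0.25), amplitude_sd = 0.03),
      B = data.frame(center = wn[c(120, 170)], width = 18,
                     amplitude = c(0.30, 0.25), amplitude_sd = 0.03)),
    baseline_intercept = c(A = 0.30, B = 0.32),
    noise_sd = noise_sd, seed = 1L)
}

# Exact distribution of a sum of independent hypergeometric draws
# (successes among m marked features when k_r are drawn from p_total),
# by direct convolution of the exact single-draw pmfs.
hyper_sum_upper_p <- function(observed, draws, m, p_total) {
  pmf <- c(1)
  for (k in draws) {
    xs <- 0:min(k, m)
    d <- stats::dhyper(xs, m, p_total - m, k)
    new <- numeric(length(pmf) + length(xs) - 1)
    for (j in seq_along(xs))
      new[j:(j + length(pmf) - 1)] <- new[j:(j + length(pmf) - 1)] + d[j] * pmf
    pmf <- new
  }
  sum(pmf[(observed + 1):length(pmf)])
}
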