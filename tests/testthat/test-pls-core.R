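test_that("a rank-1 predictor matrix is exhausted by one component", {
  set.seed(1)
  X <- outer(rnorm(8), rnorm(5))
  Y <- matrix(rnorm(16), 8, 2)
  m <- fit_pls2(X, Y, 1)
  Xc <- sweep(X, 2, m$x_mean)
  resid <- Xc - tcrossprod(m$x_scores, m$x_loadings)
  expect_lt(max(abs(resid)), 1e-8 * max(abs(X)))
  expect_error(fit_pls2(X, Y, 3), "rank")
})

test_that("full-rank PLS2 predictions match the least-squares oracle", {
  set.seed(2)
  X <- matrix(rnorm(60), 10, 6)
  Y <- matrix(rnorm(30), 10, 3)
  m <- fit_pls2(X, Y, 6)
  ols <- oracle_ols_predict(X, Y, X)
  expect_lt(max(abs(predict_pls2(m, X, 6) - ols)) / max(abs(ols)), 1e-6)
  # single response: coefficients themselves match least squares
  y <- matrix(rnorm(10))
  m1 <- fit_pls2(X, y, 6)
  Xc <- sweep(X, 2, colMeans(X))
  b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  b_pls <- pls2_coefficients(m1, 6)$coefficients
  expect_lt(max(abs(b_pls - b_ols)), 1e-6 * max(abs(b_ols)))
  expect_identical(sign(round(b_pls, 8)), sign(round(b_ols, 8)))
})

test_that("decomposition agrees with a literal textbook NIPALS oracle up to sign", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:12, 1); p <- sample(3:12, 1); K <- sample(2:4, 1)
    A <- min(n - 1, p, 4)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * K), n, K)
    m <- fit_pls2(X, Y, A)
    o <- oracle_nipals_pls2(X, Y, A)
    expect_equal_up_to_sign(m$weights, o$weights, 1e-8)
    expect_equal_up_to_sign(m$x_scores, o$x_scores, 1e-7)
    expect_equal_up_to_sign(m$x_loadings, o$x_loadings, 1e-7)
    expect_lt(max(abs(predict_pls2(m, X, A) - oracle_nipals_predict(o, X))), 1e-8)
    # score orthogonality
    G <- crossprod(m$x_scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
  }
})

test_that("predictions agree with the mixOmics regression-mode PLS cross-check", {
  skip_if_not_installed("mixOmics")
  set.seed(2)
  X <- matrix(rnorm(120), 15, 8); Y <- matrix(rnorm(45), 15, 3)
  colnames(X) <- paste0("x", 1:8); colnames(Y) <- paste0("y", 1:3)
  p1 <- predict_pls2(fit_pls2(X, Y, 4), X, 4)
  mo <- mixOmics::pls(X, Y, ncomp = 4, scale = FALSE, mode = "regression")
  p2 <- predict(mo, X)$predict[, , 4]
  expect_lt(max(abs(p1 - p2)), 1e-8)
})

test_that("prediction at the mean spectrum returns the mean response exactly", {
  set.seed(3)
  X <- matrix(rnorm(40), 8, 5); Y <- matrix(rnorm(24), 8, 3)
  m <- fit_pls2(X, Y, 3)
  expect_equal(drop(predict_pls2(m, matrix(m$x_mean, 1), 3)), m$y_mean,
               tolerance = 1e-12)
  expect_error(predict_pls2(m, matrix(1, 2, 4)), "4 columns")
})

test_that("the coefficient affine map reproduces predictions at every a", {
  set.seed(4)
  X <- matrix(rnorm(70), 10, 7); Y <- matrix(rnorm(20), 10, 2)
  m <- fit_pls2(X, Y, 5)
  X_new <- matrix(rnorm(100 * 7), 100, 7)
  for (a in c(1, 3, 5)) {
    cf <- pls2_coefficients(m, a)
    lin <- sweep(X_new %*% cf$coefficients, 2, cf$intercept, `+`)
    expect_lt(max(abs(lin - predict_pls2(m, X_new, a))), 1e-10)
  }
  expect_error(pls2_coefficients(m, 6), "outside")
})

test_that("a duplicated collinear feature column never breaks fitting", {
  set.seed(5)
  X <- matrix(rnorm(50), 10, 5)
  X2 <- cbind(X, X[, 3])
  Y <- matrix(rnorm(20), 10, 2)
  m <- fit_pls2(X2, Y, 4)
  expect_true(all(is.finite(predict_pls2(m, X2, 4))))
})

test_that("VIP scores satisfy the normalization identity and closed forms", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(9 * 7), 9, 7); Y <- matrix(rnorm(9 * 3), 9, 3)
    m <- fit_pls2(X, Y, 4)
    for (a in c(1, 2, 4)) {
      v <- vip_scores(m, a)
      expect_true(all(v$scores >= 0))
      expect_equal(colSums(v$scores^2), rep(7, 3), tolerance = 1e-10)
    }
    # a = 1: VIP is sqrt(p) |w_1| / ||w_1||, identical for every class
    v1 <- vip_scores(m, 1)$scores
    closed <- sqrt(7) * abs(m$weights[, 1]) / sqrt(sum(m$weights[, 1]^2))
    expect_equal(v1[, 1], closed, tolerance = 1e-12)
    expect_equal(v1[, 2], v1[, 1], tolerance = 1e-12)
  }
})

test_that("a feature with zero weight in all components has VIP 0", {
  set.seed(6)
  X <- cbind(matrix(rnorm(40), 8, 5), 0)  # constant column: centered to zero
  Y <- matrix(rnorm(16), 8, 2)
  m <- fit_pls2(X, Y, 3)
  expect_equal(vip_scores(m, 3)$scores[6, ], c(0, 0), tolerance = 1e-12)
})

test_that("high-VIP selection respects thresholds and class-band structure", {
  set.seed(7)
  X <- matrix(rnorm(12 * 6), 12, 6); Y <- matrix(rnorm(12 * 2), 12, 2)
  v <- vip_scores(fit_pls2(X, Y, 3), 3)
  all_feats <- high_vip_features(v, threshold = 0)
  expect_true(all(vapply(all_feats$per_class, length, 0L) == 6))
  expect_identical(all_feats$intersection, 1:6)
  none <- high_vip_features(v, threshold = max(v$scores) + 1)
  expect_true(all(vapply(none$per_class, length, 0L) == 0))
  expect_length(none$intersection, 0)
  # three classes with disjoint informative bands: each class's list keeps
  # its own band, and the cross-class intersection drops the bands specific
  # to the well-separated outer classes
  set.seed(8)
  n <- 45
  cls <- rep(c("A", "B", "C"), each = 15)
  X <- matrix(rnorm(n * 12, sd = 0.1), n, 12)
  X[cls == "A", 1:2] <- X[cls == "A", 1:2] + 2
  X[cls == "B", 5:6] <- X[cls == "B", 5:6] + 2
  X[cls == "C", 9:10] <- X[cls == "C", 9:10] + 2
  Y <- encode_indicator(cls, c("A", "B", "C"))
  v <- vip_scores(fit_pls2(X, Y, 2), 2)
  hi <- high_vip_features(v, 1)
  expect_true(all(c(1, 2) %in% hi$per_class[[1]]))
  expect_true(all(c(9, 10) %in% hi$per_class[[3]]))
  expect_false(any(c(9, 10) %in% hi$per_class[[1]]))
  expect_false(any(c(1, 2) %in% hi$per_class[[3]]))
  expect_false(any(c(1, 2, 9, 10) %in% hi$intersection))
  # pure-noise features are never flagged as important
  expect_false(any(c(3, 4, 7, 8, 11, 12) %in% unlist(hi$per_class)))
})

test_that("degenerate inputs fail loudly", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_pls2(X, matrix(1, 5, 2), 2), "zero variance")
  expect_error(fit_pls2(X, matrix(rnorm(10), 5, 2), 5), "outside")
  expect_error(fit_pls2(X[1, , drop = FALSE], matrix(1, 1, 1), 1), "2 samples")
})
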