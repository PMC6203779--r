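test_that("single-component GMM equals sample moments exactly", {
  set.seed(1)
  x <- rnorm(200, 3, 2)
  f <- fit_gmm_1d(x, K = 1)
  expect_equal(f$means, mean(x))
  expect_equal(f$variances, mean((x - mean(x))^2))
  expect_equal(f$bic, -2 * f$loglik + 2 * log(200))
  expect_error(fit_gmm_1d(x[1:3], K = 5), "exceeds")
})

test_that("BIC selects the generating component number on separated mixtures", {
  set.seed(10)
  x2 <- c(rnorm(1000, 0, 1), rnorm(1000, 4, 1))
  s2 <- select_k(x2, K_range = 1:4, n_init = 5, seed = 1)
  expect_equal(s2$best_k, 2L)
  x1 <- rnorm(2000)
  s1 <- select_k(x1, K_range = 1:4, n_init = 5, seed = 1)
  expect_equal(s1$best_k, 1L)
  # tie-break goes to the smaller K (first minimum)
  expect_equal(names(which.min(s2$bic)), "2")
})

test_that("1-D GMM agrees with an independent EM implementation (mclust)", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(8)
  x <- c(rnorm(600, -1, 0.7), rnorm(400, 3, 1.2))
  ours <- fit_gmm_1d(x, K = 2, n_init = 10, seed = 2)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("partial correlation matches the regress-out-residuals oracle", {
  residual_pcor <- function(X, i, j) {
    R <- apply(X, 2, rank)
    others <- R[, -c(i, j), drop = FALSE]
    ri <- resid(lm(R[, i] ~ others))
    rj <- resid(lm(R[, j] ~ others))
    cor(ri, rj)
  }
  set.seed(12)
  for (rep in 1:20) {
    X <- matrix(rnorm(80 * 6), 80, 6) %*% matrix(rnorm(36), 6, 6)
    P <- partial_correlation(X)
    expect_equal(dim(P), c(6L, 6L))
    expect_equal(diag(P), rep(1, 6))
    expect_equal(P, t(P), tolerance = 1e-12)
    for (pair in list(c(1, 2), c(3, 6))) {
      expect_equal(P[pair[1], pair[2]],
                   residual_pcor(X, pair[1], pair[2]), tolerance = 1e-8)
    }
  }
})

test_that("partial correlation separates conditional from marginal dependence", {
  set.seed(13)
  n <- 5000
  Z <- rnorm(n)
  X <- Z + rnorm(n); Y <- Z + rnorm(n)
  P <- partial_correlation(cbind(X = X, Y = Y, Z = Z))
  expect_lt(abs(P["X", "Y"]), 0.05)
  expect_gt(cor(X, Y, method = "spearman"), 0.4)
  # 2 columns: partial correlation is plain Spearman correlation
  P2 <- partial_correlation(cbind(X, Y))
  expect_equal(P2[1, 2], cor(X, Y, method = "spearman"))
  # rank-based: invariant under strictly monotone transforms
  P3 <- partial_correlation(cbind(X = exp(X), Y = Y, Z = Z^3 + Z))
  expect_equal(P3, P, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("K=1 mixture of regressions is exactly ordinary least squares", {
  set.seed(14)
  X <- matrix(rnorm(200), 100, 2)
  y <- 1 + X %*% c(0.5, -0.3) + rnorm(100, 0, 0.2)
  m <- fit_mixture_linear(X, y, K = 1)
  ols <- lm(y ~ scale(X))
  expect_equal(unname(m$coefficients[1, ]), unname(coef(ols)),
               tolerance = 1e-10)
  expect_error(fit_mixture_linear(cbind(X, NA), y, K = 1), "non-finite")
})

test_that("two-component regression mixture recovers planted regimes", {
  set.seed(15)
  n <- 1000
  comp <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(2 * n), n, 2)
  y <- ifelse(comp == 1,
              3 + 0.9 * X[, 1] + 0.1 * X[, 2],
              -1 + 0.2 * X[, 1] + 0.8 * X[, 2]) + rnorm(n, 0, 0.4)
  m <- fit_mixture_linear(X, y, K = 2, n_init = 10, seed = 4)
  # match fitted to true components by intercept
  k1 <- which.max(m$coefficients[, 1])
  ord <- c(k1, 3 - k1)
  expect_equal(unname(m$coefficients[ord, 1]), c(3, -1), tolerance = 0.15)
  acc <- mean((m$assignment == k1) == (comp == 1))
  expect_gt(acc, 0.9)
  # responsibilities sum to 1; assignment is their argmax
  expect_true(all(abs(rowSums(m$responsibilities) - 1) < 1e-9))
  expect_equal(m$assignment, max.col(m$responsibilities, ties.method = "first"))
  # determinism under identical seed
  m2 <- fit_mixture_linear(X, y, K = 2, n_init = 10, seed = 4)
  expect_identical(m$coefficients, m2$coefficients)
  # log-likelihood of the kept fit exceeds any collapsed alternative
  expect_true(is.finite(m$loglik))
})

test_that("predictions follow the assigned component's linear model", {
  set.seed(16)
  X <- matrix(rnorm(400), 200, 2)
  y <- ifelse(X[, 1] > 0, 2 + X[, 1], -2 - X[, 1]) + rnorm(200, 0, 0.3)
  m <- fit_mixture_linear(X, y, K = 2, seed = 1)
  p <- predict_directionality(m, X, y = y)
  X1 <- cbind(1, sweep(sweep(X, 2, m$center), 2, m$scale, "/"))
  manual <- (X1 %*% t(m$coefficients))[cbind(1:200, p$component)]
  expect_equal(p$predicted, unname(manual))
  expect_setequal(unique(p$class), m$component_labels[unique(p$component)])
  # without y, the mixing-weight-averaged prediction is returned
  p0 <- predict_directionality(m, X)
  manual0 <- as.numeric((X1 %*% t(m$coefficients)) %*% m$weights)
  expect_equal(p0$predicted, manual0)
  expect_true(all(is.na(p0$component)))
  expect_error(predict_directionality(m, X * NA), "non-finite")
})

test_that("cross-validation is exact on noiseless data and null on noise", {
  set.seed(17)
  X <- matrix(rnorm(600), 300, 2)
  colnames(X) <- c("a", "b")
  y <- 2 + X %*% c(1, -0.5)
  cv <- cross_validate(X, as.numeric(y), folds = 5, seed = 1, n_init = 3)
  expect_true(all(abs(cv$per_fold$cor[cv$per_fold$feature_set == "both"] - 1) <
                    1e-6))
  expect_setequal(unique(cv$per_fold$feature_set), c("both", "a", "b"))

  y0 <- rnorm(2000)
  X0 <- matrix(rnorm(4000), 2000, 2)
  cv0 <- cross_validate(X0, y0, folds = 10, seed = 2, n_init = 3,
                        feature_sets = list(both = 1:2))
  expect_lt(abs(mean(cv0$per_fold$cor)), 0.1)
  expect_error(cross_validate(X[1:20, ], y[1:20], folds = 10, seed = 1),
               "fewer than 3|folds")
})

test_that("adjusted Rand index matches mclust and behaves at the extremes", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, rev(a)), adjusted_rand_index(rev(a), a))
  set.seed(18)
  b <- sample(1:3, 30, replace = TRUE)
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
})
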