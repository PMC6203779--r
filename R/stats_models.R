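# Statistical models: 1-D Gaussian mixtures with BIC-based component-number
# selection for directionality ratios, Spearman partial correlations over
# directional feature tables, and the two-component mixture-of-linear-models
# directionality predictor with 10-fold cross-validation.

#' Fit a 1-D Gaussian mixture by EM
#'
#' Unequal-variance mixture fitted by expectation-maximisation; the best of
#' \code{n_init} seeded random restarts (quantile-spread means with jitter)
#' is kept. BIC is computed as \eqn{-2\ln L + p \ln n} with
#' \eqn{p = 3K - 1} free parameters (K means, K variances, K-1 weights), so
#' smaller BIC is better.
#'
#' @param values Numeric vector (e.g. pseudo-counted log2 directionality
#'   ratios).
#' @param K Number of components.
#' @param n_init Number of restarts (default 10).
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule.
#' @return A \code{gmm1d}: \code{weights}, \code{means}, \code{variances},
#'   \code{loglik}, \code{bic}, \code{responsibilities}.
#' @export
fit_gmm_1d <- function(values, K, n_init = 10L, seed = 1L, max_iter = 500L,
                       tol = 1e-8) {
  n <- length(values)
  if (K > n) stop("K exceeds the number of observations")
  if (K == 1L) {
    mu <- mean(values)
    v <- mean((values - mu)^2)
    ll <- sum(stats::dnorm(values, mu, sqrt(v), log = TRUE))
    return(structure(list(K = 1L, weights = 1, means = mu, variances = v,
                          loglik = ll, bic = -2 * ll + 2 * log(n),
                          responsibilities = matrix(1, n, 1)),
                     class = "gmm1d"))
  }
  set.seed(seed)
  var_floor <- 1e-6 * stats::var(values) + 1e-12
  best <- NULL
  for (init in seq_len(n_init)) {
    mu <- stats::quantile(values, probs = (seq_len(K) - 0.5) / K,
                          names = FALSE) +
      stats::rnorm(K, 0, stats::sd(values) / 4)
    v <- rep(stats::var(values) / K, K)
    w <- rep(1 / K, K)
    ll_prev <- -Inf
    for (iter in seq_len(max_iter)) {
      dens <- vapply(seq_len(K), function(k)
        w[k] * stats::dnorm(values, mu[k], sqrt(v[k])), numeric(n))
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      resp <- dens / tot
      ll <- sum(log(tot))
      nk <- colSums(resp)
      nk[nk == 0] <- .Machine$double.eps
      w <- nk / n
      mu <- colSums(resp * values) / nk
      v <- pmax(colSums(resp * (values - rep(mu, each = n))^2) / nk,
                var_floor)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) break
      ll_prev <- ll
    }
    if (is.null(best) || ll > best$loglik) {
      best <- list(weights = w, means = mu, variances = v, loglik = ll,
                   responsibilities = resp)
    }
  }
  ord <- order(best$means)
  p <- 3 * K - 1
  structure(list(K = K, weights = best$weights[ord], means = best$means[ord],
                 variances = best$variances[ord], loglik = best$loglik,
                 bic = -2 * best$loglik + p * log(n),
                 responsibilities = best$responsibilities[, ord, drop = FALSE]),
            class = "gmm1d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat(sprintf("gmm1d: K = %d, loglik = %.2f, BIC = %.2f\n", x$K, x$loglik,
              x$bic))
  print(round(rbind(weight = x$weights, mean = x$means, sd = sqrt(x$variances)), 3))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits \code{fit_gmm_1d} for each K in \code{K_range} and returns the K
#' minimising BIC; ties resolve to the smaller K.
#'
#' @inheritParams fit_gmm_1d
#' @param K_range Candidate component numbers (default 1:5).
#' @return List with \code{best_k}, \code{bic} (named vector), and
#'   \code{fits}.
#' @export
select_k <- function(values, K_range = 1:5, n_init = 10L, seed = 1L) {
  fits <- lapply(K_range, function(K)
    fit_gmm_1d(values, K, n_init = n_init, seed = seed + K))
  bic <- vapply(fits, `[[`, 0, "bic")
  names(bic) <- K_range
  best_k <- K_range[which.min(bic)]  # which.min takes the first minimum
  list(best_k = best_k, bic = bic, fits = fits)
}

#' Spearman partial correlations
#'
#' Columns are rank-transformed (average ranks on ties); the partial
#' correlation of each pair given all remaining columns comes from the
#' inverse of the rank correlation matrix:
#' \eqn{\rho_{ij\cdot rest} = -P_{ij} / \sqrt{P_{ii} P_{jj}}}. A singular
#' correlation matrix falls back to the Moore-Penrose pseudoinverse with a
#' warning.
#'
#' @param features Numeric matrix or data.frame, one column per feature.
#' @return Symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_correlation <- function(features) {
  X <- as.matrix(features)
  if (ncol(X) < 3L) {
    if (ncol(X) == 2L) {
      r <- stats::cor(X[, 1], X[, 2], method = "spearman")
      out <- matrix(c(1, r, r, 1), 2, 2,
                    dimnames = list(colnames(X), colnames(X)))
      return(out)
    }
    stop("need at least 2 feature columns")
  }
  if (nrow(X) <= ncol(X) + 2L) stop("need n > #features + 2 observations")
  R <- stats::cor(apply(X, 2L, rank), method = "pearson")
  P <- tryCatch(solve(R), error = function(e) {
    warning("rank correlation matrix is singular; using pseudoinverse")
    MASS::ginv(R)
  })
  D <- sqrt(diag(P))
  out <- -P / outer(D, D)
  diag(out) <- 1
  dimnames(out) <- list(colnames(X), colnames(X))
  out
}

# ---- mixture of linear regressions -----------------------------------------

.mixlm_loglik <- function(X1, y, coef, sigma2, weights) {
  K <- length(weights)
  dens <- vapply(seq_len(K), function(k)
    weights[k] * stats::dnorm(y, X1 %*% coef[k, ], sqrt(sigma2[k])),
    numeric(length(y)))
  tot <- rowSums(dens)
  tot[tot == 0] <- .Machine$double.xmin
  list(loglik = sum(log(tot)), resp = dens / tot)
}

#' Fit a mixture of linear regressions by EM
#'
#' K Gaussian-error linear regressions of \code{y} on the predictors, with
#' responsibilities updated from the component densities and per-component
#' weighted least squares in the M step. Predictors are standardised
#' internally (training mean/sd stored on the model); the response is not.
#' The best of \code{n_init} seeded restarts by log-likelihood is kept, and
#' a restart whose smallest component weight collapses below 1/n is
#' discarded with a warning. With \code{K = 1} the fit is exactly ordinary
#' least squares.
#'
#' @param X Numeric matrix or data.frame of predictors (e.g. log2
#'   forward/reverse core-promoter score ratio and H3K4me3 ratio).
#' @param y Measured log2 directionality ratio.
#' @param K Number of components (default 2).
#' @param n_init Number of restarts (default 10).
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule.
#' @return A \code{mixlm}: per-component \code{coefficients} (rows;
#'   intercept first), \code{sigma2}, \code{weights},
#'   \code{responsibilities}, \code{assignment}, \code{component_labels}
#'   ("skewed" for the component with larger mean |fitted ratio|, otherwise
#'   "balanced"), and the standardisation moments.
#' @export
fit_mixture_linear <- function(X, y, K = 2L, n_init = 10L, seed = 1L,
                               max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  n <- nrow(X)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  X1 <- cbind(`(Intercept)` = 1, Xs)
  if (K == 1L) {
    fit <- stats::lm.fit(X1, y)
    res <- fit$residuals
    sigma2 <- mean(res^2)
    ll <- sum(stats::dnorm(y, y - res, sqrt(sigma2), log = TRUE))
    coef <- matrix(fit$coefficients, 1L, dimnames = list("comp1", colnames(X1)))
    model <- list(K = 1L, coefficients = coef, sigma2 = sigma2, weights = 1,
                  responsibilities = matrix(1, n, 1), assignment = rep(1L, n),
                  loglik = ll, center = center, scale = scale,
                  component_labels = "skewed")
    class(model) <- "mixlm"
    return(model)
  }
  set.seed(seed)
  best <- NULL
  attempts <- 0L
  while (attempts < 4L * n_init && (is.null(best) || attempts < n_init)) {
    attempts <- attempts + 1L
    if (attempts %% 2L == 1L) {
      # soft split along the response: the natural starting point for an
      # explanatory mixture over a (possibly bimodal) ratio distribution
      cut <- stats::quantile(y, stats::runif(1, 0.25, 0.75), names = FALSE)
      z <- stats::plogis((y - cut) / (0.25 * stats::sd(y)))
      resp <- cbind(1 - z, z)
      if (K > 2L) {
        resp <- cbind(resp, matrix(stats::runif(n * (K - 2L)), n))
        resp <- resp / rowSums(resp)
      }
    } else {
      resp <- matrix(stats::rgamma(n * K, shape = 1), n, K)
      resp <- resp / rowSums(resp)
    }
    coef <- matrix(0, K, ncol(X1))
    sigma2 <- rep(stats::var(y), K)
    weights <- rep(1 / K, K)
    ll_prev <- -Inf
    collapsed <- FALSE
    for (iter in seq_len(max_iter)) {
      for (k in seq_len(K)) {
        wf <- stats::lm.wfit(X1, y, w = resp[, k] + 1e-10)
        coef[k, ] <- wf$coefficients
        sigma2[k] <- max(sum(resp[, k] * wf$residuals^2) / sum(resp[, k]),
                         1e-10)
      }
      weights <- colMeans(resp)
      if (any(weights < 1 / n)) { collapsed <- TRUE; break }
      e <- .mixlm_loglik(X1, y, coef, sigma2, weights)
      resp <- e$resp
      if (is.finite(ll_prev) &&
          abs(e$loglik - ll_prev) < tol * abs(ll_prev)) { ll_prev <- e$loglik; break }
      ll_prev <- e$loglik
    }
    if (collapsed) {
      warning("mixture component collapsed; restarting")
      next
    }
    if (is.null(best) || ll_prev > best$loglik) {
      best <- list(coefficients = coef, sigma2 = sigma2, weights = weights,
                   loglik = ll_prev, responsibilities = resp)
    }
  }
  if (is.null(best)) stop("all EM restarts collapsed")
  dimnames(best$coefficients) <- list(paste0("comp", seq_len(K)), colnames(X1))
  assignment <- max.col(best$responsibilities, ties.method = "first")
  fitted_k <- X1 %*% t(best$coefficients)
  mean_abs <- vapply(seq_len(K), function(k)
    stats::weighted.mean(abs(fitted_k[, k]), best$responsibilities[, k]), 0)
  labels <- rep("balanced", K)
  labels[which.max(mean_abs)] <- "skewed"
  model <- c(best, list(K = K, assignment = assignment, center = center,
                        scale = scale, component_labels = labels))
  class(model) <- "mixlm"
  model
}

#' @export
print.mixlm <- function(x, ...) {
  cat(sprintf("mixlm: K = %d, loglik = %.2f\n", x$K, x$loglik))
  tab <- cbind(x$coefficients, sigma = sqrt(x$sigma2), weight = x$weights)
  rownames(tab) <- paste0(rownames(x$coefficients), " (", x$component_labels, ")")
  print(round(tab, 3))
  invisible(x)
}

#' Predict directionality ratios from a fitted mixture of regressions
#'
#' When the measured ratio \code{y} is supplied, each region is assigned to
#' the mixture component with the higher responsibility (computed from the
#' full component densities — the explanatory clustering used when the model
#' is applied to observed data) and that component's linear prediction is
#' used. Without \code{y} there is no information to assign components, so
#' the mixing-weight-averaged prediction over components is returned
#' (\code{component} and \code{class} are \code{NA}); this is the honest
#' out-of-sample predictor used by \code{\link{cross_validate}}.
#'
#' @param model A \code{mixlm}.
#' @param X Predictor matrix on the original (unstandardised) scale.
#' @param y Optional measured response used for component assignment.
#' @return data.frame with \code{predicted} (log2 ratio), \code{component},
#'   and \code{class} ("skewed"/"balanced").
#' @export
predict_directionality <- function(model, X, y = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite features")
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  X1 <- cbind(1, Xs)
  pred_k <- X1 %*% t(model$coefficients)
  if (model$K == 1L) {
    return(data.frame(predicted = pred_k[, 1], component = 1L,
                      class = model$component_labels))
  }
  if (!is.null(y)) {
    resp <- .mixlm_loglik(X1, y, model$coefficients, model$sigma2,
                          model$weights)$resp
    comp <- max.col(resp, ties.method = "first")
    return(data.frame(predicted = pred_k[cbind(seq_len(nrow(X1)), comp)],
                      component = comp,
                      class = model$component_labels[comp]))
  }
  data.frame(predicted = as.numeric(pred_k %*% model$weights),
             component = NA_integer_, class = NA_character_)
}

#' Cross-validated predictive ability of the directionality model
#'
#' Splits the data into \code{folds} equal parts; for each fold the mixture
#' of regressions is fitted on the remainder and the held-out regions'
#' ratios are predicted without access to their measured values (the
#' mixing-weight-averaged component prediction), recording the Pearson
#' correlation of predicted vs. measured ratio. This is run for each
#' feature subset in \code{feature_sets} (by default: both predictors,
#' first only, second only).
#'
#' @inheritParams fit_mixture_linear
#' @param folds Number of folds (default 10).
#' @param feature_sets Named list of column index/name vectors.
#' @return List with \code{per_fold} (data.frame feature_set/fold/cor) and
#'   \code{summary} (mean correlation per feature set).
#' @export
cross_validate <- function(X, y, K = 2L, folds = 10L, seed = 1L,
                           n_init = 5L, feature_sets = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (is.null(feature_sets)) {
    feature_sets <- c(list(both = colnames(X)),
                      stats::setNames(as.list(colnames(X)), colnames(X)))
  }
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  if (min(table(fold_id)) < 3L) stop("folds with fewer than 3 observations")
  rows <- list()
  for (fs in names(feature_sets)) {
    cols <- feature_sets[[fs]]
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- fit_mixture_linear(X[tr, cols, drop = FALSE], y[tr], K = K,
                              n_init = n_init, seed = seed + f)
      p <- predict_directionality(m, X[!tr, cols, drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(feature_set = fs, fold = f,
                   cor = stats::cor(p$predicted, y[!tr]))
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- stats::aggregate(cor ~ feature_set, per_fold, mean)
  list(per_fold = per_fold, summary = summary)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Adjusted Rand index (1 = identical partitions, ~0 = random).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}
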