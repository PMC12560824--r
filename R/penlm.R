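#' Penalized linear model (OLS / ridge / lasso)
#'
#' Fits the linear model y = b0 + X b by minimizing the elastic-net-family
#' objective
#'
#'   (1/(2n)) * sum((y - b0 - X b)^2) + lambda * (a*||b||_1 + ((1-a)/2)*||b||_2^2)
#'
#' with a = 1 (lasso), a = 0 (ridge), or no penalty (OLS). The intercept is
#' never penalized. Predictor columns are internally centred and scaled to
#' unit variance (denominator n, the convention under which the single-
#' predictor closed forms b = rho/(1+lambda) for ridge and the soft threshold
#' max(|rho|-lambda, 0)*sign(rho) for lasso hold exactly); coefficients are
#' reported back on the caller's original predictor scale. Constant predictor
#' columns receive coefficient 0 silently.
#'
#' @param x numeric matrix, conditions in rows, predictors in columns.
#' @param y numeric response vector, length nrow(x).
#' @param penalty one of "ols", "ridge", "lasso".
#' @param lambda penalty strength (>= 0); ignored for "ols".
#' @return an object of class `penlm` with components `intercept`,
#'   `coefficients` (named, original scale), `penalty`, `lambda`,
#'   `standardization` (center/scale/kept), `fitted.values`, `residuals`.
#' @seealso [cv_penlm()] for lambda selection by cross-validation.
#' @export
penlm <- function(x, y, penalty = c("ols", "ridge", "lasso"), lambda = 0) {
  penalty <- match.arg(penalty)
  x <- as_predictor_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("NaN/NA input is not allowed")
  if (n < 3L) stop("need at least 3 observations")
  if (lambda < 0) stop("lambda must be >= 0")

  if (penalty == "ols") {
    fit <- ols_fit(x, y)
    b <- fit$beta
    b0 <- fit$intercept
    std <- list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)),
                kept = rep(TRUE, ncol(x)))
    lambda <- 0
  } else {
    std <- standardize_cols(x)
    yc <- y - mean(y)
    bs <- if (!any(std$kept)) {
      numeric(0)
    } else if (penalty == "ridge") {
      drop(ridge_path(std$xs, yc, lambda))
    } else {
      drop(lasso_path(std$xs, yc, lambda))
    }
    b <- numeric(ncol(x))
    b[std$kept] <- bs / std$scale[std$kept]
    b0 <- mean(y) - sum(b * std$center)
  }
  names(b) <- colnames(x)
  fitted <- drop(b0 + x %*% b)
  structure(list(
    intercept = b0,
    coefficients = b,
    penalty = penalty,
    lambda = lambda,
    standardization = std[c("center", "scale", "kept")],
    fitted.values = fitted,
    residuals = y - fitted,
    nobs = n
  ), class = "penlm")
}

as_predictor_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  x
}

# column means and population (denominator n) sds; near-constant columns dropped
standardize_cols <- function(x) {
  n <- nrow(x)
  center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  scale <- sqrt(colSums(xc^2) / n)
  kept <- scale > 1e-10 * (abs(center) + 1)
  xs <- sweep(xc[, kept, drop = FALSE], 2L, scale[kept], "/")
  list(center = center, scale = scale, kept = kept, xs = xs)
}

ols_fit <- function(x, y) {
  xm <- cbind(`(Intercept)` = 1, x)
  qr_fit <- qr(xm)
  if (qr_fit$rank < ncol(xm)) {
    stop("rank-deficient design: OLS requires full column rank (use ridge or lasso)")
  }
  cf <- qr.coef(qr_fit, y)
  list(intercept = cf[[1]], beta = cf[-1])
}

# ridge solution path via one SVD: b(lambda) = V diag(d/(d^2 + n*lambda)) U'y
# (minimizer of (1/(2n))||yc - Xs b||^2 + (lambda/2)||b||^2)
ridge_path <- function(xs, yc, lambdas) {
  n <- nrow(xs)
  sv <- svd(xs)
  uty <- drop(crossprod(sv$u, yc))
  shrink <- outer(sv$d, lambdas, function(d, l) d / (d^2 + n * l))
  sv$v %*% (shrink * uty)  # p x length(lambdas)
}

# lasso path by cyclic coordinate descent with covariance updates, warm
# starts, and a KKT-guided active set. Columns are standardized so the
# coordinate update is an exact soft threshold (G[j,j] = 1). A sweep cap
# bounds the work in the degenerate small-lambda regime (p > n, non-unique
# minimizer) where cyclic descent drifts along flat directions.
lasso_path <- function(xs, yc, lambdas, tol = 1e-10, max_sweeps = 200L) {
  n <- nrow(xs)
  G <- crossprod(xs) / n
  cvec <- drop(crossprod(xs, yc)) / n
  ord <- order(lambdas, decreasing = TRUE)
  res <- lasso_cd_path(G, cvec, lambdas[ord], tol, max_sweeps)
  res[, order(ord), drop = FALSE]
}

soft_threshold <- function(z, lam) sign(z) * max(abs(z) - lam, 0)

#' Lambda path scaffold
#'
#' Log-spaced sequence of `nlambda` values from lambda_max (the smallest
#' penalty at which the lasso solution is entirely zero,
#' max |(1/n) x_std' y_centered|) down to `lambda_max * min_ratio`. Ridge
#' shares the same scaffold.
#'
#' @param x predictor matrix; @param y response.
#' @param nlambda path length (default 100).
#' @param min_ratio ratio of smallest to largest lambda (default 1e-4).
#' @return decreasing numeric vector.
#' @export
lambda_path <- function(x, y, nlambda = 100L, min_ratio = 1e-4) {
  x <- as_predictor_matrix(x)
  std <- standardize_cols(x)
  yc <- y - mean(y)
  if (!any(std$kept)) return(rev(exp(seq(log(1e-3 * min_ratio), log(1e-3), length.out = nlambda))))
  lmax <- max(abs(drop(crossprod(std$xs, yc)) / nrow(x)))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Fit with penalty strength chosen by inner cross-validation
#'
#' Splits the data into `nfolds` random folds (capped at n), fits the whole
#' lambda path on each training part, and picks the lambda minimizing the mean
#' squared out-of-fold error (minimum-CV rule, not 1-SE; ties resolved toward
#' the larger, more regularized lambda). The final model is refit on all
#' provided data at the chosen lambda. A constant response cannot be
#' cross-validated and is an error; callers skip such reactions.
#'
#' @param x,y training data.
#' @param penalty "ridge" or "lasso".
#' @param lambdas candidate path; defaults to [lambda_path()] on (x, y).
#' @param nfolds inner fold count (default 10, capped at n).
#' @param seed integer seed for the fold assignment.
#' @return object of class `cv_penlm`: the chosen-`lambda` refit (`fit`),
#'   `lambda_min`, `lambdas`, `cvm` (mean CV error per lambda).
#' @export
cv_penlm <- function(x, y, penalty = c("ridge", "lasso"), lambdas = NULL,
                     nfolds = 10L, seed = 1L) {
  penalty <- match.arg(penalty)
  x <- as_predictor_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 observations for lambda cross-validation")
  if (max(y) - min(y) == 0) stop("constant response")
  if (is.null(lambdas)) lambdas <- lambda_path(x, y)
  lambdas <- sort(as.numeric(lambdas), decreasing = TRUE)
  nfolds <- max(2L, min(nfolds, n))
  fold_id <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  sse <- numeric(length(lambdas))
  for (f in seq_len(nfolds)) {
    test <- fold_id == f
    preds <- path_predict(x[!test, , drop = FALSE], y[!test],
                          x[test, , drop = FALSE], penalty, lambdas)
    sse <- sse + colSums((preds - y[test])^2)
  }
  cvm <- sse / n
  best <- which(cvm <= min(cvm) + 1e-15)[1]  # ties -> largest lambda
  fit <- penlm(x, y, penalty = penalty, lambda = lambdas[best])
  structure(list(fit = fit, lambda_min = lambdas[best],
                 lambdas = lambdas, cvm = cvm, nfolds = nfolds),
            class = "cv_penlm")
}

# fit the path on training data, return test predictions (n_test x n_lambda)
path_predict <- function(xtr, ytr, xte, penalty, lambdas) {
  std <- standardize_cols(xtr)
  ytr_mean <- mean(ytr)
  yc <- ytr - ytr_mean
  if (!any(std$kept)) {
    return(matrix(ytr_mean, nrow(xte), length(lambdas)))
  }
  bs <- if (penalty == "ridge") ridge_path(std$xs, yc, lambdas)
        else lasso_path(std$xs, yc, lambdas)
  xte_s <- sweep(sweep(xte[, std$kept, drop = FALSE], 2L, std$center[std$kept], "-"),
                 2L, std$scale[std$kept], "/")
  ytr_mean + xte_s %*% bs
}

#' @export
predict.penlm <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  nm <- names(object$coefficients)
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), nm)) {
      stop("newdata predictors do not match the training predictors")
    }
    x <- x[, nm, drop = FALSE]
  } else if (ncol(x) != length(nm)) {
    stop("newdata has ", ncol(x), " columns, model expects ", length(nm))
  }
  drop(object$intercept + x %*% object$coefficients)
}

#' @export
predict.cv_penlm <- function(object, newdata, ...) predict(object$fit, newdata, ...)

#' @export
coef.penlm <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
coef.cv_penlm <- function(object, ...) coef(object$fit, ...)

#' @export
fitted.penlm <- function(object, ...) object$fitted.values

#' @export
residuals.penlm <- function(object, ...) object$residuals

#' @export
print.penlm <- function(x, ...) {
  cat(sprintf("penlm: %s%s, %d predictors (%d non-zero), n = %d\n",
              x$penalty,
              if (x$penalty == "ols") "" else sprintf(" (lambda = %.4g)", x$lambda),
              length(x$coefficients), sum(x$coefficients != 0), x$nobs))
  invisible(x)
}

#' @export
print.cv_penlm <- function(x, ...) {
  cat(sprintf("cv_penlm: %s, lambda_min = %.4g (path of %d, %d folds)\n",
              x$fit$penalty, x$lambda_min, length(x$lambdas), x$nfolds))
  invisible(x)
}

#' @export
summary.penlm <- function(object, ...) {
  res <- object$residuals
  out <- list(model = object,
              rss = sum(res^2),
              r_squared = 1 - sum(res^2) / sum((res + object$fitted.values -
                mean(res + object$fitted.values))^2),
              n_nonzero = sum(object$coefficients != 0))
  class(out) <- "summary.penlm"
  out
}

#' @export
print.summary.penlm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training R^2 = %.4f, RSS = %.4g\n", x$r_squared, x$rss))
  invisible(x)
}

#' @export
plot.cv_penlm <- function(x, ...) {
  graphics::plot(log(x$lambdas), x$cvm, type = "b", pch = 20,
                 xlab = "log(lambda)", ylab = "mean CV squared error", ...)
  graphics::abline(v = log(x$lambda_min), lty = 2)
  invisible(x)
}
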