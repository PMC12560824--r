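test_that("single-predictor closed forms hold exactly", {
  x <- standardized_predictor(40, seed = 1)
  # ridge: beta = rho / (1 + lambda), here rho = (1/n) sum(x*y) = 1
  f <- penlm(matrix(x, dimnames = list(NULL, "p1")), x, "ridge", lambda = 1)
  expect_equal(unname(f$coefficients), 0.5, tolerance = 1e-10)
  f <- penlm(matrix(x, dimnames = list(NULL, "p1")), x, "ridge", lambda = 3)
  expect_equal(unname(f$coefficients), 0.25, tolerance = 1e-10)

  # lasso: soft threshold max(|rho| - lambda, 0) * sign(rho), rho = 0.5
  y <- 0.5 * x + 2
  f <- penlm(matrix(x, dimnames = list(NULL, "p1")), y, "lasso", lambda = 0.2)
  expect_equal(unname(f$coefficients), 0.3, tolerance = 1e-10)
  f <- penlm(matrix(x, dimnames = list(NULL, "p1")), y, "lasso", lambda = 0.6)
  expect_identical(unname(f$coefficients), 0)      # full shrinkage, exact zero
  expect_equal(f$intercept, mean(y))
  # negative rho shrinks toward zero from below
  f <- penlm(matrix(x, dimnames = list(NULL, "p1")), -0.5 * x, "lasso", lambda = 0.2)
  expect_equal(unname(f$coefficients), -0.3, tolerance = 1e-10)
})

test_that("ridge at lambda -> 0 equals OLS on full-rank designs", {
  set.seed(41)
  for (i in 1:5) {
    x <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
    ols <- coef(lm(y ~ x))
    r0 <- penlm(x, y, "ridge", lambda = 0)
    expect_equal(unname(coef(r0)), unname(ols), tolerance = 1e-8)
    f_ols <- penlm(x, y, "ols")
    expect_equal(unname(coef(f_ols)), unname(ols), tolerance = 1e-10)
  }
})

test_that("coordinate descent and SVD solutions match the FISTA oracle", {
  set.seed(42)
  for (i in 1:5) {
    x <- matrix(rnorm(40), 5, 8)
    y <- rnorm(5)
    for (spec_ in list(list(pen = "lasso", alpha = 1), list(pen = "ridge", alpha = 0))) {
      for (lam in c(0.05, 0.3)) {
        fit <- penlm(x, y, spec_$pen, lambda = lam)
        oracle <- fista_elnet(x, y, alpha = spec_$alpha, lambda = lam)
        expect_equal(unname(fit$coefficients), unname(oracle$beta),
                     tolerance = 1e-6)
        expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-6)
        # optimality sanity: objective no worse than the oracle's
        obj_fit <- elnet_objective(x, y, fit$intercept, fit$coefficients,
                                   spec_$alpha, lam)
        obj_orc <- elnet_objective(x, y, oracle$intercept, oracle$beta,
                                   spec_$alpha, lam)
        expect_lte(obj_fit, obj_orc + 1e-10)
      }
    }
  }
})

test_that("lasso agrees with glmnet; ridge agrees with the normal equations", {
  skip_if_not_installed("glmnet")
  set.seed(43)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- drop(x %*% c(1, -0.5, rep(0, 8))) + rnorm(20, 0, 0.3)
  for (lam in c(0.02, 0.2)) {
    g <- glmnet::glmnet(x, y, alpha = 1, lambda = lam,
                        standardize = TRUE, thresh = 1e-14)
    fit <- penlm(x, y, "lasso", lambda = lam)
    expect_equal(unname(fit$coefficients),
                 unname(as.numeric(g$beta)), tolerance = 1e-5)
    expect_equal(fit$intercept, unname(g$a0), tolerance = 1e-5)
  }
  # ridge oracle: direct solve of (X'X/n + lambda I) b = X'y/n on the
  # standardized problem, mapped back to the original scale
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  scl <- sqrt(colMeans(xc^2))
  xs <- sweep(xc, 2, scl, "/")
  for (lam in c(0.02, 0.2)) {
    bs <- solve(crossprod(xs) / 20 + lam * diag(10),
                drop(crossprod(xs, y - mean(y))) / 20)
    fit <- penlm(x, y, "ridge", lambda = lam)
    expect_equal(unname(fit$coefficients), unname(bs / scl), tolerance = 1e-8)
    expect_equal(fit$intercept, mean(y) - sum((bs / scl) * center),
                 tolerance = 1e-8)
  }
})

test_that("prediction is affine in the coefficients and handles mismatches", {
  f <- structure(list(intercept = 1, coefficients = c(p1 = 2),
                      penalty = "ols", lambda = 0), class = "penlm")
  expect_equal(predict(f, matrix(3, dimnames = list(NULL, "p1"))), 7)
  expect_error(predict(f, matrix(3, dimnames = list(NULL, "other"))),
               "do not match")

  # huge lambda: all coefficients shrink away, prediction = training mean
  x <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  f <- penlm(x, y, "lasso", lambda = 1e6)
  expect_equal(unname(predict(f, x)), rep(mean(y), 10))

  # full-rank OLS residuals are orthogonal to the design columns
  f <- penlm(x, y, "ols")
  expect_lt(max(abs(crossprod(cbind(1, x), residuals(f)))), 1e-8)
  expect_equal(fitted(f) + residuals(f), y)
})

test_that("constant predictor columns get zero coefficients silently", {
  set.seed(44)
  x <- cbind(const = rep(2, 12), live = rnorm(12))
  y <- 0.7 * x[, "live"] + rnorm(12, 0, 0.1)
  for (pen in c("ridge", "lasso")) {
    f <- penlm(x, y, pen, lambda = 0.01)
    expect_identical(unname(f$coefficients["const"]), 0)
    expect_gt(abs(f$coefficients["live"]), 0.1)
  }
})

test_that("lambda path is decreasing and starts at the all-zero point", {
  set.seed(45)
  x <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12)
  path <- lambda_path(x, y)
  expect_length(path, 100L)
  expect_true(all(diff(path) < 0))
  expect_equal(path[100] / path[1], 1e-4, tolerance = 1e-10)
  f <- penlm(x, y, "lasso", lambda = path[1])
  expect_identical(sum(f$coefficients != 0), 0L)
  f <- penlm(x, y, "lasso", lambda = path[1] * 0.95)
  expect_gte(sum(f$coefficients != 0), 1L)
})

test_that("lasso support is monotone along the path on orthonormal designs", {
  set.seed(46)
  n <- 16
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 5), n))))[, 2:6] * sqrt(n)
  # columns are mean-zero with population variance 1 and mutually orthogonal
  y <- drop(q %*% c(2, -1, 0.5, 0, 0)) + rnorm(n, 0, 0.1)
  path <- lambda_path(q, y)
  counts <- vapply(path, function(l) sum(penlm(q, y, "lasso", l)$coefficients != 0),
                   integer(1))
  expect_true(all(diff(counts) >= 0))  # non-increasing in lambda (path decreases)
})

test_that("inner-CV lambda selection recovers noiseless signals and shrinks noise fits", {
  set.seed(47)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * x[, "a"] - 1
  cvf <- cv_penlm(x, y, "ridge", seed = 9)
  xte <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  yte <- 2 * xte[, "a"] - 1
  expect_gt(cv_r2(yte, predict(cvf, xte)), 1 - 1e-6)
  expect_equal(cvf$lambda_min, min(cvf$lambdas))

  # independent response: CV-chosen ridge shrinks every coefficient below OLS
  y_noise <- rnorm(20)
  cvn <- cv_penlm(x, y_noise, "ridge", seed = 9)
  ols <- penlm(x, y_noise, "ols")
  expect_true(all(abs(cvn$fit$coefficients) < abs(ols$coefficients)))

  expect_error(cv_penlm(x, rep(1, 20), "ridge"), "constant response")
})

test_that("OLS errors on rank-deficient designs and NaN input", {
  set.seed(48)
  x <- matrix(rnorm(20), 4, 5)
  expect_error(penlm(x, rnorm(4), "ols"), "rank-deficient")
  x2 <- matrix(rnorm(20), 10, 2)
  x2[1, 1] <- NaN
  expect_error(penlm(x2, rnorm(10), "ridge", 0.1), "NaN")
})
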