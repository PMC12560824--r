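# Independent oracles used across tests. These deliberately avoid the
# package's own solvers: the elastic-net objective is minimized by
# accelerated proximal gradient (FISTA), and cross-validated predictions are
# enumerated fold by fold with stats::lm.

# Objective value of the penalized least-squares problem on the original scale
elnet_objective <- function(x, y, b0, b, alpha, lambda) {
  n <- length(y)
  r <- y - b0 - drop(as.matrix(x) %*% b)
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
}

# FISTA minimizer of the same objective under the same internal
# standardization contract (columns scaled to population sd 1, response
# centred, intercept unpenalized), returning original-scale coefficients.
fista_elnet <- function(x, y, alpha, lambda, iters = 50000L, tol = 1e-14) {
  x <- as.matrix(x)
  n <- nrow(x)
  center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  scl <- sqrt(colSums(xc^2) / n)
  kept <- scl > 1e-10 * (abs(center) + 1)
  xs <- sweep(xc[, kept, drop = FALSE], 2L, scl[kept], "/")
  yc <- y - mean(y)
  p <- ncol(xs)
  G <- crossprod(xs) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) +
    lambda * (1 - alpha)
  step <- 1 / L
  cvec <- drop(crossprod(xs, yc)) / n
  b <- z <- numeric(p)
  t_k <- 1
  for (i in seq_len(iters)) {
    grad <- drop(G %*% z) - cvec + lambda * (1 - alpha) * z
    u <- z - step * grad
    b_new <- sign(u) * pmax(abs(u) - step * lambda * alpha, 0)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    if (max(abs(b_new - b)) < tol) { b <- b_new; break }
    b <- b_new
    t_k <- t_new
  }
  beta <- numeric(ncol(x))
  beta[kept] <- b / scl[kept]
  names(beta) <- colnames(x)
  list(intercept = mean(y) - sum(beta * center), beta = beta)
}

# Brute-force leave-one-out OLS: per-fold lm fits, predictions pooled per
# held-out condition.
brute_loo_ols <- function(x, y) {
  n <- length(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    df <- data.frame(y = y[-i], x[-i, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    pred[i] <- stats::predict(fit, newdata = data.frame(x[i, , drop = FALSE]))
  }
  pred
}

# A small hand-buildable dataset: 2 reactions, 3 proteins, 4 conditions.
tiny_dataset <- function() {
  expr <- expression_matrix(
    matrix(c(1, 2, 4, 8,
             2, 2, 2, 4,
             1, 3, 9, 27), nrow = 3, byrow = TRUE),
    protein_ids = c("PA", "PB", "PC"),
    condition_ids = c("c1", "c2", "c3", "c4"))
  rates <- rate_table(
    matrix(c(0.5, 1.0, 2.0, 4.0,
             3.0, 2.0, 1.0, 0.5), nrow = 2, byrow = TRUE),
    reaction_ids = c("R1", "R2"),
    condition_ids = c("c1", "c2", "c3", "c4"))
  ann <- annotation_map(
    reaction_to_proteins = list(R1 = "PA", R2 = "PC"),
    subsystem_members = list(SS1 = c("PA", "PB"), SS2 = c("PC")),
    reaction_to_subsystem = c(R1 = "SS1", R2 = "SS2"))
  design <- condition_design(data.frame(
    condition_id = c("c1", "c2", "c3", "c4"),
    media_type = c("glucose", "glucose", "ammonium", "ammonium"),
    growth_rate = c(0.1, 0.2, 0.1, 0.2)))
  list(expr = expr, rates = rates, ann = ann, design = design)
}

# Six-condition fixture whose rate vector is zero except in one condition:
# under media or growth-rate leave-out folds some training response is
# constant, triggering the skip rule.
sparse_rate_fixture <- function() {
  conds <- paste0("c", 1:6)
  set.seed(55)
  expr <- expression_matrix(matrix(2^rnorm(12), 2, 6), c("PA", "PB"), conds)
  rates <- rate_table(matrix(c(0, 0, 0, 0, 0, 7), 1,
                             dimnames = list("R1", conds)))
  ann <- annotation_map(list(R1 = "PA"), list(SS1 = c("PA", "PB")),
                        c(R1 = "SS1"))
  design <- condition_design(data.frame(
    condition_id = conds,
    media_type = rep(c("glucose", "ammonium", "phosphate"), each = 2),
    growth_rate = rep(c(0.1, 0.2), 3)))
  list(expr = expr, rates = rates, ann = ann, design = design)
}

# Expression + annotations where reaction R1 sits in a subsystem with
# n_members quantified proteins (for the >5 size rule).
make_subsystem_fixture <- function(n_members) {
  set.seed(50)
  prots <- paste0("P", seq_len(n_members + 2))
  conds <- paste0("c", 1:8)
  expr <- expression_matrix(matrix(2^rnorm(length(prots) * 8),
                                   length(prots), 8),
                            prots, conds)
  ann <- annotation_map(
    reaction_to_proteins = list(R1 = "P1"),
    subsystem_members = list(SSA = prots[seq_len(n_members)]),
    reaction_to_subsystem = c(R1 = "SSA"))
  list(expr = expr, ann = ann)
}

# Predictor column standardized to mean 0, population (denominator n) sd 1,
# under which the single-predictor ridge/lasso closed forms are exact.
standardized_predictor <- function(n, seed = 1) {
  x <- with(list(), { set.seed(seed); stats::rnorm(n) })
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}
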