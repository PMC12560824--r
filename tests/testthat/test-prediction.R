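test_that("predictor scales apply the quantified-membership size rule", {
  f5 <- make_subsystem_fixture(5)
  out5 <- build_predictors("R1", "subsystem", f5$expr, f5$ann)
  expect_s3_class(out5, "skip_signal")
  expect_identical(out5$reason, "SUBSYSTEM_TOO_SMALL")

  f6 <- make_subsystem_fixture(6)
  out6 <- build_predictors("R1", "subsystem", f6$expr, f6$ann)
  expect_identical(dim(out6), c(8L, 6L))

  prot_all <- build_predictors("R1", "proteome", f6$expr, f6$ann)
  expect_identical(ncol(prot_all), nrow(f6$expr))
  expect_equal(unname(prot_all), unname(t(log2_transform(f6$expr))))

  # focal requires a bidirectionally 1:1 mapping
  foc <- build_predictors("R1", "focal", f6$expr, f6$ann)
  expect_identical(ncol(foc), 1L)
  ann_multi <- annotation_map(list(R1 = c("P1", "P2")),
                              f6$ann$subsystem_members, c(R1 = "SSA"))
  expect_s3_class(build_predictors("R1", "focal", f6$expr, ann_multi),
                  "skip_signal")

  # subsystem_mean: one column per subsystem, mean of member log2 abundances
  sm <- build_predictors("R1", "subsystem_mean", f6$expr, f6$ann)
  expect_identical(colnames(sm), "SSA")
  expect_equal(sm[, 1], colMeans(log2(f6$expr)[paste0("P", 1:6), ]))

  # global z-scoring mode for coefficient display
  z <- build_predictors("R1", "subsystem", f6$expr, f6$ann, zscore = TRUE)
  expect_lt(max(abs(colMeans(z))), 1e-12)
})

test_that("fold construction matches each scheme's partition contract", {
  design <- condition_design(data.frame(
    condition_id = paste0("c", 1:25),
    media_type = rep(paste0("m", 1:5), each = 5),
    growth_rate = rep(c(0.05, 0.1, 0.2, 0.3, 0.35), 5)))

  fm <- make_folds(design, cv_scheme("leave_media_out"))
  expect_length(fm, 5L)
  expect_true(all(vapply(fm, function(f) length(f$test) == 5L, TRUE)))
  expect_setequal(unlist(lapply(fm, `[[`, "test")), design$condition_id)

  fg <- make_folds(design, cv_scheme("leave_growth_rate_out"))
  expect_length(fg, 5L)
  media_in_test <- vapply(fg, function(f)
    length(unique(design$media_type[design$condition_id %in% f$test])), 1L)
  expect_true(all(media_in_test == 5L))  # all media at that rate held out

  f2 <- make_folds(design, cv_scheme("leave_n_out", n_out = 2, iterations = 100,
                                     seed = 21))
  expect_length(f2, 100L)
  expect_true(all(vapply(f2, function(f) length(f$test) == 2L, TRUE)))
  expect_identical(f2, make_folds(design, cv_scheme("leave_n_out", n_out = 2,
                                                    iterations = 100, seed = 21)))
  expect_false(identical(f2, make_folds(design, cv_scheme("leave_n_out",
                                                          n_out = 2,
                                                          iterations = 100,
                                                          seed = 22))))

  d8 <- condition_design(data.frame(condition_id = paste0("c", 1:8),
                                    media_type = rep(c("a", "b"), 4),
                                    growth_rate = rep(1:4, each = 2)))
  expect_length(make_folds(d8, cv_scheme("leave_one_out")), 8L)
  expect_error(make_folds(d8, cv_scheme("leave_n_out", n_out = 8)), "smaller")
  d1m <- condition_design(data.frame(condition_id = c("c1", "c2"),
                                     media_type = c("a", "a"),
                                     growth_rate = c(1, 2)))
  expect_error(make_folds(d1m, cv_scheme("leave_media_out")), "2 media")
})

test_that("cross-validated R2 follows 1 - SSE/SST, negative values included", {
  expect_equal(cv_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cv_r2(c(1, 2, 3), c(2, 2, 2)), 0)     # SSE = SST = 2
  expect_equal(cv_r2(c(1, 2, 3), c(3, 2, 1)), -3)    # SSE = 8, SST = 2
  expect_error(cv_r2(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  # invariance under common affine rescaling
  set.seed(51)
  obs <- rnorm(10); pred <- obs + rnorm(10, 0, 0.4)
  expect_equal(cv_r2(3 * obs - 7, 3 * pred - 7), cv_r2(obs, pred))
})

test_that("leave-one-out OLS pooling equals brute-force enumeration and PRESS", {
  x <- matrix(c(1.0, 2.0, 3.0, 5.0, 8.0, 13.0), ncol = 1,
              dimnames = list(paste0("c", 1:6), "PA"))
  y <- c(c1 = 2.1, c2 = 3.9, c3 = 6.2, c4 = 9.8, c5 = 16.1, c6 = 25.9)
  design <- condition_design(data.frame(condition_id = paste0("c", 1:6),
                                        media_type = rep(c("a", "b"), 3),
                                        growth_rate = 1:6 / 10))
  folds <- make_folds(design, cv_scheme("leave_one_out"))
  res <- cross_validated_predict("RX", x, y, folds, penalty = "ols")
  brute <- brute_loo_ols(x, y)
  expect_equal(res$pooled$prediction, brute, tolerance = 1e-12)
  expect_equal(res$cv_r2,
               1 - sum((y - brute)^2) / sum((y - mean(y))^2))
  # PRESS closed form: loo residual = e_i / (1 - h_ii)
  full <- lm(y ~ x)
  h <- lm.influence(full)$hat
  expect_equal(y - res$pooled$prediction,
               unname(residuals(full) / (1 - h)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("noiseless linear signals are recovered through nested CV", {
  set.seed(52)
  x <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("c", 1:12),
                                                c("pa", "pb", "pc")))
  y <- setNames(1.5 * x[, "pb"] + 4, rownames(x))
  design <- condition_design(data.frame(condition_id = rownames(x),
                                        media_type = rep(c("a", "b"), 6),
                                        growth_rate = 1:12))
  folds <- make_folds(design, cv_scheme("leave_one_out"))
  res <- cross_validated_predict("RX", x, y, folds, penalty = "ridge", seed = 4)
  expect_gte(res$cv_r2, 0.99)
})

test_that("constant training responses mark the reaction as skipped", {
  d <- sparse_rate_fixture()
  x <- build_predictors("R1", "focal", d$expr, d$ann)
  folds <- make_folds(d$design, cv_scheme("leave_media_out"))
  res <- cross_validated_predict("R1", x, d$rates["R1", ], folds,
                                 penalty = "ols")
  expect_true(res$skipped)
  expect_identical(res$reason, "CONSTANT_RESPONSE")
})

test_that("no information leaks from held-out conditions into training fits", {
  cfg <- generator_config(n_media = 3, n_growth_rates = 3, seed = 23,
                          n_simple_constant = 2, n_simple_hidden = 1,
                          n_branched = 1, n_bystander_proteins = 15)
  d <- generate_dataset(cfg)
  x <- build_predictors("RSC01", "proteome", d$expression, d$annotations)
  y <- d$rates["RSC01", ]
  scheme <- cv_scheme("leave_n_out", n_out = 2, iterations = 6, seed = 61)
  folds <- make_folds(d$design, scheme)
  res <- cross_validated_predict("RSC01", x, y, folds, penalty = "ridge",
                                 seed = 77)
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    refit <- cv_penlm(x[tr, , drop = FALSE], y[tr], penalty = "ridge",
                      lambdas = lambda_path(x[tr, , drop = FALSE], y[tr]),
                      nfolds = 10, seed = proflux:::derive_seed(77, f))
    expect_identical(unname(refit$fit$coefficients),
                     unname(res$coefficients[, f]))
    expect_identical(refit$fit$intercept, res$intercepts[f])
  }
})

test_that("batch runs propagate skips and penalty cardinality", {
  cfg <- generator_config(n_media = 3, n_growth_rates = 2, seed = 29,
                          n_simple_constant = 2, n_simple_hidden = 0,
                          n_branched = 0, n_bystander_proteins = 8,
                          bystanders_per_subsystem = 2)
  d <- generate_dataset(cfg)
  scheme <- cv_scheme("leave_n_out", n_out = 1, iterations = 5, seed = 31)
  out <- run_all_scales(d$expression, d$rates, d$design, d$annotations, scheme,
                        scales = c("focal", "subsystem", "proteome"),
                        penalties = c("ridge", "lasso"), seed = 2)
  res <- out$results
  # subsystems have 3 quantified members (< 6): all subsystem rows skipped
  expect_true(all(res$skipped[res$scale == "subsystem"]))
  expect_true(all(res$reason[res$scale == "subsystem"] == "SUBSYSTEM_TOO_SMALL"))
  expect_false(any(res$skipped[res$scale != "subsystem"]))
  # focal runs OLS once per reaction; other scales run once per penalty
  expect_identical(sum(res$scale == "focal"), 2L)
  expect_identical(sum(res$scale == "proteome"), 4L)
  expect_setequal(unique(res$penalty[res$scale == "proteome"]),
                  c("ridge", "lasso"))
})
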