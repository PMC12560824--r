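#' Build the predictor table for a reaction at a given proteomic scale
#'
#' Predictors are log2-transformed abundances, conditions in rows. The three
#' scales mirror how much proteomic context the model sees: `focal` uses the
#' single annotated enzyme (requires a bidirectionally 1:1 reaction/protein
#' mapping), `subsystem` uses all quantified proteins sharing the reaction's
#' subsystem (only when strictly more than `min_subsystem_size` members are
#' quantified; smaller pathways emit a skip signal), `proteome` uses every
#' quantified protein, and `subsystem_mean` coarse-grains the proteome to one
#' column per subsystem (mean of member log2 abundances).
#'
#' @param reaction_id reaction to predict.
#' @param scale one of "focal", "subsystem", "proteome", "subsystem_mean".
#' @param expr expression matrix (linear scale).
#' @param ann annotation_map.
#' @param min_subsystem_size quantified-membership threshold that must be
#'   exceeded (default 5).
#' @param zscore additionally z-score each predictor column across all
#'   conditions (coefficient-display mode; predictive cross-validation
#'   standardizes within training folds instead and should leave this FALSE).
#' @return conditions x predictors numeric matrix, or an object of class
#'   `skip_signal` (fields `reaction_id`, `reason`) when the scale's filter
#'   rule excludes the reaction.
#' @export
build_predictors <- function(reaction_id, scale = c("focal", "subsystem",
                                                    "proteome", "subsystem_mean"),
                             expr, ann, min_subsystem_size = 5L, zscore = FALSE) {
  scale <- match.arg(scale)
  lg <- log2_transform(expr)
  cols <- switch(scale,
    focal = {
      prots <- ann$reaction_to_proteins[[reaction_id]]
      if (is.null(prots) || length(prots) != 1L) {
        return(skip_signal(reaction_id, "NOT_ONE_TO_ONE"))
      }
      n_rxn <- sum(vapply(ann$reaction_to_proteins,
                          function(p) prots %in% p, logical(1)))
      if (n_rxn != 1L) return(skip_signal(reaction_id, "NOT_ONE_TO_ONE"))
      if (!(prots %in% rownames(expr))) {
        return(skip_signal(reaction_id, "NOT_QUANTIFIED"))
      }
      prots
    },
    subsystem = {
      ss <- ann$reaction_to_subsystem[[reaction_id]]
      if (is.null(ss) || is.na(ss)) return(skip_signal(reaction_id, "NO_SUBSYSTEM"))
      members <- intersect(ann$subsystem_members[[ss]], rownames(expr))
      if (length(members) <= min_subsystem_size) {
        return(skip_signal(reaction_id, "SUBSYSTEM_TOO_SMALL"))
      }
      members
    },
    proteome = rownames(expr),
    subsystem_mean = NULL)
  x <- if (scale == "subsystem_mean") {
    sets <- lapply(ann$subsystem_members, intersect, rownames(expr))
    sets <- sets[lengths(sets) > 0]
    if (length(sets) == 0L) return(skip_signal(reaction_id, "NO_SUBSYSTEM"))
    do.call(cbind, lapply(sets, function(mm) colMeans(lg[mm, , drop = FALSE])))
  } else {
    t(lg[cols, , drop = FALSE])
  }
  if (zscore) {
    sdv <- apply(x, 2L, stats::sd)
    x <- sweep(sweep(x, 2L, colMeans(x), "-"), 2L, pmax(sdv, 1e-300), "/")
  }
  x
}

skip_signal <- function(reaction_id, reason) {
  structure(list(reaction_id = reaction_id, reason = reason),
            class = "skip_signal")
}

#' Describe an outer cross-validation scheme
#'
#' @param kind "leave_n_out" (random test sets of size `n_out`,
#'   `iterations` times), "leave_media_out" (one fold per media type),
#'   "leave_growth_rate_out" (one fold per distinct dilution rate, all media
#'   at that rate held out), or "leave_one_out".
#' @param n_out test-set size for leave_n_out (default 2).
#' @param iterations number of random folds for leave_n_out (default 100).
#' @param seed integer seed for the random draws.
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("leave_n_out", "leave_media_out",
                               "leave_growth_rate_out", "leave_one_out"),
                      n_out = 2L, iterations = 100L, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_out = as.integer(n_out),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Build outer train/test folds from the condition design
#'
#' @param design condition design data frame.
#' @param scheme a [cv_scheme()].
#' @return list of folds, each `list(train = ids, test = ids)`.
#' @export
make_folds <- function(design, scheme) {
  stopifnot(inherits(scheme, "cv_scheme"))
  ids <- design$condition_id
  n <- length(ids)
  switch(scheme$kind,
    leave_one_out = lapply(ids, function(i) list(train = setdiff(ids, i), test = i)),
    leave_media_out = {
      media <- unique(design$media_type)
      if (length(media) < 2L) stop("leave_media_out needs at least 2 media types")
      lapply(media, function(mt) {
        test <- ids[design$media_type == mt]
        list(train = setdiff(ids, test), test = test)
      })
    },
    leave_growth_rate_out = {
      rates <- unique(design$growth_rate)
      if (length(rates) < 2L) stop("leave_growth_rate_out needs at least 2 distinct rates")
      lapply(rates, function(gr) {
        test <- ids[design$growth_rate == gr]
        list(train = setdiff(ids, test), test = test)
      })
    },
    leave_n_out = {
      if (scheme$n_out >= n) stop("n_out must be smaller than the number of conditions")
      with_seed(scheme$seed, lapply(seq_len(scheme$iterations), function(i) {
        test <- sample(ids, scheme$n_out)
        list(train = setdiff(ids, test), test = test)
      }))
    })
}

#' Cross-validated R-squared
#'
#' R2 = 1 - SSE/SST, where SSE uses only out-of-training predictions and SST
#' is the total sum of squares of the observations (about their mean). Can be
#' negative when the residual variance exceeds the total variance.
#'
#' @param observed,predicted equal-length numeric vectors (>= 3 values);
#'   `observed` must have non-zero variance.
#' @return a single number <= 1.
#' @export
cv_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3L) stop("need at least 3 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("zero variance in observed values")
  1 - sum((observed - predicted)^2) / sst
}

#' Outer cross-validation with inner lambda selection for one reaction
#'
#' For each outer fold the model is fit on the training conditions only
#' (standardization and, for penalized fits, the ~10-fold inner lambda
#' cross-validation all happen inside the training part, so no information
#' leaks from held-out conditions), and the held-out conditions are predicted.
#' Out-of-fold predictions are pooled per condition by arithmetic mean across
#' iterations and a single cross-validated R2 is computed for the reaction;
#' a fold-wise variant (summing squared errors over every out-of-fold
#' prediction) is reported alongside. If the training response is constant in
#' any fold the reaction x scheme is marked skipped with reason
#' CONSTANT_RESPONSE.
#'
#' @param reaction_id identifier carried through to the result.
#' @param predictors conditions x predictors matrix (log2 abundances).
#' @param y named numeric vector of rates (names = condition ids).
#' @param folds outer folds from [make_folds()].
#' @param penalty "ols", "ridge" or "lasso".
#' @param inner_folds inner CV fold count for lambda selection (default 10).
#' @param nlambda lambda path length (default 100).
#' @param seed integer; inner fold assignments derive from it per outer fold.
#' @param scale,scheme_kind labels recorded in the result.
#' @return object of class `prediction_result`.
#' @export
cross_validated_predict <- function(reaction_id, predictors, y, folds,
                                    penalty = c("ridge", "lasso", "ols"),
                                    inner_folds = 10L, nlambda = 100L,
                                    seed = 1L, scale = NA_character_,
                                    scheme_kind = NA_character_) {
  penalty <- match.arg(penalty)
  conds <- rownames(predictors)
  if (is.null(conds)) stop("predictor matrix must have condition rownames")
  if (!all(names(y) %in% conds) || length(y) != length(conds)) {
    stop("predictors and rates must share the same condition set")
  }
  y <- y[conds]
  p <- ncol(predictors)
  pred_sum <- stats::setNames(numeric(length(conds)), conds)
  pred_n <- stats::setNames(integer(length(conds)), conds)
  coefs <- matrix(NA_real_, p, length(folds),
                  dimnames = list(colnames(predictors), NULL))
  intercepts <- numeric(length(folds))
  lambdas <- rep(NA_real_, length(folds))
  fold_obs <- list(); fold_pred <- list()

  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    ytr <- y[tr]
    if (max(ytr) - min(ytr) == 0) {
      return(structure(list(reaction_id = reaction_id, scale = scale,
                            penalty = penalty, scheme_kind = scheme_kind,
                            skipped = TRUE, reason = "CONSTANT_RESPONSE"),
                       class = "prediction_result"))
    }
    xtr <- predictors[tr, , drop = FALSE]
    xte <- predictors[te, , drop = FALSE]
    if (penalty == "ols") {
      fit <- penlm(xtr, ytr, penalty = "ols")
    } else {
      cvfit <- cv_penlm(xtr, ytr, penalty = penalty,
                        lambdas = lambda_path(xtr, ytr, nlambda = nlambda),
                        nfolds = inner_folds, seed = derive_seed(seed, f))
      fit <- cvfit$fit
      lambdas[f] <- cvfit$lambda_min
    }
    pr <- predict(fit, xte)
    pred_sum[te] <- pred_sum[te] + pr
    pred_n[te] <- pred_n[te] + 1L
    coefs[, f] <- fit$coefficients
    intercepts[f] <- fit$intercept
    fold_obs[[f]] <- y[te]; fold_pred[[f]] <- pr
  }

  seen <- pred_n > 0L
  pooled <- pred_sum[seen] / pred_n[seen]
  obs <- y[seen]
  r2 <- cv_r2(obs, pooled)
  all_obs <- unlist(fold_obs); all_pred <- unlist(fold_pred)
  r2_foldwise <- 1 - sum((all_obs - all_pred)^2) /
    sum((all_obs - mean(obs))^2)
  structure(list(
    reaction_id = reaction_id, scale = scale, penalty = penalty,
    scheme_kind = scheme_kind, skipped = FALSE, reason = NA_character_,
    n_predictors = p,
    pooled = data.frame(condition_id = names(obs), observed = unname(obs),
                        prediction = unname(pooled),
                        n_times_held_out = unname(pred_n[seen]),
                        stringsAsFactors = FALSE),
    cv_r2 = r2, cv_r2_foldwise = r2_foldwise,
    coefficients = coefs, intercepts = intercepts, chosen_lambdas = lambdas
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("prediction_result: %s [skipped: %s]\n", x$reaction_id, x$reason))
  } else {
    cat(sprintf("prediction_result: %s, scale=%s, penalty=%s, cv R2 = %.3f (%d predictors)\n",
                x$reaction_id, x$scale, x$penalty, x$cv_r2, x$n_predictors))
  }
  invisible(x)
}

#' Run the prediction pipeline across reactions, scales and penalties
#'
#' The focal scale uses simple linear regression (OLS on the single annotated
#' enzyme); subsystem, proteome and subsystem_mean scales use the requested
#' penalized fits (ridge by default, lasso optionally) with nested
#' cross-validation. Skip signals (non-1:1 mappings, undersized subsystems,
#' constant responses) are propagated as flagged rows and never abort the
#' batch.
#'
#' @param expr expression matrix; @param rates rate table;
#' @param design condition design; @param ann annotation_map.
#' @param scheme outer [cv_scheme()].
#' @param scales character vector of scales to run.
#' @param penalties penalties for the multi-predictor scales
#'   (subset of "ridge", "lasso").
#' @param min_subsystem_size see [build_predictors()].
#' @param inner_folds,nlambda passed to [cross_validated_predict()].
#' @param seed master seed; per-(reaction, scale, penalty) substreams derive
#'   from it.
#' @return list with `results` (one data.frame row per reaction x scale x
#'   penalty) and `details` (the prediction_result objects, named
#'   `reaction|scale|penalty`).
#' @export
run_all_scales <- function(expr, rates, design, ann, scheme,
                           scales = c("focal", "subsystem", "proteome"),
                           penalties = "ridge", min_subsystem_size = 5L,
                           inner_folds = 10L, nlambda = 100L, seed = 1L) {
  check_paired_conditions(expr, rates)
  validate_annotations(ann, expr, rates)
  folds <- make_folds(design, scheme)
  details <- list()
  rows <- list()
  predictor_cache <- list()
  task_id <- 0L
  for (scale in scales) {
    pens <- if (scale == "focal") "ols" else penalties
    for (rxn in rownames(rates)) {
      key <- paste(scale, rxn, sep = "|")
      x <- if (scale %in% c("proteome", "subsystem_mean")) {
        if (is.null(predictor_cache[[scale]])) {
          predictor_cache[[scale]] <- build_predictors(rxn, scale, expr, ann,
                                                       min_subsystem_size)
        }
        predictor_cache[[scale]]
      } else {
        build_predictors(rxn, scale, expr, ann, min_subsystem_size)
      }
      for (pen in pens) {
        task_id <- task_id + 1L
        nm <- paste(rxn, scale, pen, sep = "|")
        if (inherits(x, "skip_signal")) {
          res <- structure(list(reaction_id = rxn, scale = scale, penalty = pen,
                                scheme_kind = scheme$kind, skipped = TRUE,
                                reason = x$reason), class = "prediction_result")
        } else {
          res <- cross_validated_predict(rxn, x, rates[rxn, ], folds,
                                         penalty = pen,
                                         inner_folds = inner_folds,
                                         nlambda = nlambda,
                                         seed = derive_seed(seed, task_id),
                                         scale = scale,
                                         scheme_kind = scheme$kind)
        }
        details[[nm]] <- res
        rows[[nm]] <- data.frame(
          reaction_id = rxn, scale = scale, penalty = pen,
          cv_scheme = scheme$kind,
          n_predictors = if (isTRUE(res$skipped)) NA_integer_ else res$n_predictors,
          cv_r2 = if (isTRUE(res$skipped)) NA_real_ else res$cv_r2,
          cv_r2_foldwise = if (isTRUE(res$skipped)) NA_real_ else res$cv_r2_foldwise,
          skipped = isTRUE(res$skipped),
          reason = if (isTRUE(res$skipped)) res$reason else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, details = details)
}
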