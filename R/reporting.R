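#' Summarize cross-validated R2 distributions per scale/penalty/scheme
#'
#' Medians and 5th/25th/75th/95th quantiles (linear interpolation between
#' order statistics, `stats::quantile` type 7) over the unskipped reactions of
#' each (scale, penalty, cv_scheme) group; skipped reactions are counted
#' separately. Groups with no unskipped result are omitted with a message.
#'
#' @param results the `results` data frame from [run_all_scales()].
#' @return data.frame: scale, penalty, cv_scheme, n_reactions, n_skipped,
#'   median_cv_r2, q05, q25, q75, q95.
#' @export
summarize_results <- function(results) {
  groups <- unique(results[, c("scale", "penalty", "cv_scheme")])
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sub <- results[results$scale == g$scale & results$penalty == g$penalty &
                     results$cv_scheme == g$cv_scheme, ]
    ok <- !sub$skipped
    if (!any(ok)) {
      message(sprintf("group %s/%s/%s: all %d reactions skipped, omitted",
                      g$scale, g$penalty, g$cv_scheme, nrow(sub)))
      next
    }
    q <- stats::quantile(sub$cv_r2[ok], c(0.05, 0.25, 0.5, 0.75, 0.95),
                         names = FALSE, type = 7)
    rows[[i]] <- data.frame(scale = g$scale, penalty = g$penalty,
                            cv_scheme = g$cv_scheme,
                            n_reactions = nrow(sub), n_skipped = sum(!ok),
                            median_cv_r2 = q[3], q05 = q[1], q25 = q[2],
                            q75 = q[4], q95 = q[5], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no unskipped results to summarize")
  rownames(out) <- NULL
  out
}

#' Coefficient stability across cross-validation iterations
#'
#' Mean and sample standard deviation of each predictor's coefficient over
#' the outer CV iterations. The intercept is never included in the output.
#'
#' @param result an unskipped `prediction_result`.
#' @return data.frame: predictor_id, mean_beta, sd_beta, frac_nonzero,
#'   plus attribute `single_iteration` flag when sd is undefined.
#' @export
coefficient_stability <- function(result) {
  stopifnot(inherits(result, "prediction_result"))
  if (isTRUE(result$skipped)) stop("result was skipped: ", result$reason)
  cf <- result$coefficients
  n_iter <- ncol(cf)
  out <- data.frame(
    predictor_id = rownames(cf),
    mean_beta = rowMeans(cf),
    sd_beta = if (n_iter >= 2L) apply(cf, 1L, stats::sd) else NA_real_,
    frac_nonzero = rowMeans(cf != 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "single_iteration") <- n_iter < 2L
  out
}

#' Count non-zero LASSO coefficients per cross-validation iteration
#'
#' LASSO sets coefficients exactly to zero (soft-thresholding), so an exact
#' zero test is legitimate. Per reaction, reports the per-iteration counts of
#' non-zero coefficients and their 25th-75th quantile range. Non-lasso input
#' yields an empty summary with a message.
#'
#' @param details the `details` list from [run_all_scales()] (or any list of
#'   `prediction_result` objects).
#' @return data.frame: reaction_id, scale, n_predictors, median_nonzero,
#'   q25_nonzero, q75_nonzero; attribute `counts` holds the per-iteration
#'   count vectors.
#' @export
lasso_sparsity <- function(details) {
  lasso <- Filter(function(r) !isTRUE(r$skipped) && r$penalty == "lasso", details)
  if (length(lasso) == 0L) {
    message("no lasso results present; sparsity summary is empty")
    return(data.frame(reaction_id = character(), scale = character(),
                      n_predictors = integer(), median_nonzero = numeric(),
                      q25_nonzero = numeric(), q75_nonzero = numeric(),
                      stringsAsFactors = FALSE))
  }
  counts <- lapply(lasso, function(r) colSums(r$coefficients != 0))
  out <- data.frame(
    reaction_id = vapply(lasso, `[[`, character(1), "reaction_id"),
    scale = vapply(lasso, `[[`, character(1), "scale"),
    n_predictors = vapply(lasso, `[[`, integer(1), "n_predictors"),
    median_nonzero = vapply(counts, stats::median, numeric(1)),
    q25_nonzero = vapply(counts, function(x) stats::quantile(x, 0.25, names = FALSE),
                         numeric(1)),
    q75_nonzero = vapply(counts, function(x) stats::quantile(x, 0.75, names = FALSE),
                         numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

#' Correlation of each rate with growth rate, joined with predictability
#'
#' Checks whether rates must track growth (dilution) rate to be predictable:
#' reports the Pearson correlation of each reaction's rate vector with the
#' growth rate across conditions, joined with that reaction's proteome-scale
#' cross-validated R2. Constant-rate reactions are flagged and excluded from
#' the correlation.
#'
#' @param rates rate table; @param design condition design.
#' @param results results data frame from [run_all_scales()] (proteome rows
#'   are used; if several penalties are present, ridge is preferred).
#' @return data.frame: reaction_id, pearson_with_growth, cv_r2, flagged.
#' @export
growth_decoupling <- function(rates, design, results) {
  g <- stats::setNames(design$growth_rate, design$condition_id)[colnames(rates)]
  if (anyNA(g)) stop("growth_rate missing for some conditions")
  prot <- results[results$scale == "proteome" & !results$skipped, ]
  if (any(prot$penalty == "ridge")) prot <- prot[prot$penalty == "ridge", ]
  r2 <- stats::setNames(prot$cv_r2, prot$reaction_id)
  rows <- lapply(rownames(rates), function(rxn) {
    v <- rates[rxn, ]
    flagged <- stats::sd(v) == 0
    data.frame(reaction_id = rxn,
               pearson_with_growth = if (flagged) NA_real_ else
                 stats::cor(v, g, method = "pearson"),
               cv_r2 = if (rxn %in% names(r2)) r2[[rxn]] else NA_real_,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline from a structured configuration
#'
#' Stages: simulate (optional; otherwise input paths are required) ->
#' correlate (focal covariation table) -> predict (all requested scales,
#' penalties and CV scheme) -> report (summaries, sparsity, growth
#' decoupling). All outputs are tab-separated files plus a JSON manifest
#' recording the configuration hash, seed and package version; outputs are
#' byte-identical across runs with the same configuration and seed. Any stage
#' error aborts with a stage-labelled message.
#'
#' @param config path to a YAML file or an equivalent nested list. Top-level
#'   fields: `simulate` (generator_config fields) or `inputs` (paths:
#'   expression, rates, conditions, reaction_protein, subsystems,
#'   reaction_subsystem), optional `covariation` (exclude_conditions, mi_k),
#'   optional `predict` (scales, penalties, cv, n_out, iterations,
#'   inner_folds, min_subsystem_size), `seed`, `out`.
#' @param out output directory (overrides config `out`).
#' @param seed seed override (overrides config `seed`).
#' @return invisibly, a list with all in-memory stage outputs.
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.null(out)) cfg$out <- out
  if (is.null(cfg$out)) stop("config: missing required field 'out'")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  data <- stage("simulate", {
    if (!is.null(cfg$simulate)) {
      gc_args <- cfg$simulate
      gc_args$seed <- derive_seed(cfg$seed, 1L)
      d <- generate_dataset(do.call(generator_config, gc_args))
      write_dataset(d, file.path(cfg$out, "dataset"))
      d
    } else if (!is.null(cfg$inputs)) {
      need <- c("expression", "rates", "conditions", "reaction_protein",
                "subsystems", "reaction_subsystem")
      missing_f <- setdiff(need, names(cfg$inputs))
      if (length(missing_f)) {
        stop("config: missing input field(s): ", paste(missing_f, collapse = ", "))
      }
      list(expression = read_matrix(cfg$inputs$expression, "expression"),
           rates = read_matrix(cfg$inputs$rates, "rate"),
           design = read_condition_design(cfg$inputs$conditions),
           annotations = read_annotations(cfg$inputs$reaction_protein,
                                          cfg$inputs$subsystems,
                                          cfg$inputs$reaction_subsystem))
    } else {
      stop("config: need either a 'simulate' block or an 'inputs' block")
    }
  })

  cov <- stage("correlate", {
    excl <- as.character(cfg$covariation$exclude_conditions %||% character())
    k <- cfg$covariation$mi_k %||% 3L
    pairs <- extract_focal_pairs(data$rates, data$expression, data$annotations,
                                 excluded_conditions = excl)
    covariation_table(pairs, k = k)
  })
  write_tsv(cov$table, file.path(cfg$out, "covariation.tsv"))

  pred <- stage("predict", {
    pc <- cfg$predict %||% list()
    scheme <- cv_scheme(kind = pc$cv %||% "leave_n_out",
                        n_out = pc$n_out %||% 2L,
                        iterations = pc$iterations %||% 100L,
                        seed = derive_seed(cfg$seed, 2L))
    run_all_scales(data$expression, data$rates, data$design, data$annotations,
                   scheme = scheme,
                   scales = unlist(pc$scales %||% c("focal", "subsystem", "proteome")),
                   penalties = unlist(pc$penalties %||% "ridge"),
                   min_subsystem_size = pc$min_subsystem_size %||% 5L,
                   inner_folds = pc$inner_folds %||% 10L,
                   nlambda = pc$nlambda %||% 100L,
                   seed = derive_seed(cfg$seed, 3L))
  })
  write_tsv(pred$results, file.path(cfg$out, "results.tsv"))
  write_tsv(collect_predictions(pred$details), file.path(cfg$out, "predictions.tsv"))
  write_tsv(collect_coefficients(pred$details), file.path(cfg$out, "coefficients.tsv"))

  report <- stage("report", {
    list(summary = summarize_results(pred$results),
         sparsity = suppressMessages(lasso_sparsity(pred$details)),
         growth = growth_decoupling(data$rates, data$design, pred$results))
  })
  write_tsv(report$summary, file.path(cfg$out, "summary.tsv"))
  write_tsv(report$sparsity, file.path(cfg$out, "sparsity.tsv"))
  write_tsv(report$growth, file.path(cfg$out, "growth_decoupling.tsv"))

  cfg_canon <- tempfile(fileext = ".yaml")
  cfg_hashable <- cfg[setdiff(sort(names(cfg)), "out")]  # hash the science, not the destination
  yaml::write_yaml(cfg_hashable, cfg_canon)
  manifest <- list(
    package = "proflux",
    version = as.character(utils::packageVersion("proflux")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_canon)),
    n_skipped = sum(pred$results$skipped)
  )
  unlink(cfg_canon)
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(data = data, covariation = cov, prediction = pred,
                 report = report, out = cfg$out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collect_predictions <- function(details) {
  rows <- lapply(details, function(r) {
    if (isTRUE(r$skipped)) return(NULL)
    cbind(data.frame(reaction_id = r$reaction_id, scale = r$scale,
                     penalty = r$penalty, stringsAsFactors = FALSE),
          r$pooled)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

collect_coefficients <- function(details) {
  rows <- lapply(details, function(r) {
    if (isTRUE(r$skipped)) return(NULL)
    st <- coefficient_stability(r)
    cbind(data.frame(reaction_id = r$reaction_id, scale = r$scale,
                     penalty = r$penalty, stringsAsFactors = FALSE), st)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  if (is.null(df) || nrow(df) == 0L) {
    writeLines(paste(names(df), collapse = "\t"), path, useBytes = TRUE)
    return(invisible(path))
  }
  cells <- vapply(seq_along(df), function(j) {
    col <- df[[j]]
    if (is.numeric(col) && !is.integer(col)) format_num(col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
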