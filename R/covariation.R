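#' Spearman rank correlation with a zero-variance flag
#'
#' Pearson correlation of average-rank vectors (the standard tie policy; rate
#' vectors in this domain contain exact zeros, so ties are expected). When
#' either vector has zero rank variance the correlation is undefined and a
#' flag is returned instead of a fabricated value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` (NA when flagged) and `zero_variance_flag`.
#' @export
spearman_rho <- function(x, y) {
  check_pair(x, y)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, zero_variance_flag = TRUE))
  }
  list(rho = stats::cor(x, y, method = "spearman"), zero_variance_flag = FALSE)
}

#' Pearson correlation, optionally on log2-transformed abundances
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must be strictly
#'   positive when `log2_x = TRUE`.
#' @param log2_x log2-transform `x` before correlating (the abundance axis).
#' @return list with `r` (NA when flagged) and `zero_variance_flag`.
#' @export
pearson_r <- function(x, y, log2_x = FALSE) {
  check_pair(x, y)
  if (log2_x) {
    if (any(x <= 0)) stop("log2 transform requires strictly positive x")
    x <- log2(x)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, zero_variance_flag = TRUE))
  }
  list(r = stats::cor(x, y, method = "pearson"), zero_variance_flag = FALSE)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  invisible(TRUE)
}

#' Kraskov-Stoegbauer-Grassberger mutual information estimate
#'
#' k-nearest-neighbour estimator (KSG variant 1) for continuous data:
#' MI = psi(k) + psi(N) - mean_i[psi(nx_i + 1) + psi(ny_i + 1)], with
#' neighbourhoods in the max-norm on the joint space and strict-inequality
#' marginal counts. The estimator can return small negative values for
#' independent data; by default these are clipped to zero and flagged.
#' Heavily tied input (over half the points duplicated in either marginal)
#' degrades the neighbour counts, and is flagged.
#'
#' @param x,y numeric vectors of equal length; length >= 10*k recommended.
#' @param k neighbour count (default 3).
#' @param clip clip negative estimates to 0 (default TRUE).
#' @return list with `mi` (nats), `mi_raw` (unclipped), `clipped`, and
#'   `tie_warning`.
#' @export
mutual_information <- function(x, y, k = 3L, clip = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (k < 1L) stop("k must be >= 1")
  if (n < k + 2L) stop("too few points for the requested k")
  tie_warning <- (sum(duplicated(x)) > n / 2) || (sum(duplicated(y)) > n / 2)

  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dj <- pmax(dx, dy)
  diag(dj) <- Inf
  # distance to the k-th nearest neighbour in the joint (max-norm) space
  eps <- vapply(seq_len(n), function(i) {
    sort.int(dj[i, ], partial = k)[k]
  }, numeric(1))
  # strict-inequality counts in each marginal (variant 1), excluding self
  nx <- rowSums(dx < eps) - 1L
  ny <- rowSums(dy < eps) - 1L
  mi_raw <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  clipped <- clip && mi_raw < 0
  list(mi = if (clipped) 0 else mi_raw, mi_raw = mi_raw,
       clipped = clipped, tie_warning = tie_warning)
}

#' Extract bidirectionally one-to-one reaction/protein pairs
#'
#' The focal-enzyme analysis considers only reactions catalysed by exactly one
#' protein where that protein maps to exactly one reaction (so the abundance
#' signal is not shared across rates). Conditions can be excluded, e.g.
#' conditions grown as genetically modified auxotrophs, where the modification
#' itself could drive the relationship.
#'
#' @param rates rate table.
#' @param expr expression matrix (same condition set).
#' @param ann annotation_map.
#' @param excluded_conditions character vector of condition ids to drop from
#'   both series (must be known conditions).
#' @return list of focal pairs, each a list with `reaction_id`, `protein_id`,
#'   `abundances`, `rates`, `condition_ids`.
#' @export
extract_focal_pairs <- function(rates, expr, ann, excluded_conditions = character()) {
  check_paired_conditions(expr, rates)
  conditions <- colnames(rates)
  if (length(excluded_conditions)) {
    unknown <- setdiff(excluded_conditions, conditions)
    if (length(unknown)) {
      stop("excluded_conditions not in the data: ", paste(unknown, collapse = ", "))
    }
  }
  keep <- setdiff(conditions, excluded_conditions)
  r2p <- ann$reaction_to_proteins
  # reciprocal map restricted to quantified proteins and known reactions
  pair_df <- data.frame(
    reaction = rep(names(r2p), lengths(r2p)),
    protein = unlist(r2p, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  protein_counts <- table(pair_df$protein)
  out <- list()
  for (rxn in names(r2p)) {
    prots <- r2p[[rxn]]
    if (length(prots) != 1L) next                        # reaction must have one protein
    p <- prots[[1]]
    if (protein_counts[[p]] != 1L) next                  # protein must have one reaction
    if (!(p %in% rownames(expr)) || !(rxn %in% rownames(rates))) next
    out[[rxn]] <- list(reaction_id = rxn, protein_id = p,
                       abundances = expr[p, keep],
                       rates = rates[rxn, keep],
                       condition_ids = keep)
  }
  unname(out)
}

#' Covariation statistics for every focal pair
#'
#' For each one-to-one reaction/protein pair, computes Spearman correlation,
#' Pearson correlation with and without log2 transform of the abundances, and
#' the KSG mutual information, plus distribution summaries. Spearman is
#' computed from the raw abundances; it is identical on log-abundances by
#' monotone invariance.
#'
#' @param pairs list of focal pairs from [extract_focal_pairs()].
#' @param k mutual-information neighbour count.
#' @return list with `table` (one row per pair: reaction_id, protein_id, n,
#'   spearman, pearson_linear, pearson_log2, mi_nats, zero_variance, mi_clipped,
#'   mi_tie_warning) and `summary` (mean/median Spearman over unflagged pairs).
#' @export
covariation_table <- function(pairs, k = 3L) {
  if (length(pairs) == 0L) stop("no focal pairs supplied")
  rows <- lapply(pairs, function(p) {
    n <- length(p$rates)
    sp <- spearman_rho(p$abundances, p$rates)
    pe_lin <- pearson_r(p$abundances, p$rates, log2_x = FALSE)
    pe_log <- pearson_r(p$abundances, p$rates, log2_x = TRUE)
    mi <- if (n >= k + 2L) mutual_information(p$abundances, p$rates, k = k)
          else list(mi = NA_real_, clipped = FALSE, tie_warning = FALSE)
    data.frame(reaction_id = p$reaction_id, protein_id = p$protein_id, n = n,
               spearman = sp$rho, pearson_linear = pe_lin$r,
               pearson_log2 = pe_log$r, mi_nats = mi$mi,
               zero_variance = sp$zero_variance_flag,
               mi_clipped = mi$clipped, mi_tie_warning = mi$tie_warning,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !is.na(tab$spearman)
  list(table = tab,
       summary = list(n_pairs = nrow(tab),
                      n_flagged = sum(!ok),
                      mean_spearman = mean(tab$spearman[ok]),
                      median_spearman = stats::median(tab$spearman[ok])))
}
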