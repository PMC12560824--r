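#' Configuration for the synthetic chemostat dataset generator
#'
#' The generator emulates the structure of steady-state chemostat proteomics
#' studies: a factorial design of media types (limiting nutrients) crossed
#' with dilution rates, log-normally distributed protein abundances driven by
#' condition factors, and reaction rates that are exact closed-form functions
#' of the true enzyme levels and substrate supply. Three reaction classes
#' span the covariation spectrum: "simple-constant" (v = k*e, fixed substrate;
#' strong focal covariation), "simple-hidden" (v = k*e*S_media with a
#' media-specific substrate level; weakened covariation) and "branched"
#' (the shared-substrate competition motif of [toy_steady_state()], with the
#' competitor's media response amplified; weak or negative covariation).
#'
#' @param n_media number of media types (max 8 named types).
#' @param n_growth_rates dilution levels per media type.
#' @param growth_rate_values dilution rates (per hour), length n_growth_rates.
#' @param n_simple_constant,n_simple_hidden,n_branched reaction counts per class.
#' @param n_bystander_proteins proteins carrying condition information but not
#'   mapped to any reaction.
#' @param bystanders_per_subsystem bystanders grouped with each motif into its
#'   subsystem (drawn from the shared pool; subsystems may overlap).
#' @param noise_sd_log2 sd of the measurement noise added to true log2
#'   abundances in the observed expression matrix (log2 units).
#' @param coupling_slope factor amplifying the branched competitor's media
#'   response relative to its focal enzyme.
#' @param seed integer; all draws derive deterministically from it.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_media = 5L, n_growth_rates = 5L,
                             growth_rate_values = seq(0.05, 0.35,
                                                      length.out = n_growth_rates),
                             n_simple_constant = 10L, n_simple_hidden = 20L,
                             n_branched = 10L, n_bystander_proteins = 150L,
                             bystanders_per_subsystem = 5L,
                             noise_sd_log2 = 0.25, coupling_slope = 2,
                             seed = 1L) {
  cfg <- list(n_media = as.integer(n_media),
              n_growth_rates = as.integer(n_growth_rates),
              growth_rate_values = as.numeric(growth_rate_values),
              n_simple_constant = as.integer(n_simple_constant),
              n_simple_hidden = as.integer(n_simple_hidden),
              n_branched = as.integer(n_branched),
              n_bystander_proteins = as.integer(n_bystander_proteins),
              bystanders_per_subsystem = as.integer(bystanders_per_subsystem),
              noise_sd_log2 = as.numeric(noise_sd_log2),
              coupling_slope = as.numeric(coupling_slope),
              seed = as.integer(seed))
  counts <- c(cfg$n_media, cfg$n_growth_rates, cfg$n_simple_constant,
              cfg$n_simple_hidden, cfg$n_branched, cfg$n_bystander_proteins,
              cfg$bystanders_per_subsystem)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$noise_sd_log2 < 0) stop("noise_sd_log2 must be >= 0")
  if (length(cfg$growth_rate_values) != cfg$n_growth_rates) {
    stop("growth_rate_values must have length n_growth_rates")
  }
  if (any(cfg$growth_rate_values < 0)) stop("growth rates must be >= 0")
  if (cfg$n_bystander_proteins < cfg$bystanders_per_subsystem) {
    stop("bystander pool smaller than bystanders_per_subsystem")
  }
  class(cfg) <- "generator_config"
  cfg
}

media_names <- function(n) {
  base <- c("glucose", "ammonium", "phosphate", "leucine", "uracil",
            "sulfate", "fructose", "gluconate")
  if (n <= length(base)) base[seq_len(n)] else paste0("media", seq_len(n))
}

#' Generate a ground-truth synthetic chemostat dataset
#'
#' Latent condition factors are the dilution rate g_c and the media identity.
#' Each protein i has true log2 abundance b_i + s_i*g_c + m_(i, media(c)) with
#' baselines b ~ N(0, 1), growth slopes s ~ N(0, 0.5) and media effects
#' m ~ N(0, 0.5) drawn once; the observed matrix adds cellwise measurement
#' noise N(0, noise_sd_log2) on the log2 scale. Rates are exact closed-form
#' functions of the *true* enzyme levels (and of the substrate supply
#' C_c = C0*(1 + g_c) for branched motifs), so with zero noise the focal
#' protein of a simple-constant reaction covaries perfectly with its rate,
#' while noise attenuates the observable covariation. Every motif is grouped
#' with bystander proteins into one subsystem, and the full latent state is
#' returned in the `truth` channel for oracle testing.
#'
#' @param cfg a [generator_config()].
#' @return list of class `synthetic_dataset`: `expression`, `rates`, `design`,
#'   `annotations`, `truth`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n_cond <- cfg$n_media * cfg$n_growth_rates
  if (n_cond == 0L) stop("zero conditions: n_media and n_growth_rates must be > 0")
  n_rxn <- cfg$n_simple_constant + cfg$n_simple_hidden + cfg$n_branched
  if (n_rxn == 0L) stop("zero reactions configured")

  media <- media_names(cfg$n_media)
  design <- condition_design(data.frame(
    condition_id = paste0(rep(media, each = cfg$n_growth_rates), "_D",
                          sprintf("%03.0f", rep(cfg$growth_rate_values * 1000,
                                                cfg$n_media))),
    media_type = rep(media, each = cfg$n_growth_rates),
    growth_rate = rep(cfg$growth_rate_values, cfg$n_media),
    stringsAsFactors = FALSE
  ))

  rxn <- data.frame(
    reaction_id = c(sprintf("RSC%02d", seq_len2(cfg$n_simple_constant)),
                    sprintf("RSH%02d", seq_len2(cfg$n_simple_hidden)),
                    sprintf("RBR%02d", seq_len2(cfg$n_branched))),
    type = rep(c("simple_constant", "simple_hidden", "branched"),
               c(cfg$n_simple_constant, cfg$n_simple_hidden, cfg$n_branched)),
    stringsAsFactors = FALSE
  )
  rxn$focal_protein <- sub("^R", "P", rxn$reaction_id)
  rxn$competitor_protein <- ifelse(rxn$type == "branched",
                                   paste0(sub("^R", "P", rxn$reaction_id), "c"),
                                   NA_character_)
  bystanders <- sprintf("PBY%03d", seq_len2(cfg$n_bystander_proteins))
  proteins <- c(rxn$focal_protein,
                rxn$competitor_protein[!is.na(rxn$competitor_protein)],
                bystanders)
  n_prot <- length(proteins)

  # protein-level parameter draws (one substream per section)
  b <- with_seed(derive_seed(cfg$seed, 11L),
                 stats::setNames(stats::rnorm(n_prot, 0, 1), proteins))
  s <- with_seed(derive_seed(cfg$seed, 12L),
                 stats::setNames(stats::rnorm(n_prot, 0, 0.5), proteins))
  m <- with_seed(derive_seed(cfg$seed, 13L),
                 matrix(stats::rnorm(n_prot * cfg$n_media, 0, 0.5), n_prot,
                        cfg$n_media, dimnames = list(proteins, media)))
  # branched competitors: media response is the focal response, amplified
  for (i in which(rxn$type == "branched")) {
    m[rxn$competitor_protein[i], ] <- cfg$coupling_slope * m[rxn$focal_protein[i], ]
  }

  g <- stats::setNames(design$growth_rate, design$condition_id)
  media_of <- stats::setNames(design$media_type, design$condition_id)
  true_log2 <- b + outer(s, g) + m[, media_of[design$condition_id], drop = FALSE]
  colnames(true_log2) <- design$condition_id
  e_true <- 2^true_log2

  # kinetic constants per reaction
  kdraw <- with_seed(derive_seed(cfg$seed, 14L),
                     2^stats::rnorm(n_rxn + cfg$n_branched, 0, 0.5))
  s_media <- with_seed(derive_seed(cfg$seed, 15L),
                       matrix(2^stats::rnorm(cfg$n_simple_hidden * cfg$n_media, 0, 1),
                              cfg$n_simple_hidden, cfg$n_media,
                              dimnames = list(rxn$reaction_id[rxn$type == "simple_hidden"],
                                              media)))
  C0 <- 1
  C_c <- C0 * (1 + g)

  constants <- vector("list", n_rxn)
  names(constants) <- rxn$reaction_id
  rates <- matrix(NA_real_, n_rxn, n_cond,
                  dimnames = list(rxn$reaction_id, design$condition_id))
  ki <- 1L
  for (i in seq_len(n_rxn)) {
    id <- rxn$reaction_id[i]
    fp <- rxn$focal_protein[i]
    if (rxn$type[i] == "simple_constant") {
      constants[[id]] <- list(k = kdraw[ki]); ki <- ki + 1L
      rates[id, ] <- constants[[id]]$k * e_true[fp, ]
    } else if (rxn$type[i] == "simple_hidden") {
      constants[[id]] <- list(k = kdraw[ki],
                              S_media = s_media[id, ]); ki <- ki + 1L
      rates[id, ] <- constants[[id]]$k * e_true[fp, ] *
        constants[[id]]$S_media[media_of[design$condition_id]]
    } else {
      cp <- rxn$competitor_protein[i]
      constants[[id]] <- list(k1 = kdraw[ki], k2 = kdraw[ki + 1L], C0 = C0)
      ki <- ki + 2L
      ss <- toy_steady_state(constants[[id]]$k1, constants[[id]]$k2, C_c,
                             e_true[fp, ], e_true[cp, ])
      rates[id, ] <- ss$v1
    }
  }

  eps <- with_seed(derive_seed(cfg$seed, 16L),
                   matrix(stats::rnorm(n_prot * n_cond, 0, cfg$noise_sd_log2),
                          n_prot, n_cond))
  observed <- signif(2^(true_log2 + eps), 12)
  rates <- signif(rates, 12)

  # subsystems: motif proteins + bystanders drawn from the shared pool
  subsystems <- list()
  r2p <- list()
  r2s <- character(0)
  if (cfg$n_bystander_proteins > 0) {
    picks <- with_seed(derive_seed(cfg$seed, 17L), lapply(seq_len(n_rxn), function(i)
      sample(bystanders, cfg$bystanders_per_subsystem)))
  } else {
    picks <- rep(list(character(0)), n_rxn)
  }
  for (i in seq_len(n_rxn)) {
    id <- rxn$reaction_id[i]
    ss_name <- paste0("SS_", id)
    members <- c(rxn$focal_protein[i],
                 if (!is.na(rxn$competitor_protein[i])) rxn$competitor_protein[i],
                 picks[[i]])
    subsystems[[ss_name]] <- members
    r2p[[id]] <- rxn$focal_protein[i]
    r2s[id] <- ss_name
  }

  truth <- list(
    schema_version = 1L,
    config = unclass(cfg),
    factors = list(growth_rate = g, media = media_of),
    protein_params = list(baseline = b, growth_slope = s, media_effect = m),
    true_log2 = true_log2,
    reactions = rxn,
    constants = constants,
    supply = list(C0 = C0, C = C_c)
  )

  structure(list(
    expression = expression_matrix(observed, proteins, design$condition_id),
    rates = rate_table(rates, rxn$reaction_id, design$condition_id),
    design = design,
    annotations = annotation_map(r2p, subsystems, r2s),
    truth = truth
  ), class = "synthetic_dataset")
}

seq_len2 <- function(n) if (n > 0) seq_len(n) else integer(0)

#' Recompute rates from the truth channel
#'
#' Evaluates each reaction's closed-form rate function on the true enzyme
#' levels recorded in `truth`; used as a self-consistency oracle (the
#' generator's rate table must match to within formatting precision).
#'
#' @param truth the `truth` component of a [generate_dataset()] result.
#' @return reactions x conditions rate matrix.
#' @export
evaluate_truth_rates <- function(truth) {
  e_true <- 2^truth$true_log2
  media_of <- truth$factors$media
  C_c <- truth$supply$C
  rxn <- truth$reactions
  out <- matrix(NA_real_, nrow(rxn), ncol(e_true),
                dimnames = list(rxn$reaction_id, colnames(e_true)))
  for (i in seq_len(nrow(rxn))) {
    id <- rxn$reaction_id[i]
    cst <- truth$constants[[id]]
    fp <- rxn$focal_protein[i]
    out[id, ] <- switch(rxn$type[i],
      simple_constant = cst$k * e_true[fp, ],
      simple_hidden = cst$k * e_true[fp, ] * cst$S_media[media_of[colnames(e_true)]],
      branched = toy_steady_state(cst$k1, cst$k2, C_c, e_true[fp, ],
                                  e_true[rxn$competitor_protein[i], ])$v1)
  }
  out
}

#' Write a synthetic dataset to a directory
#'
#' Emits `expression.tsv`, `rates.tsv`, `conditions.tsv`,
#' `reaction_protein.tsv`, `reaction_subsystem.tsv`, `subsystems.gmt` and a
#' structured `truth.json` sidecar (schema_version 1). Re-reading with
#' [read_dataset()] reproduces the dataset.
#'
#' @param d a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(d$expression, file.path(dir, "expression.tsv"), "expression")
  write_matrix(d$rates, file.path(dir, "rates.tsv"), "rate")
  write_condition_design(d$design, file.path(dir, "conditions.tsv"))
  r2p <- d$annotations$reaction_to_proteins
  writeLines(c("reaction_id\tprotein_id",
               paste(rep(names(r2p), lengths(r2p)),
                     unlist(r2p, use.names = FALSE), sep = "\t")),
             file.path(dir, "reaction_protein.tsv"), useBytes = TRUE)
  r2s <- d$annotations$reaction_to_subsystem
  writeLines(c("reaction_id\tsubsystem",
               paste(names(r2s), r2s, sep = "\t")),
             file.path(dir, "reaction_subsystem.tsv"), useBytes = TRUE)
  write_gmt(d$annotations$subsystem_members, file.path(dir, "subsystems.gmt"))
  truth <- d$truth
  truth$true_log2 <- matrix_to_json_form(truth$true_log2)
  truth$protein_params$media_effect <- matrix_to_json_form(truth$protein_params$media_effect)
  # named vectors are written as JSON objects so names survive the round trip
  truth$protein_params$baseline <- as.list(truth$protein_params$baseline)
  truth$protein_params$growth_slope <- as.list(truth$protein_params$growth_slope)
  truth$factors <- lapply(truth$factors, as.list)
  truth$supply$C <- as.list(truth$supply$C)
  truth$constants <- lapply(truth$constants, function(cst) lapply(cst, as.list))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = FALSE,
                       na = "null")
  invisible(dir)
}

matrix_to_json_form <- function(m) {
  list(row_ids = rownames(m), col_ids = colnames(m),
       values = apply(m, 1L, function(r) unname(as.list(r)), simplify = FALSE))
}

matrix_from_json_form <- function(x) {
  vals <- do.call(rbind, lapply(x$values, function(r) unlist(r)))
  dimnames(vals) <- list(unlist(x$row_ids), unlist(x$col_ids))
  vals
}

#' Read a synthetic dataset written by [write_dataset()]
#'
#' @param dir directory containing the dataset files.
#' @return a `synthetic_dataset` (truth included when `truth.json` is present).
#' @export
read_dataset <- function(dir) {
  expr <- read_matrix(file.path(dir, "expression.tsv"), "expression")
  rates <- read_matrix(file.path(dir, "rates.tsv"), "rate")
  design <- read_condition_design(file.path(dir, "conditions.tsv"))
  ann <- read_annotations(file.path(dir, "reaction_protein.tsv"),
                          file.path(dir, "subsystems.gmt"),
                          file.path(dir, "reaction_subsystem.tsv"))
  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth$true_log2 <- matrix_from_json_form(truth$true_log2)
    truth$protein_params$media_effect <-
      matrix_from_json_form(truth$protein_params$media_effect)
    truth$factors$growth_rate <- unlist(truth$factors$growth_rate)
    truth$factors$media <- unlist(truth$factors$media)
    truth$supply$C <- unlist(truth$supply$C)
    truth$constants <- lapply(truth$constants, function(cst) {
      lapply(cst, unlist)
    })
    truth$protein_params$baseline <- unlist(truth$protein_params$baseline)
    truth$protein_params$growth_slope <- unlist(truth$protein_params$growth_slope)
  }
  structure(list(expression = expr, rates = rates, design = design,
                 annotations = ann, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d proteins x %d conditions, %d reactions\n",
              nrow(x$expression), ncol(x$expression), nrow(x$rates)))
  invisible(x)
}
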