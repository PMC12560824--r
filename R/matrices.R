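#' Construct a validated expression matrix
#'
#' An expression matrix holds linear-scale protein (or transcript) abundances,
#' proteins in rows and growth conditions in columns. Values must be strictly
#' positive so that the log2 transform used throughout the pipeline is defined
#' everywhere, and the matrix must be complete: missing cells are an error,
#' never imputed.
#'
#' @param values numeric matrix (proteins x conditions), all finite and > 0.
#' @param protein_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param condition_ids character vector of unique column identifiers; defaults
#'   to `colnames(values)`.
#' @param units free-text unit annotation carried as an attribute (e.g.
#'   "relative to total protein", "mmol/gCDW").
#' @return a numeric matrix with dimnames set and a `units` attribute.
#' @export
expression_matrix <- function(values, protein_ids = rownames(values),
                              condition_ids = colnames(values),
                              units = "relative") {
  m <- as_id_matrix(values, protein_ids, condition_ids, "protein_id")
  validate_expression_values(m)
  attr(m, "units") <- units
  m
}

#' Construct a validated rate table
#'
#' Reaction rates (fluxes) in rows, conditions in columns. Rates may be zero or
#' negative (reversible reactions), unlike expression values.
#'
#' @param values numeric matrix (reactions x conditions), all finite.
#' @param reaction_ids,condition_ids unique identifiers; default to dimnames.
#' @param units free-text unit annotation (e.g. "umol/h/mL cell volume").
#' @return a numeric matrix with dimnames set and a `units` attribute.
#' @export
rate_table <- function(values, reaction_ids = rownames(values),
                       condition_ids = colnames(values), units = "umol/h") {
  m <- as_id_matrix(values, reaction_ids, condition_ids, "reaction_id")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell at row '%s', column '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  attr(m, "units") <- units
  m
}

as_id_matrix <- function(values, row_ids, col_ids, what) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(row_ids) || is.null(col_ids)) {
    stop("row and column identifiers are required")
  }
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (length(row_ids) != nrow(m) || length(col_ids) != ncol(m)) {
    stop("identifier length does not match matrix dimensions")
  }
  if (anyDuplicated(row_ids)) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(unique(row_ids[duplicated(row_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(col_ids)) {
    stop(sprintf("duplicate condition_id: %s",
                 paste(unique(col_ids[duplicated(col_ids)]), collapse = ", ")))
  }
  dimnames(m) <- list(row_ids, col_ids)
  m
}

validate_expression_values <- function(m) {
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell at row '%s', column '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive expression value %g at row '%s', column '%s' (log2 transform undefined)",
      m[bad[1], bad[2]], rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  invisible(m)
}

#' Read an expression or rate matrix from TSV
#'
#' The on-disk format is tab-separated, UTF-8, "." decimal, no quoting, with a
#' mandatory header whose first cell is `protein_id` (expression) or
#' `reaction_id` (rates) and remaining cells the condition identifiers.
#'
#' @param path file path.
#' @param kind `"expression"` or `"rate"`; expression additionally enforces
#'   strict positivity.
#' @return an [expression_matrix()] or [rate_table()].
#' @export
read_matrix <- function(path, kind = c("expression", "rate")) {
  kind <- match.arg(kind)
  id_col <- if (kind == "expression") "protein_id" else "reaction_id"
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[[1]] != id_col) {
    stop(sprintf("malformed header in %s: first cell must be '%s'", path, id_col))
  }
  cond <- header[-1]
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(rows, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(cond))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1]
    if (length(cells) != length(cond)) {
      stop(sprintf("row %d ('%s') has %d value cells, expected %d",
                   i + 1L, ids[i], length(cells), length(cond)))
    }
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   cells[j], ids[i], cond[j]))
    }
    vals[i, ] <- v
  }
  if (kind == "expression") {
    expression_matrix(vals, ids, cond)
  } else {
    rate_table(vals, ids, cond)
  }
}

#' Write an expression or rate matrix to TSV
#'
#' Values are written with up to 12 significant digits so that a
#' read-write-read round trip is bit-exact for such representations.
#'
#' @param m matrix with dimnames.
#' @param path destination file.
#' @param kind `"expression"` or `"rate"` (sets the header id column).
#' @export
write_matrix <- function(m, path, kind = c("expression", "rate")) {
  kind <- match.arg(kind)
  id_col <- if (kind == "expression") "protein_id" else "reaction_id"
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format_num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

#' Read condition metadata (design) from TSV
#'
#' Three columns: `condition_id`, `media_type`, `growth_rate`. Growth rate is
#' the chemostat dilution rate (per hour) and must be non-negative; the
#' (media_type, growth_rate) pairs must be unique.
#'
#' @param path file path.
#' @return a `data.frame` with columns condition_id, media_type, growth_rate.
#' @export
read_condition_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c("character", "character", "numeric"),
                          fileEncoding = "UTF-8")
  condition_design(df)
}

#' Validate a condition design data frame
#'
#' @param df data.frame with columns condition_id, media_type, growth_rate.
#' @return the validated data frame.
#' @export
condition_design <- function(df) {
  need <- c("condition_id", "media_type", "growth_rate")
  if (!all(need %in% names(df))) {
    stop("condition design must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$condition_id <- as.character(df$condition_id)
  df$media_type <- as.character(df$media_type)
  df$growth_rate <- as.numeric(df$growth_rate)
  if (anyDuplicated(df$condition_id)) stop("duplicate condition_id in design")
  if (any(df$growth_rate < 0)) stop("growth_rate must be non-negative")
  key <- paste(df$media_type, df$growth_rate, sep = "\r")
  if (anyDuplicated(key)) stop("(media_type, growth_rate) pairs must be unique")
  rownames(df) <- NULL
  df
}

#' @export
write_condition_design <- function(df, path) {
  header <- "condition_id\tmedia_type\tgrowth_rate"
  body <- paste(df$condition_id, df$media_type, format_num(df$growth_rate),
                sep = "\t")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Assemble reaction/protein/subsystem annotations
#'
#' @param mapping_path 2-column TSV (reaction_id, protein_id); duplicate pairs
#'   are deduplicated silently.
#' @param gmt_path GMT file: set name, description, then member protein ids,
#'   tab-separated; empty member lists are allowed, empty set names are not.
#' @param reaction_subsystem_path 2-column TSV (reaction_id, subsystem).
#' @return an object of class `annotation_map` with components
#'   `reaction_to_proteins` (named list of character vectors),
#'   `protein_to_subsystems` (named list), and `reaction_to_subsystem`
#'   (named character vector).
#' @export
read_annotations <- function(mapping_path, gmt_path, reaction_subsystem_path) {
  map_df <- read_two_col(mapping_path, c("reaction_id", "protein_id"))
  subsystems <- read_gmt(gmt_path)
  rs_df <- read_two_col(reaction_subsystem_path, c("reaction_id", "subsystem"))
  annotation_map(
    reaction_to_proteins = split_unique(map_df[[2]], map_df[[1]]),
    subsystem_members = subsystems,
    reaction_to_subsystem = stats::setNames(rs_df[[2]], rs_df[[1]])
  )
}

read_two_col <- function(path, expected) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2L)) {
    stop(sprintf("%s: line %d has %d columns, expected 2",
                 path, which(nc != 2L)[1], nc[nc != 2L][1]))
  }
  first <- parts[[1]]
  if (identical(first, expected)) parts <- parts[-1]  # optional header
  data.frame(a = vapply(parts, `[[`, character(1), 1L),
             b = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file path.
#' @return named list of character vectors (unique member ids per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    cells <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(cells) < 2L) {
      stop(sprintf("%s: GMT line %d has fewer than 2 fields", path, i))
    }
    if (!nzchar(cells[[1]])) stop(sprintf("%s: empty set name at line %d", path, i))
    members <- cells[-(1:2)]
    out[[cells[[1]]]] <- unique(members[nzchar(members)])
  }
  out
}

#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

split_unique <- function(values, keys) {
  sp <- split(values, keys)
  lapply(sp, function(v) unique(v))
}

#' Construct an annotation map
#'
#' Relates reactions to the proteins catalysing them, proteins to the
#' subsystems (pathways) they belong to, and reactions to one subsystem each.
#' A reaction may map to 0..many proteins; the bidirectional 1:1 filter used
#' by the focal-enzyme analysis is applied downstream, not here.
#'
#' @param reaction_to_proteins named list: reaction_id -> character vector.
#' @param subsystem_members named list: subsystem -> member protein ids.
#' @param reaction_to_subsystem named character vector: reaction_id -> subsystem.
#' @return object of class `annotation_map`.
#' @export
annotation_map <- function(reaction_to_proteins, subsystem_members,
                           reaction_to_subsystem) {
  p2s <- invert_membership(subsystem_members)
  structure(list(
    reaction_to_proteins = lapply(reaction_to_proteins, unique),
    subsystem_members = subsystem_members,
    protein_to_subsystems = p2s,
    reaction_to_subsystem = reaction_to_subsystem
  ), class = "annotation_map")
}

invert_membership <- function(sets) {
  if (length(sets) == 0) return(list())
  pairs <- data.frame(
    protein = unlist(sets, use.names = FALSE),
    set = rep(names(sets), lengths(sets)),
    stringsAsFactors = FALSE
  )
  split_unique(pairs$set, pairs$protein)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d reactions, %d subsystems, %d annotated proteins\n",
              length(x$reaction_to_proteins), length(x$subsystem_members),
              length(x$protein_to_subsystems)))
  invisible(x)
}

#' Validate annotations against the data matrices
#'
#' Checks that every reaction and protein referenced by the annotation map is
#' present in the paired rate table / expression matrix; unknown identifiers
#' raise an error naming the offenders. Subsystem members absent from the
#' expression matrix are allowed (they are simply unquantified proteins).
#'
#' @param ann annotation_map.
#' @param expr expression matrix.
#' @param rates rate table.
#' @return invisibly, `ann`.
#' @export
validate_annotations <- function(ann, expr, rates) {
  bad_rxn <- setdiff(union(names(ann$reaction_to_proteins),
                           names(ann$reaction_to_subsystem)),
                     rownames(rates))
  if (length(bad_rxn)) {
    stop("annotation references unknown reactions: ",
         paste(sort(bad_rxn), collapse = ", "))
  }
  bad_prot <- setdiff(unlist(ann$reaction_to_proteins, use.names = FALSE),
                      rownames(expr))
  if (length(bad_prot)) {
    stop("reaction-protein mapping references unquantified proteins: ",
         paste(sort(unique(bad_prot)), collapse = ", "))
  }
  invisible(ann)
}

check_paired_conditions <- function(expr, rates) {
  if (!setequal(colnames(expr), colnames(rates))) {
    stop("expression and rate tables must cover the same conditions")
  }
  invisible(TRUE)
}

#' log2-transform an expression matrix
#'
#' @param m strictly positive matrix.
#' @return matrix of the same shape with each cell replaced by log2(value).
#' @export
log2_transform <- function(m) {
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive value at row '%s', column '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  out <- log2(m)
  attr(out, "units") <- NULL
  out
}

#' z-score each protein row across conditions
#'
#' Each row is centred and scaled to sample standard deviation 1 (denominator
#' n - 1) across conditions. Constant rows are an error naming the protein,
#' since their z-score is undefined.
#'
#' @param m matrix (typically log2-transformed abundances), >= 2 columns.
#' @return row-standardized matrix.
#' @export
zscore_by_protein <- function(m) {
  if (ncol(m) < 2L) stop("z-scoring requires at least 2 conditions")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  if (any(sdv == 0)) {
    stop("constant row(s), z-score undefined: ",
         paste(rownames(m)[sdv == 0], collapse = ", "))
  }
  out <- (m - mu) / sdv
  attr(out, "units") <- NULL
  out
}
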