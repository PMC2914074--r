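#' Construct a decoy score table
#'
#' A `score_table` holds one target's decoys scored by one or more scoring
#' functions (knowledge- or physics-based energies such as Rosetta, DFIRE,
#' DOPE; values are produced externally). Scores are oriented so that lower is
#' better. An optional per-decoy RMSD to the native structure (in Angstrom)
#' serves as the ground-truth quality label for evaluation.
#'
#' @param scores Numeric matrix, rows = decoys, columns = scoring functions.
#' @param decoy_ids Character vector of unique, non-empty decoy identifiers;
#'   defaults to the matrix rownames.
#' @param function_names Character vector of unique scoring-function names;
#'   defaults to the matrix colnames.
#' @param rmsd Optional numeric vector of non-negative RMSD values (Angstrom),
#'   one per decoy.
#' @param target_id Single string naming the target.
#' @return An object of class `score_table`: a list with fields `target_id`,
#'   `decoy_ids`, `function_names`, `scores`, `rmsd`.
#' @examples
#' m <- matrix(c(1, 2, 3, 6, 5, 4), ncol = 2,
#'             dimnames = list(c("a", "b", "c"), c("f1", "f2")))
#' score_table(m, rmsd = c(0.3, 1.2, 2.5))
#' @export
score_table <- function(scores, decoy_ids = rownames(scores),
                        function_names = colnames(scores),
                        rmsd = NULL, target_id = "target") {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(decoy_ids)) decoy_ids <- paste0("d", seq_len(nrow(scores)))
  if (is.null(function_names)) function_names <- paste0("f", seq_len(ncol(scores)))
  decoy_ids <- as.character(decoy_ids)
  function_names <- as.character(function_names)
  dimnames(scores) <- list(decoy_ids, function_names)
  obj <- structure(
    list(target_id = as.character(target_id)[1],
         decoy_ids = decoy_ids,
         function_names = function_names,
         scores = scores,
         rmsd = if (!is.null(rmsd)) as.double(rmsd) else NULL),
    class = "score_table")
  validate_score_table(obj)
  obj
}

#' Validate a score table's invariants
#'
#' Checks identifier uniqueness, shape agreement, finiteness of all score
#' entries, and (when present) that RMSD values are finite and non-negative.
#'
#' @param x A `score_table`.
#' @return `x`, invisibly; errors on any violation.
#' @export
validate_score_table <- function(x) {
  stopifnot(inherits(x, "score_table"))
  ids <- x$decoy_ids
  if (length(ids) < 1L) stop("score table must contain at least one decoy")
  if (any(!nzchar(ids))) stop("decoy ids must be non-empty strings")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate decoy ids: ", paste(dup, collapse = ", "))
  if (length(x$function_names) < 1L)
    stop("score table must contain at least one scoring function")
  if (anyDuplicated(x$function_names))
    stop("duplicate scoring-function names")
  if (nrow(x$scores) != length(ids) || ncol(x$scores) != length(x$function_names))
    stop("score matrix shape does not match decoy/function identifiers")
  if (!all(is.finite(x$scores))) {
    bad <- which(!is.finite(x$scores), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite score at decoy '%s', function '%s'",
                 ids[bad[1]], x$function_names[bad[2]]))
  }
  if (!is.null(x$rmsd)) {
    if (length(x$rmsd) != length(ids))
      stop("rmsd length does not match number of decoys")
    if (!all(is.finite(x$rmsd)) || any(x$rmsd < 0))
      stop("rmsd values must be finite and >= 0")
  }
  invisible(x)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<%s> target '%s': %d decoys x %d scoring functions%s\n",
              paste(class(x), collapse = "/"), x$target_id,
              length(x$decoy_ids), length(x$function_names),
              if (is.null(x$rmsd)) "" else ", with RMSD"))
  if (inherits(x, "normalized_score_table"))
    cat(sprintf("  normalization floor delta = %g\n", attr(x, "floor")))
  invisible(x)
}

#' Read a decoy score table from delimited text
#'
#' Expects a header row with an ID column, one or more numeric score columns,
#' and optionally an RMSD column. Lines starting with `#` are skipped. All
#' columns other than the ID and RMSD columns are interpreted as scores.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field delimiter (default tab).
#' @param id_col Name of the decoy-identifier column (default `"decoy"`).
#' @param rmsd_col Name of the RMSD column (default `"rmsd"`).
#' @param use_rmsd If `FALSE`, an RMSD column is ignored even when present.
#' @param target_id Target identifier; defaults to the file name sans extension.
#' @param missing Policy for missing score cells: `"error"` (default) or
#'   `"impute_worst"`, which fills each missing cell with its column's maximum
#'   (worst) raw value and warns. Imputation can alter Pareto fronts, hence the
#'   conservative default.
#' @return A validated `score_table`; the attribute `"score_columns"` records
#'   which columns were interpreted as scores.
#' @export
read_score_table <- function(path, sep = "\t", id_col = "decoy",
                             rmsd_col = "rmsd", use_rmsd = TRUE,
                             target_id = NULL,
                             missing = c("error", "impute_worst")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, na.strings = c("NA", ""))
  if (!id_col %in% names(df))
    stop("ID column '", id_col, "' not found in ", path)
  ids <- as.character(df[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate decoy ids in ", path, ": ", paste(dup, collapse = ", "))
  rmsd <- NULL
  score_cols <- setdiff(names(df), id_col)
  if (rmsd_col %in% names(df)) {
    score_cols <- setdiff(score_cols, rmsd_col)
    if (use_rmsd) rmsd <- as.double(df[[rmsd_col]])
  }
  if (!length(score_cols))
    stop("no score columns found in ", path)
  for (cn in score_cols) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop(sprintf("non-numeric score in column '%s', row %d of %s",
                   cn, if (is.na(bad)) 1L else bad, path))
    }
  }
  m <- as.matrix(df[score_cols])
  if (anyNA(m)) {
    if (missing == "error") {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing score at decoy '%s', column '%s' in %s",
                   ids[bad[1]], score_cols[bad[2]], path))
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) {
        m[nas, j] <- max(m[, j], na.rm = TRUE)
        warning(sprintf("imputed %d missing value(s) in column '%s' with the column worst score",
                        sum(nas), score_cols[j]))
      }
    }
  }
  if (is.null(target_id))
    target_id <- sub("\\.[^.]*$", "", basename(path))
  out <- score_table(m, decoy_ids = ids, function_names = score_cols,
                     rmsd = rmsd, target_id = target_id)
  attr(out, "score_columns") <- score_cols
  out
}

#' Write a score table to delimited text
#'
#' Normalized tables carry a `#normalized floor=<delta>` comment header so the
#' normalization floor travels with the file. Output is UTF-8 with `.` as
#' decimal separator.
#'
#' @param table A `score_table` (or `normalized_score_table`).
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @param id_col,rmsd_col Column names to use on output.
#' @param digits Significant digits for scores (default 12, enough for a
#'   lossless round trip at double precision for typical energies).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path, sep = "\t", id_col = "decoy",
                              rmsd_col = "rmsd", digits = 12) {
  validate_score_table(table)
  df <- data.frame(table$decoy_ids,
                   signif(table$scores, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, table$function_names)
  if (!is.null(table$rmsd)) df[[rmsd_col]] <- signif(table$rmsd, digits)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (inherits(table, "normalized_score_table"))
    writeLines(sprintf("#normalized floor=%g", attr(table, "floor")), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Orient score columns so that lower is uniformly better
#'
#' All five scoring functions used in the loop-modelling study are energies
#' (lower = better); this helper supports arbitrary inputs by negating columns
#' declared higher-is-better.
#'
#' @param table A `score_table`.
#' @param higher_better Character vector of function names whose raw scores
#'   increase with quality; those columns are negated.
#' @return The oriented `score_table`; attribute `"flipped"` records the
#'   negated columns.
#' @export
orient_scores <- function(table, higher_better = character()) {
  validate_score_table(table)
  unknown <- setdiff(higher_better, table$function_names)
  if (length(unknown))
    stop("unknown scoring function(s) in orientation: ",
         paste(unknown, collapse = ", "))
  if (length(higher_better))
    table$scores[, higher_better] <- -table$scores[, higher_better]
  attr(table, "flipped") <- higher_better
  table
}

#' Normalize scores onto (0, 1] per scoring function
#'
#' Each column is mapped by the strictly increasing affine map
#' `g(f) = delta + (1 - delta) * (f - min) / (max - min)` onto the interval
#' `[delta, 1]`. The floor `delta > 0` guarantees strictly positive normalized
#' scores, so the bounded-ratio fuzzy memberships downstream never divide by
#' zero. A column that is constant across decoys maps to all 1, a neutral
#' factor in every fuzzy degree (equivalent to dropping the column).
#'
#' Because `g` is strictly increasing on each non-constant column, the Pareto
#' front of the normalized table equals that of the raw table, and the map is
#' invariant under positive affine transforms of a raw column.
#'
#' @param table A `score_table`, oriented lower-is-better.
#' @param floor The floor `delta`, in `(0, 0.1]`; default `0.01`.
#' @return A `normalized_score_table` (subclass of `score_table`) with every
#'   entry in `(0, 1]` and attribute `"floor"`.
#' @examples
#' tab <- score_table(matrix(c(10, 20, 30), ncol = 1))
#' normalize_scores(tab)$scores  # 0.01, 0.505, 1
#' @export
normalize_scores <- function(table, floor = 0.01) {
  validate_score_table(table)
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0 || floor > 0.1)
    stop("floor must be a single value in (0, 0.1]")
  m <- table$scores
  for (j in seq_len(ncol(m))) {
    lo <- min(m[, j]); hi <- max(m[, j])
    m[, j] <- if (hi > lo) floor + (1 - floor) * (m[, j] - lo) / (hi - lo) else 1
  }
  table$scores <- m
  class(table) <- c("normalized_score_table", "score_table")
  attr(table, "floor") <- floor
  table
}

#' Test whether a table is normalized
#' @param x Object to test.
#' @return `TRUE` for a `normalized_score_table`.
#' @export
is_normalized <- function(x) inherits(x, "normalized_score_table")

# Ensure a normalized table; normalize with defaults when given a raw one.
as_normalized <- function(table, floor = 0.01) {
  if (is_normalized(table)) table else normalize_scores(table, floor = floor)
}
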