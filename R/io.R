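#' Write a ranking to TSV or JSON
#'
#' The TSV carries the columns of the `decoy_ranking` data frame (rank, decoy,
#' method-specific criterion columns, normalized scores). The JSON variant
#' wraps the same rows in an object with a provenance block: method,
#' normalization floor, reference policy where applicable, and package
#' version.
#'
#' @param ranking A `decoy_ranking`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(ranking, "decoy_ranking"))
  prov <- list(method = attr(ranking, "method"),
               target_id = attr(ranking, "target_id"),
               floor = attr(ranking, "floor"),
               reference_policy = attr(ranking, "reference_policy"),
               package = "pocrank",
               version = as.character(utils::packageVersion("pocrank")))
  prov <- prov[!vapply(prov, is.null, logical(1))]
  if (format == "tsv") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("#", names(prov), "=", unlist(prov)), con)
    df <- as.data.frame(ranking)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(provenance = prov, ranking = as.data.frame(ranking)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a target evaluation or aggregate report
#'
#' @param x A `target_evaluation` or `aggregate_report`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (inherits(x, "target_evaluation"))
    cbind(target_id = x$target_id, x$methods)
  else if (inherits(x, "aggregate_report")) x$methods
  else stop("x must be a target_evaluation or aggregate_report")
  if (format == "tsv") {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    out <- if (inherits(x, "aggregate_report"))
      list(n_targets = x$n_targets, methods = df,
           pareto = as.data.frame(x$pareto))
    else list(target_id = x$target_id, methods = x$methods,
              pareto = list(front_size = x$pareto$front_size,
                            front_fraction = x$pareto$front_fraction,
                            coverage = x$pareto$coverage))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Dump a ROC polyline for external plotting
#'
#' @param roc A `roc_curve`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.table(as.data.frame(roc$points), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
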