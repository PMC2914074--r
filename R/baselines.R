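#' Vote configuration for rank-by-vote
#'
#' @param k_percent Vote threshold: each scoring function gives one vote to
#'   each of its top `k_percent`% decoys. Default 2 (the value used in the
#'   consensus-strategy comparison). The number of vote slots per function is
#'   `ceiling(k_percent * N / 100)`, never below 1, so small decoy sets still
#'   cast votes.
#' @param tie_policy How vote-count ties are broken: `"score"` (default, by
#'   mean normalized score then input order) — a documented choice, since the
#'   vote strategy itself does not define one.
#' @return A `vote_config` list.
#' @export
vote_config <- function(k_percent = 2, tie_policy = "score") {
  if (!is.numeric(k_percent) || length(k_percent) != 1L ||
      k_percent <= 0 || k_percent > 100)
    stop("k_percent must be a single value in (0, 100]")
  structure(list(k_percent = k_percent, tie_policy = tie_policy),
            class = "vote_config")
}

# Assemble a baseline ranking data frame in a fixed schema.
make_ranking <- function(table, ord, method, extra = NULL) {
  ids <- table$decoy_ids[ord]
  res <- data.frame(rank = seq_along(ord), decoy = ids,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) for (nm in names(extra)) res[[nm]] <- extra[[nm]][ord]
  res <- cbind(res, as.data.frame(table$scores[ord, , drop = FALSE],
                                  row.names = NULL))
  rownames(res) <- NULL
  structure(res, class = c("decoy_ranking", "data.frame"), method = method,
            floor = attr(table, "floor"), target_id = table$target_id)
}

#' Rank-by-number consensus
#'
#' Decoys are ordered by their mean normalized score across all scoring
#' functions, ascending (lower = better). Ties keep input order.
#'
#' @param table A `score_table` (normalized with defaults when raw, so the
#'   per-function averages are comparable).
#' @return A `decoy_ranking` with a `mean_score` column.
#' @export
rank_by_number <- function(table) {
  table <- as_normalized(table)
  ms <- rowMeans(table$scores)
  ord <- order(ms, seq_along(ms))
  make_ranking(table, ord, "number", list(mean_score = unname(ms)))
}

#' Rank-by-rank consensus
#'
#' Each scoring function ranks the decoys (fractional ranks: ties share the
#' mean rank); decoys are then ordered by their mean rank across functions.
#'
#' @inheritParams rank_by_number
#' @return A `decoy_ranking` with a `mean_rank` column.
#' @export
rank_by_rank <- function(table) {
  table <- as_normalized(table)
  per_fun <- apply(table$scores, 2, rank, ties.method = "average")
  if (is.null(dim(per_fun))) per_fun <- matrix(per_fun, nrow = 1L)
  mr <- rowMeans(per_fun)
  ord <- order(mr, seq_along(mr))
  make_ranking(table, ord, "rank", list(mean_rank = unname(mr)))
}

#' Rank-by-vote consensus
#'
#' Each scoring function casts one vote for each of its best
#' `ceiling(k% * N / 100)` decoys (at least one slot; ties at the slot
#' boundary go to the better score, then input order). Decoys are ordered by
#' descending vote count; vote ties break by mean normalized score, then
#' input order.
#'
#' @inheritParams rank_by_number
#' @param config A [vote_config()].
#' @return A `decoy_ranking` with a `votes` column.
#' @export
rank_by_vote <- function(table, config = vote_config()) {
  table <- as_normalized(table)
  if (!inherits(config, "vote_config")) stop("config must be a vote_config")
  n <- length(table$decoy_ids)
  slots <- max(1L, as.integer(ceiling(config$k_percent * n / 100)))
  votes <- integer(n)
  for (j in seq_len(ncol(table$scores))) {
    top <- order(table$scores[, j], seq_len(n))[seq_len(slots)]
    votes[top] <- votes[top] + 1L
  }
  ms <- rowMeans(table$scores)
  ord <- order(-votes, ms, seq_len(n))
  make_ranking(table, ord, "vote", list(votes = votes))
}

#' Ranking by a single scoring function
#'
#' Plain ascending sort on one score column; the per-function comparator the
#' consensus methods are measured against.
#'
#' @inheritParams rank_by_number
#' @param function_name Name of the scoring function to sort by.
#' @return A `decoy_ranking`; the method attribute is `"single:<name>"`.
#' @export
rank_by_single <- function(table, function_name) {
  table <- as_normalized(table)
  if (!function_name %in% table$function_names)
    stop("unknown scoring function: ", function_name)
  ord <- order(table$scores[, function_name], seq_along(table$decoy_ids))
  make_ranking(table, ord, paste0("single:", function_name))
}

#' Run one or more ranking methods on a table
#'
#' Convenience dispatcher used by the CLI and the evaluation driver.
#'
#' @param table A `score_table`.
#' @param methods Character vector among `"poc"`, `"number"`, `"rank"`,
#'   `"vote"`, `"single:<function>"`, or `"all"` (expands to every consensus
#'   method plus each single function).
#' @param vote A [vote_config()].
#' @param floor Normalization floor for raw tables.
#' @param reference_policy Passed to [poc_rank()].
#' @return Named list of `decoy_ranking` objects.
#' @export
rank_methods <- function(table, methods = "poc", vote = vote_config(),
                         floor = 0.01, reference_policy = "remaining") {
  table <- as_normalized(table, floor = floor)
  if ("all" %in% methods)
    methods <- unique(c(setdiff(methods, "all"), "poc", "number", "rank",
                        "vote", paste0("single:", table$function_names)))
  out <- list()
  for (m in methods) {
    out[[m]] <- if (m == "poc") poc_rank(table, reference_policy)
    else if (m == "number") rank_by_number(table)
    else if (m == "rank") rank_by_rank(table)
    else if (m == "vote") rank_by_vote(table, vote)
    else if (startsWith(m, "single:"))
      rank_by_single(table, sub("^single:", "", m))
    else stop("unknown method: ", m)
  }
  out
}
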