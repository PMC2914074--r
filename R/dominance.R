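#' Crisp Pareto dominance between two score vectors
#'
#' Decoy `u` dominates decoy `v` when `u` is no worse in every scoring
#' function and strictly better in at least one (lower = better).
#'
#' @param u,v Numeric vectors of equal length (normalized scores in `(0, 1]`).
#' @return `TRUE` iff `u` dominates `v`.
#' @examples
#' dominates(c(0.2, 0.2), c(0.4, 0.6))  # TRUE
#' dominates(c(0.3, 0.3), c(0.3, 0.3))  # FALSE: no strict improvement
#' @export
dominates <- function(u, v) {
  if (length(u) != length(v) || length(u) < 1L)
    stop("score vectors must have equal, positive length")
  all(u <= v) && any(u < v)
}

# Pairwise crisp dominance matrix: D[i, j] = TRUE iff decoy i dominates decoy j.
# Accumulated per scoring function with outer comparisons; O(N^2 K).
dominance_matrix <- function(scores) {
  n <- nrow(scores)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(scores))) {
    cmp <- outer(scores[, j], scores[, j], "-")
    le <- le & (cmp <= 0)
    lt <- lt | (cmp < 0)
  }
  le & lt
}

#' Extract the Pareto-optimal front
#'
#' The decoys in `among` that are dominated by no other decoy in `among` form
#' the Pareto-optimal set. It is never empty: a minimal element always exists
#' for a finite set under the dominance partial order.
#'
#' @param table A `normalized_score_table` (a raw `score_table` is normalized
#'   with defaults; the front is identical either way since normalization is
#'   strictly increasing per column).
#' @param among Optional character subset of decoy ids to restrict to;
#'   default all.
#' @return Character vector of front member ids, in input order.
#' @export
pareto_front <- function(table, among = NULL) {
  table <- as_normalized(table)
  if (is.null(among)) among <- table$decoy_ids
  if (!length(among)) stop("'among' must be non-empty")
  unknown <- setdiff(among, table$decoy_ids)
  if (length(unknown))
    stop("unknown decoy id(s): ", paste(unknown, collapse = ", "))
  idx <- match(among, table$decoy_ids)
  sc <- table$scores[idx, , drop = FALSE]
  dom <- dominance_matrix(sc)
  among[colSums(dom) == 0L]
}

#' Bounded division
#'
#' The ratio `x / y` capped at 1, so per-function membership values stay in
#' `(0, 1]`. Equals 1 whenever `x >= y`. Vectorized with recycling.
#'
#' @param x,y Positive numerics.
#' @return `min(1, x / y)`, elementwise.
#' @examples
#' bounded_divide(0.2, 0.4)  # 0.5
#' bounded_divide(0.4, 0.2)  # 1
#' @export
bounded_divide <- function(x, y) {
  if (any(x <= 0) || any(y <= 0))
    stop("bounded division requires strictly positive arguments")
  pmin(1, x / y)
}

#' Fuzzy Pareto dominance degrees for all decoy pairs
#'
#' With the linear membership `min(x, y) / y`, decoy `u` dominates decoy `v`
#' by degree
#' \deqn{\mu_a(u, v) = \prod_i \min(g_i(u), g_i(v)) / g_i(u)}
#' and is dominated by `v` by degree
#' \deqn{\mu_p(u, v) = \prod_i \min(g_i(u), g_i(v)) / g_i(v),}
#' the products running over all normalized scoring functions `g_i`. Each
#' factor is a bounded division, so both degrees lie in `(0, 1]`. A crisp
#' dominator `u` of `v` has `mu_a(u, v) = 1` exactly (every factor capped at
#' 1), while its `mu_p(u, v) < 1` shrinks as the dominance gets stronger —
#' this asymmetry is what lets the method grade dominance strength instead of
#' merely counting dominated models.
#'
#' Role symmetry holds by construction: `mu_a[u, v] == mu_p[v, u]`.
#'
#' Products over many functions are accumulated in log space when the number
#' of functions exceeds 16, avoiding underflow; results agree with the direct
#' product to well below 1e-12.
#'
#' @param table A `normalized_score_table` (raw tables are normalized with
#'   defaults).
#' @return A `fuzzy_dominance_matrix`: list with `decoy_ids` and square
#'   matrices `mu_a` (dominating degrees) and `mu_p` (dominated degrees),
#'   both with unit diagonal.
#' @examples
#' tab <- score_table(rbind(u = c(0.2, 0.2), v = c(0.4, 0.6)))
#' class(tab) <- c("normalized_score_table", class(tab))
#' fuzzy_dominance(tab)$mu_p["u", "v"]  # 1/6
#' @export
fuzzy_dominance <- function(table) {
  table <- as_normalized(table)
  g <- table$scores
  if (any(g <= 0) || any(g > 1))
    stop("normalized scores must lie in (0, 1]")
  n <- nrow(g)
  k <- ncol(g)
  # factor[i, j] for function m: min(g[i,m], g[j,m]) / g[i,m] = min(1, g[j,m]/g[i,m])
  if (k <= 16L) {
    mu_a <- matrix(1, n, n)
    for (m in seq_len(k))
      mu_a <- mu_a * pmin(1, outer(g[, m], g[, m], function(a, b) b / a))
  } else {
    acc <- matrix(0, n, n)
    for (m in seq_len(k))
      acc <- acc + log(pmin(1, outer(g[, m], g[, m], function(a, b) b / a)))
    mu_a <- exp(acc)
  }
  dimnames(mu_a) <- list(table$decoy_ids, table$decoy_ids)
  structure(list(decoy_ids = table$decoy_ids, mu_a = mu_a, mu_p = t(mu_a)),
            class = "fuzzy_dominance_matrix")
}

#' @export
print.fuzzy_dominance_matrix <- function(x, ...) {
  cat(sprintf("<fuzzy_dominance_matrix> %d decoys\n", length(x$decoy_ids)))
  invisible(x)
}

#' Fuzzy ranking value
#'
#' The ranking value `r(x)` of a decoy is the largest degree to which any
#' other decoy in the reference set dominates it (its worst-case fuzzy
#' dominated degree). Smaller is better: a decoy that crisply dominates every
#' other reference decoy is itself dominated only weakly (all its dominated
#' degrees stay below 1) and receives the best rank, while every decoy it
#' crisply dominates carries `r = 1`.
#'
#' @param fdm A `fuzzy_dominance_matrix`.
#' @param members Decoy ids to compute values for.
#' @param reference Decoy ids to rank against; must contain `members`.
#' @return Named numeric vector of ranking values, one per member (0 when the
#'   reference contains no other decoy).
#' @export
ranking_value <- function(fdm, members = fdm$decoy_ids,
                          reference = fdm$decoy_ids) {
  stopifnot(inherits(fdm, "fuzzy_dominance_matrix"))
  if (length(setdiff(members, reference)))
    stop("all members must belong to the reference set")
  if (length(setdiff(reference, fdm$decoy_ids)))
    stop("reference contains unknown decoy ids")
  vapply(members, function(id) {
    others <- setdiff(reference, id)
    if (!length(others)) 0 else max(fdm$mu_p[id, others])
  }, numeric(1))
}

#' Rank a full decoy set by Pareto-optimal consensus
#'
#' The complete POC procedure: identify the Pareto-optimal front, order its
#' members by fuzzy ranking value, remove them, and repeat on the remaining
#' decoys until none are left. Every decoy receives a front index (1 = the
#' Pareto front of the full set) and a ranking value; the global order lists
#' fronts in ascending index, each internally ordered.
#'
#' Under the default `"remaining"` reference policy the ranking value of a
#' front-k member is computed against all decoys still present when that front
#' is extracted (already-peeled fronts have been removed); `"full"` ranks every
#' front against the complete set. Ties on ranking value break by smaller mean
#' normalized score, then input order, so output is deterministic.
#'
#' Fuzzy degrees are computed once on the full set and sliced per front; the
#' pairwise evaluation makes the whole procedure O(N^2) in the number of
#' decoys, practical to roughly 20k decoys.
#'
#' @param table A `score_table`; raw tables are normalized with `floor`.
#' @param reference_policy `"remaining"` (default) or `"full"`.
#' @param floor Normalization floor used when `table` is not yet normalized.
#' @return A `decoy_ranking` data frame with columns `rank`, `decoy`,
#'   `front_index`, `rank_value`, plus one column per normalized scoring
#'   function. Attributes: `method = "poc"`, `floor`, `reference_policy`.
#' @examples
#' tab <- score_table(rbind(A = c(0.2, 0.2), B = c(0.4, 0.6),
#'                          C = c(0.9, 0.3), D = c(0.8, 0.8)))
#' class(tab) <- c("normalized_score_table", class(tab))
#' poc_rank(tab)  # fronts {A}, {B, C}, {D}
#' @export
poc_rank <- function(table, reference_policy = c("remaining", "full"),
                     floor = 0.01) {
  reference_policy <- match.arg(reference_policy)
  table <- as_normalized(table, floor = floor)
  ids <- table$decoy_ids
  n <- length(ids)
  fdm <- fuzzy_dominance(table)
  dom <- dominance_matrix(table$scores)
  mean_score <- rowMeans(table$scores)
  input_pos <- stats::setNames(seq_len(n), ids)

  remaining <- seq_len(n)
  out_id <- character(0); out_front <- integer(0); out_rv <- numeric(0)
  front_k <- 0L
  while (length(remaining)) {
    front_k <- front_k + 1L
    sub <- dom[remaining, remaining, drop = FALSE]
    front <- remaining[colSums(sub) == 0L]
    ref_ids <- if (reference_policy == "remaining") ids[remaining] else ids
    rv <- ranking_value(fdm, members = ids[front], reference = ref_ids)
    ord <- order(rv, mean_score[front], input_pos[ids[front]])
    out_id <- c(out_id, ids[front][ord])
    out_front <- c(out_front, rep.int(front_k, length(front)))
    out_rv <- c(out_rv, rv[ord])
    remaining <- setdiff(remaining, front)
  }
  res <- data.frame(rank = seq_len(n), decoy = out_id,
                    front_index = out_front, rank_value = unname(out_rv),
                    stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(table$scores[out_id, , drop = FALSE],
                                  row.names = NULL))
  rownames(res) <- NULL
  structure(res, class = c("decoy_ranking", "data.frame"),
            method = "poc", floor = attr(table, "floor"),
            reference_policy = reference_policy,
            target_id = table$target_id)
}

#' @export
print.decoy_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<decoy_ranking> method '%s', %d decoys\n",
              attr(x, "method"), nrow(x)))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}
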