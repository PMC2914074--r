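# Independent brute-force oracles and fixture builders used across the suite.

# Wrap a matrix of already-normalized scores (entries in (0,1]) as a table.
norm_table <- function(m, rmsd = NULL, floor = 0.01) {
  tab <- score_table(m, rmsd = rmsd)
  class(tab) <- c("normalized_score_table", "score_table")
  attr(tab, "floor") <- floor
  tab
}

# The four-decoy worked example used throughout: fronts {A}, {B, C}, {D}.
abcd_table <- function() {
  norm_table(rbind(A = c(0.2, 0.2), B = c(0.4, 0.6),
                   C = c(0.9, 0.3), D = c(0.8, 0.8)))
}

# Brute-force crisp dominance: explicit double loop over ordered pairs,
# independent of the package's vectorized matrix path.
oracle_dominates <- function(u, v) all(u <= v) && any(u < v)

oracle_front <- function(scores, among = seq_len(nrow(scores))) {
  keep <- logical(length(among))
  for (a in seq_along(among)) {
    dominated <- FALSE
    for (b in seq_along(among)) {
      if (a != b &&
          oracle_dominates(scores[among[b], ], scores[among[a], ])) {
        dominated <- TRUE
        break
      }
    }
    keep[a] <- !dominated
  }
  among[keep]
}

# Peel fronts with the brute-force oracle; returns front index per row.
oracle_front_partition <- function(scores) {
  n <- nrow(scores)
  front <- integer(n)
  remaining <- seq_len(n)
  k <- 0L
  while (length(remaining)) {
    k <- k + 1L
    f <- oracle_front(scores, remaining)
    front[f] <- k
    remaining <- setdiff(remaining, f)
  }
  front
}

# Mann-Whitney pair-count AUC for a ranked-data ROC: fraction of
# (positive, negative) pairs with the positive ranked better, +1/2 per tie.
oracle_auc_paircount <- function(rank_pos, is_positive) {
  p <- rank_pos[is_positive]
  n <- rank_pos[!is_positive]
  if (!length(p) || !length(n)) stop("need both classes")
  total <- 0
  for (pi in p) total <- total + sum(pi < n) + 0.5 * sum(pi == n)
  total / (length(p) * length(n))
}

# Random normalized table with distinct-ish entries in (0, 1].
random_norm_table <- function(n, k, rmsd = NULL) {
  norm_table(matrix(stats::runif(n * k, 0.01, 1), n, k,
                    dimnames = list(sprintf("r%03d", seq_len(n)), NULL)),
             rmsd = rmsd)
}
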