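#' Evaluation configuration
#'
#' @param near_native_cutoff RMSD cutoff (Angstrom) below which a decoy counts
#'   as near-native; strict `<`. Default 0.5 (the main loop analysis; the
#'   membrane-protein analysis uses 1.0).
#' @param top_list_sizes Top-list sizes for false-positive summaries; default
#'   `c(1, 5)`.
#' @param coverage_cutoffs RMSD margins (Angstrom) for Pareto-front coverage of
#'   the best decoy; default `c(0, 0.1, 0.4)`.
#' @param roc_positive_rank The positive threshold r for the ranked-data ROC is
#'   the `roc_positive_rank`-th best RMSD in the decoy set; default 10.
#' @param roc_policy What to do for decoy sets smaller than
#'   `roc_positive_rank`: `"skip"` (AUC = NA, excluded from aggregate means;
#'   default) or `"error"`.
#' @return An `evaluation_config` list.
#' @export
evaluation_config <- function(near_native_cutoff = 0.5,
                              top_list_sizes = c(1L, 5L),
                              coverage_cutoffs = c(0, 0.1, 0.4),
                              roc_positive_rank = 10L,
                              roc_policy = c("skip", "error")) {
  stopifnot(near_native_cutoff >= 0, all(top_list_sizes >= 1),
            all(coverage_cutoffs >= 0), roc_positive_rank >= 1)
  structure(list(near_native_cutoff = near_native_cutoff,
                 top_list_sizes = as.integer(top_list_sizes),
                 coverage_cutoffs = coverage_cutoffs,
                 roc_positive_rank = as.integer(roc_positive_rank),
                 roc_policy = match.arg(roc_policy)),
            class = "evaluation_config")
}

#' Near-native label
#'
#' A decoy is near-native when its RMSD to the native structure is strictly
#' below the cutoff.
#'
#' @param rmsd Non-negative RMSD values (Angstrom).
#' @param cutoff Cutoff in Angstrom; default 0.5.
#' @return Logical vector.
#' @export
label_near_native <- function(rmsd, cutoff = 0.5) {
  if (any(rmsd < 0)) stop("rmsd must be >= 0")
  rmsd < cutoff
}

# Align an RMSD vector (named, or parallel to a table) with a ranking.
ranked_rmsd <- function(ranking, rmsd) {
  ids <- if (is.data.frame(ranking)) ranking$decoy else as.character(ranking)
  if (is.null(names(rmsd)))
    stop("rmsd must be a named vector (names = decoy ids)")
  missing <- setdiff(ids, names(rmsd))
  if (length(missing))
    stop("rmsd missing for ranked decoy(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  unname(rmsd[ids])
}

#' False-positive summary of a ranking
#'
#' A false positive is a non-near-native decoy placed at a top rank. For each
#' top-list size m this reports whether the top-ranked decoy is a false
#' positive (m = 1) and whether all of the top-m decoys are false positives
#' (m = 5 asks whether the near-native structures are missed entirely in the
#' top five).
#'
#' @param ranking A `decoy_ranking` or character vector of decoy ids in rank
#'   order.
#' @param rmsd Named RMSD vector (names = decoy ids).
#' @param config An [evaluation_config()].
#' @return Data frame with columns `top` (list size), `all_false_positive`.
#' @export
false_positive_summary <- function(ranking, rmsd, config = evaluation_config()) {
  r <- ranked_rmsd(ranking, rmsd)
  nn <- label_near_native(r, config$near_native_cutoff)
  data.frame(top = config$top_list_sizes,
             all_false_positive = vapply(config$top_list_sizes, function(m) {
               m <- min(m, length(nn)); !any(nn[seq_len(m)])
             }, logical(1)))
}

#' Pareto-front coverage of the best decoy
#'
#' For each cutoff c, reports whether the front contains a decoy within c
#' Angstrom of the set-best RMSD (`min(front RMSD) <= min(all RMSD) + c`),
#' together with the front size and the front fraction of the set.
#'
#' @param front Character vector of front member ids.
#' @param rmsd Named RMSD vector over the whole decoy set.
#' @param config An [evaluation_config()].
#' @return List with `coverage` (data frame cutoff/covered), `front_size`,
#'   `front_fraction`, `front_best_rmsd`, `set_best_rmsd`.
#' @export
pareto_coverage <- function(front, rmsd, config = evaluation_config()) {
  stopifnot(length(front) >= 1)
  fb <- min(ranked_rmsd(front, rmsd))
  sb <- min(rmsd)
  list(coverage = data.frame(cutoff = config$coverage_cutoffs,
                             covered = fb <= sb + config$coverage_cutoffs),
       front_size = length(front),
       front_fraction = length(front) / length(rmsd),
       front_best_rmsd = fb, set_best_rmsd = sb)
}

#' Ranked-data ROC curve and AUC
#'
#' ROC construction for a ranking rather than a continuous score: positives
#' are the decoys with RMSD less than or equal to r, where r is the q-th best
#' RMSD in the set (q = `roc_positive_rank`; RMSD ties at r make all tied
#' decoys positive). Sweeping the cutoff N from 0 to the set size, the true
#' positives are the positives among the top-N ranked decoys and the false
#' positives the negatives among them; the curve is the polyline of
#' (FPR(N), TPR(N)) and the AUC its trapezoidal integral. An AUC of 1
#' indicates perfect ranking of the top decoys; 0.5 is representative of a
#' random ranking.
#'
#' @param ranking A `decoy_ranking` or character vector of ids in rank order.
#' @param rmsd Named RMSD vector.
#' @param config An [evaluation_config()]; `roc_positive_rank` gives q.
#' @return A `roc_curve` object: list with `points` (matrix with columns
#'   `fpr`, `tpr`, rows N = 0..set size), `positive_threshold` (r, Angstrom),
#'   `n_positive`, `n_negative`, `auc`.
#' @export
roc_curve <- function(ranking, rmsd, config = evaluation_config()) {
  r_vals <- ranked_rmsd(ranking, rmsd)
  n <- length(r_vals)
  q <- config$roc_positive_rank
  if (n < q)
    stop(sprintf("decoy set (%d) smaller than roc_positive_rank (%d); use a smaller rank",
                 n, q))
  thr <- sort(rmsd)[q]
  pos <- r_vals <= thr
  np <- sum(pos); nn <- n - np
  if (nn == 0L)
    stop("all decoys are positives at this threshold; ROC undefined")
  tpr <- c(0, cumsum(pos) / np)
  fpr <- c(0, cumsum(!pos) / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = cbind(fpr = fpr, tpr = tpr),
                 positive_threshold = unname(thr),
                 n_positive = np, n_negative = nn, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d positives / %d negatives at r = %.3f A, AUC = %.4f\n",
              x$n_positive, x$n_negative, x$positive_threshold, x$auc))
  invisible(x)
}

#' Best RMSD among the top-k ranked decoys
#'
#' @param ranking A `decoy_ranking` or id vector in rank order.
#' @param rmsd Named RMSD vector.
#' @param k Top-list size (uses all decoys when `k` exceeds the set size).
#' @return Minimum RMSD (Angstrom) over the top-k decoys.
#' @export
best_of_top_k_rmsd <- function(ranking, rmsd, k = 5L) {
  stopifnot(k >= 1)
  r <- ranked_rmsd(ranking, rmsd)
  min(r[seq_len(min(k, length(r)))])
}

#' Evaluate a set of rankings of one target against RMSD ground truth
#'
#' @param table A `score_table` with RMSD present.
#' @param rankings Named list of `decoy_ranking` objects (e.g. from
#'   [rank_methods()]).
#' @param config An [evaluation_config()].
#' @param group Optional grouping label (e.g. loop length) carried into
#'   aggregation.
#' @return A `target_evaluation`: list with `target_id`, `group`, `methods`
#'   (data frame: method, per-top-list FP flags, best-of-top-k RMSD, ROC AUC)
#'   and `pareto` (front statistics and coverage from [pareto_coverage()]).
#' @export
evaluate_target <- function(table, rankings, config = evaluation_config(),
                            group = NA_character_) {
  validate_score_table(table)
  if (is.null(table$rmsd))
    stop("target '", table$target_id, "' has no rmsd column; cannot evaluate")
  rmsd <- stats::setNames(table$rmsd, table$decoy_ids)
  norm <- as_normalized(table)
  rows <- lapply(names(rankings), function(m) {
    rk <- rankings[[m]]
    fp <- false_positive_summary(rk, rmsd, config)
    auc <- if (length(rmsd) >= config$roc_positive_rank)
      roc_curve(rk, rmsd, config)$auc
    else if (config$roc_policy == "skip") NA_real_
    else stop("target '", table$target_id, "' smaller than roc_positive_rank")
    row <- data.frame(method = m, roc_auc = auc, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(fp)))
      row[[sprintf("top%d_all_fp", fp$top[i])]] <- fp$all_false_positive[i]
    for (k in config$top_list_sizes)
      row[[sprintf("best_of_top%d_rmsd", k)]] <- best_of_top_k_rmsd(rk, rmsd, k)
    row
  })
  structure(list(target_id = table$target_id, group = group,
                 methods = do.call(rbind, rows),
                 pareto = pareto_coverage(pareto_front(norm), rmsd, config)),
            class = "target_evaluation")
}

#' Aggregate per-target evaluations
#'
#' Rolls per-target results up to per-method counts and means: number and
#' fraction of targets whose top-1 (top-5, ...) decoys are all false
#' positives, mean ROC AUC (NA AUCs excluded), and mean best-of-top-k RMSD —
#' optionally grouped by the targets' group label — plus Pareto coverage
#' counts per cutoff and the mean front fraction.
#'
#' @param evals List of `target_evaluation` objects with identical method sets.
#' @param by_group If `TRUE`, method summaries are additionally split by the
#'   group label.
#' @return An `aggregate_report`: list with `n_targets`, `methods` (data
#'   frame), optional `methods_by_group`, and `pareto` (data frame
#'   cutoff/covered count/fraction + mean front fraction attribute).
#' @export
aggregate_evaluations <- function(evals, by_group = FALSE) {
  stopifnot(length(evals) >= 1)
  msets <- lapply(evals, function(e) sort(e$methods$method))
  if (!all(vapply(msets, identical, logical(1), msets[[1]])))
    stop("inconsistent method sets across targets")
  per <- do.call(rbind, lapply(evals, function(e)
    cbind(target_id = e$target_id, group = e$group, e$methods)))
  summarise <- function(df) {
    flag_cols <- grep("_all_fp$", names(df), value = TRUE)
    rmsd_cols <- grep("^best_of_top", names(df), value = TRUE)
    do.call(rbind, lapply(split(df, df$method), function(d) {
      row <- data.frame(method = d$method[1], n_targets = nrow(d),
                        mean_roc_auc = mean(d$roc_auc, na.rm = TRUE),
                        stringsAsFactors = FALSE)
      for (fc in flag_cols) {
        row[[sub("_all_fp$", "_fp_count", fc)]] <- sum(d[[fc]])
        row[[sub("_all_fp$", "_fp_fraction", fc)]] <- mean(d[[fc]])
      }
      for (rc in rmsd_cols) row[[paste0("mean_", rc)]] <- mean(d[[rc]])
      row
    }))
  }
  methods <- summarise(per)
  rownames(methods) <- NULL
  cov <- do.call(rbind, lapply(evals, function(e) e$pareto$coverage$covered))
  pareto <- data.frame(cutoff = evals[[1]]$pareto$coverage$cutoff,
                       covered_count = colSums(cov),
                       covered_fraction = colMeans(cov))
  attr(pareto, "mean_front_fraction") <-
    mean(vapply(evals, function(e) e$pareto$front_fraction, numeric(1)))
  out <- list(n_targets = length(evals), methods = methods, pareto = pareto)
  if (by_group) {
    out$methods_by_group <- do.call(rbind, lapply(
      split(per, per$group), function(d) cbind(group = d$group[1], summarise(d))))
    rownames(out$methods_by_group) <- NULL
  }
  structure(out, class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf("<aggregate_report> %d targets\n", x$n_targets))
  print.data.frame(x$methods, digits = 4)
  invisible(x)
}
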