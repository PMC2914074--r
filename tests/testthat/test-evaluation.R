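test_that("near-native labelling is strict at the cutoff", {
  expect_true(label_near_native(0.49, 0.5))
  expect_false(label_near_native(0.5, 0.5))
  expect_true(label_near_native(0.17, 0.5))   # a typical best loop decoy
  expect_equal(label_near_native(c(0.2, 0.9, 1.1), 1.0),
               c(TRUE, TRUE, FALSE))
  expect_error(label_near_native(-0.1), ">= 0")
})

test_that("false-positive summary flags top-1 and all-of-top-5", {
  rmsd <- c(t1 = 0.6, t2 = 0.7, t3 = 0.9, t4 = 1.2, t5 = 0.4, t6 = 0.1)
  fp <- false_positive_summary(paste0("t", 1:6), rmsd)
  expect_equal(fp$all_false_positive, c(TRUE, FALSE))  # t5 rescues the top 5
  allbad <- false_positive_summary(paste0("t", 1:4), rmsd[1:4])
  expect_equal(allbad$all_false_positive, c(TRUE, TRUE))
  good <- false_positive_summary(c("t6", "t1", "t2", "t3", "t4"), rmsd)
  expect_equal(good$all_false_positive, c(FALSE, FALSE))
  expect_error(false_positive_summary(c("t1", "zz"), rmsd), "zz")
})

test_that("pareto coverage compares the front's best RMSD to the set best", {
  rmsd <- c(a = 0.17, b = 0.25, c = 0.60, d = 2.0)
  cov <- pareto_coverage(c("a", "c"), rmsd)
  expect_equal(cov$coverage$covered, c(TRUE, TRUE, TRUE))  # best decoy in front
  cov2 <- pareto_coverage(c("b", "d"), rmsd)
  expect_equal(cov2$coverage$covered, c(FALSE, TRUE, TRUE)) # 0.25 <= 0.17+0.1
  cov3 <- pareto_coverage(c("c", "d"), rmsd)
  expect_equal(cov3$coverage$covered, c(FALSE, FALSE, FALSE)) # 0.6 > 0.57
  expect_equal(cov2$front_fraction, 0.5)
  expect_equal(cov2$front_best_rmsd, 0.25)
})

test_that("ranked-data ROC has the stated endpoints and worked values", {
  rmsd <- stats::setNames(c(0.1, 0.2, 0.3, 0.4, 0.8, 0.9, 1.2, 1.5, 2, 3,
                            4, 5), paste0("d", 1:12))
  cfg <- evaluation_config(roc_positive_rank = 4)
  perfect <- roc_curve(names(sort(rmsd)), rmsd, cfg)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$positive_threshold, 0.4)
  expect_equal(perfect$points[1, ], c(fpr = 0, tpr = 0))
  expect_equal(perfect$points[13, ], c(fpr = 1, tpr = 1))
  expect_true(all(diff(perfect$points[, "fpr"]) >= 0))
  expect_true(all(diff(perfect$points[, "tpr"]) >= 0))
  reversed <- roc_curve(rev(names(sort(rmsd))), rmsd, cfg)
  expect_equal(reversed$auc, 0)

  # 4 decoys, q = 2, positives at ranks 2 and 4: hand trapezoid gives 0.25
  r4 <- c(p1 = 0.1, p2 = 0.2, n1 = 1, n2 = 2)
  roc <- roc_curve(c("n1", "p1", "n2", "p2"), r4,
                   evaluation_config(roc_positive_rank = 2))
  expect_equal(unname(roc$points[, "fpr"]), c(0, 0.5, 0.5, 1, 1))
  expect_equal(unname(roc$points[, "tpr"]), c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$auc, 0.25)

  expect_error(roc_curve(names(r4), r4, evaluation_config(roc_positive_rank = 9)),
               "smaller")
})

test_that("RMSD ties at the positive threshold all count as positives", {
  rmsd <- stats::setNames(c(0.1, 0.3, 0.3, 0.3, 1, 2, 3, 4, 5, 6),
                          paste0("d", 1:10))
  roc <- roc_curve(paste0("d", 1:10), rmsd,
                   evaluation_config(roc_positive_rank = 2))
  expect_equal(roc$n_positive, 4L)  # threshold 0.3 captures the tied trio
})

test_that("trapezoid AUC equals the pair-count oracle on random instances", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(12:60, 1)
    rmsd <- stats::setNames(stats::runif(n, 0, 5), sprintf("x%03d", 1:n))
    ranking <- sample(names(rmsd))
    cfg <- evaluation_config(roc_positive_rank = sample(2:10, 1))
    roc <- roc_curve(ranking, rmsd, cfg)
    pos <- unname(rmsd[ranking]) <= roc$positive_threshold
    expect_equal(roc$auc,
                 oracle_auc_paircount(seq_len(n), pos), tolerance = 1e-12)
  }
})

test_that("best-of-top-k picks the minimum RMSD in the head of the ranking", {
  rmsd <- c(a = 0.6, b = 0.7, c = 0.9, d = 1.2, e = 0.4, f = 0.05)
  rk <- c("a", "b", "c", "d", "e", "f")
  expect_equal(best_of_top_k_rmsd(rk, rmsd, 5), 0.4)
  expect_equal(best_of_top_k_rmsd(rk, rmsd, 1), 0.6)
  expect_equal(best_of_top_k_rmsd(rk, rmsd, 6), 0.05)
  expect_equal(best_of_top_k_rmsd(rk, rmsd, 99), 0.05)  # clamps to set size
})

test_that("metrics ignore permutations below the inspected depth", {
  rmsd <- stats::setNames(stats::runif(30, 0, 3), sprintf("p%02d", 1:30))
  set.seed(13)
  base <- names(rmsd)
  shuffled <- c(base[1:5], sample(base[6:30]))
  expect_identical(false_positive_summary(base, rmsd),
                   false_positive_summary(shuffled, rmsd))
  expect_identical(best_of_top_k_rmsd(base, rmsd, 5),
                   best_of_top_k_rmsd(shuffled, rmsd, 5))
})

test_that("target evaluation and aggregation roll metrics up per method", {
  tab1 <- generate_decoy_set(synthetic_config(n_decoys = 40, n_functions = 3,
                                              seed = 101), "tgt1")
  tab2 <- generate_decoy_set(synthetic_config(n_decoys = 40, n_functions = 3,
                                              seed = 102), "tgt2")
  cfg <- evaluation_config()
  ev1 <- evaluate_target(tab1, rank_methods(tab1, c("poc", "number")), cfg, "L4")
  ev2 <- evaluate_target(tab2, rank_methods(tab2, c("poc", "number")), cfg, "L8")
  expect_setequal(ev1$methods$method, c("poc", "number"))
  expect_true(all(ev1$methods$roc_auc >= 0 & ev1$methods$roc_auc <= 1))

  agg <- aggregate_evaluations(list(ev1, ev2), by_group = TRUE)
  expect_equal(agg$n_targets, 2)
  expect_equal(agg$methods$mean_roc_auc[agg$methods$method == "poc"],
               mean(c(ev1$methods$roc_auc[ev1$methods$method == "poc"],
                      ev2$methods$roc_auc[ev2$methods$method == "poc"])))
  expect_equal(agg$methods$top1_fp_fraction,
               (ev1$methods$top1_all_fp + ev2$methods$top1_all_fp)[order(ev1$methods$method)] / 2,
               ignore_attr = TRUE)
  expect_equal(nrow(agg$methods_by_group), 4)
  # single target: aggregate equals its own evaluation
  solo <- aggregate_evaluations(list(ev1))
  expect_equal(solo$methods$mean_roc_auc,
               ev1$methods$roc_auc[order(ev1$methods$method)],
               ignore_attr = TRUE)

  ev_other <- ev2; ev_other$methods <- ev_other$methods[1, ]
  expect_error(aggregate_evaluations(list(ev1, ev_other)), "inconsistent")
})

test_that("small decoy sets follow the ROC exclusion policy", {
  tab <- generate_decoy_set(synthetic_config(n_decoys = 5, n_functions = 2,
                                             seed = 3), "tiny")
  ev <- evaluate_target(tab, rank_methods(tab, "poc"), evaluation_config())
  expect_true(is.na(ev$methods$roc_auc))
  expect_error(
    evaluate_target(tab, rank_methods(tab, "poc"),
                    evaluation_config(roc_policy = "error")),
    "roc_positive_rank")
  # NA AUCs drop out of aggregate means
  big <- generate_decoy_set(synthetic_config(n_decoys = 40, n_functions = 2,
                                             seed = 4), "big")
  evb <- evaluate_target(big, rank_methods(big, "poc"), evaluation_config())
  agg <- aggregate_evaluations(list(ev, evb))
  expect_equal(agg$methods$mean_roc_auc, evb$methods$roc_auc)
})
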