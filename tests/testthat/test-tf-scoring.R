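# Classifier machinery: AUC-PR against a threshold-enumeration oracle,
# cost tuning, cross-validation, baselines, scaled scores, feature
# importance and the score-bin diagnostic.

# A feature matrix where module M0001 linearly separates the positives.
separable_G <- function(n_pos = 5, n_neg = 15, seed = 1) {
  n <- n_pos + n_neg
  withr::with_seed(seed, {
    G <- cbind(M0001 = c(rep(0.9, n_pos), rep(0.1, n_neg)) + runif(n, 0, 0.02),
               M0002 = runif(n), M0003 = runif(n))
  })
  rownames(G) <- sprintf("tf%02d", seq_len(n))
  G
}

separable_labels <- function(n_pos = 5, n_neg = 15, families = 4) {
  n <- n_pos + n_neg
  label_set(sprintf("tf%02d", seq_len(n)),
            c(rep("positive", n_pos), rep("negative", n_neg)),
            family = sprintf("F%d", ((seq_len(n) - 1) %% families) + 1))
}

test_that("AUC-PR equals the brute-force threshold oracle, ties included", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      n <- sample(4:20, 1)
      scores <- sample(round(runif(n), 2))  # rounding forces ties
      labels <- runif(n) < 0.4
      if (!any(labels)) labels[1] <- TRUE
      expect_equal(auc_pr(scores, labels), aucpr_oracle(scores, labels),
                   tolerance = 1e-14)
    }
  })
  # perfect separation
  expect_equal(auc_pr(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1.0)
  expect_error(auc_pr(1:3, rep(FALSE, 3)), "no positive")
})

test_that("the cost grid has 100 points and ties resolve to the smallest C", {
  G <- separable_G()
  lab <- separable_labels()
  tuned <- tune_c(G, lab, seed = 3)
  expect_equal(nrow(tuned$grid), 100)
  expect_equal(tuned$grid$C[1], 0.001)
  expect_equal(tuned$grid$C[100], 9.901, tolerance = 1e-9)
  plateau <- tuned$grid$C[tuned$grid$mean_auc_pr ==
                            max(tuned$grid$mean_auc_pr)]
  expect_equal(tuned$C, min(plateau))

  all_pos <- label_set(rownames(G), rep("positive", nrow(G)),
                       require_both_classes = FALSE)
  expect_error(tune_c(G, all_pos, seed = 1), "both classes|both a positive")
})

test_that("cross-validation is seeded, near-perfect when separable, and null when permuted", {
  G <- separable_G()
  lab <- separable_labels()
  cv <- crossvalidate(G, lab, C = 1, n_runs = 3, seed = 5)
  expect_equal(cv$mean_auc_pr, 1.0)
  expect_identical(cv, crossvalidate(G, lab, C = 1, n_runs = 3, seed = 5))
  expect_true(all(abs(table(cv$folds$run)[] - 5) == 0))

  # label permutation: mean AUC-PR near the positive prevalence (held-out
  # folds of 100 examples keep the null's small-sample bias below the band)
  G_big <- separable_G(125, 375)
  lab_big <- separable_labels(125, 375)
  withr::with_seed(8, {
    perm <- lab_big
    perm$label <- sample(perm$label)
  })
  cv_null <- crossvalidate(G_big, perm, C = 1, n_runs = 10, seed = 6)
  prevalence <- mean(lab_big$label == "positive")
  expect_lt(abs(cv_null$mean_auc_pr - prevalence), 0.1)
})

test_that("baselines redraw labels as specified", {
  G <- separable_G(6, 18)
  lab <- separable_labels(6, 18, families = 3)
  # family-matched draws preserve the positive family histogram
  b <- baseline(G, lab, "family_matched", C = 1, n_runs = 3, seed = 9)
  expect_s3_class(b, "cv_report")
  expect_equal(length(unique(b$folds$run)), 3)
  fam_of <- setNames(lab$family, lab$tf_id)
  want_hist <- table(fam_of[lab$tf_id[lab$label == "positive"]])
  for (pos in b$draws) {
    expect_identical(table(fam_of[pos])[names(want_hist)], want_hist)
  }
  # n_runs = 0 gives an empty report
  empty <- baseline(G, lab, "uniform", C = 1, n_runs = 0, seed = 1)
  expect_equal(nrow(empty$folds), 0)
  expect_true(is.na(empty$mean_auc_pr))
})

test_that("uniform baseline underperforms the true labels on separable data", {
  G <- separable_G()
  lab <- separable_labels()
  cv <- crossvalidate(G, lab, C = 1, n_runs = 10, seed = 11)
  bu <- baseline(G, lab, "uniform", C = 1, n_runs = 10, seed = 12)
  tt <- t.test(cv$run_means, bu$run_means, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})

test_that("scores scale ranks to [0, 1] with deterministic, feature-consistent margins", {
  G <- separable_G()
  lab <- separable_labels()
  st <- score_all(G, lab, C = 1, seed = 21)
  expect_setequal(st$tf_id, rownames(G))
  expect_identical(sort(st$rank), 1:nrow(G))
  expect_equal(max(st$score), 1.0)
  expect_equal(min(st$score), 0.0)
  # strictly decreasing in rank
  expect_true(all(diff(st$score[order(st$rank)]) < 0))
  expect_identical(as.data.frame(st),
                   as.data.frame(score_all(G, lab, C = 1, seed = 21)))

  # two TFs with identical features and identical label status get equal D
  G2 <- rbind(G, tfdup = G["tf01", ])
  rownames(G2)[nrow(G2)] <- "tf99"
  lab2 <- rbind(lab, data.frame(tf_id = "tf99", label = "positive",
                                family = "F1"))
  # place the duplicate pair: tf01 labeled, tf99 unlabeled
  st2 <- score_all(G2, lab, C = 1, seed = 21)
  m <- attr(st2, "models")
  d_tf01 <- mean(vapply(m, function(mm) {
    sum(G2["tf01", ] * mm$w) + mm$b
  }, numeric(1)))
  d_tf99 <- st2$margin[st2$tf_id == "tf99"]
  expect_lt(abs(d_tf01 - d_tf99), 1e-9)
})

test_that("planted discriminative modules dominate feature importance", {
  G <- separable_G()
  lab <- separable_labels()
  st <- score_all(G, lab, C = 1, seed = 2)
  fi <- feature_importance(st)
  expect_identical(fi$module_id[1], "M0001")
  expect_true(all(fi$importance >= 0))

  # constant feature gets (numerically) zero weight
  G3 <- cbind(G, M0004 = 0.5)
  st3 <- score_all(G3, lab, C = 1, seed = 2)
  fi3 <- feature_importance(st3)
  expect_lt(fi3$importance[fi3$module_id == "M0004"], 1e-8)

  # importance is invariant to column order
  G4 <- G[, c(3, 1, 2)]
  st4 <- score_all(G4, lab, C = 1, seed = 2)
  fi4 <- feature_importance(st4)
  expect_equal(fi4$importance[match(fi$module_id, fi4$module_id)],
               fi$importance, tolerance = 1e-9)

  expect_identical(top_modules(fi, 0.3), "M0001")
})

test_that("score bins partition the TFs with the remainder on leading bins", {
  gt <- simulate_grn(2, 2, 6, p_bg = 0, seed = 61)
  expr <- simulate_expression(gt, 20, 20, seed = 62)
  n <- length(gt$tfs)
  st <- data.frame(tf_id = gt$tfs, margin = rev(seq_len(n)),
                   rank = seq_len(n), score = 1 - (seq_len(n) - 1) / (n - 1))
  class(st) <- c("score_table", "data.frame")
  dd <- decile_diagnostic(st, expr, n_bins = 4, n_folds = 2, group_size = 2,
                          seed = 63)
  expect_identical(dd$n_tfs, rep(1L, 4))
  expect_equal(dd$group, c(1, 1, 2, 2))

  # 4 TFs in 3 bins: the remainder goes to the leading bin
  dd3 <- decile_diagnostic(st, expr, n_bins = 3, n_folds = 2, group_size = 3,
                           seed = 63)
  expect_identical(dd3$n_tfs, c(2L, 1L, 1L))

  # TFs absent from the expression matrix: bins reported missing, not an error
  st2 <- data.frame(tf_id = sprintf("x%02d", 1:23), margin = 23:1,
                    rank = 1:23, score = seq(1, 0, length.out = 23))
  class(st2) <- c("score_table", "data.frame")
  dd2 <- decile_diagnostic(st2, expr, n_bins = 10, n_folds = 2,
                           group_size = 5, seed = 64)
  expect_true(all(is.na(dd2$auc_roc)))
})
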