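# Supervised prioritization of regulators: linear-margin SVM on the
# TF x module feature matrix, cross-validation machinery, randomized
# baselines, scaled scores and the per-bin sample-classification
# diagnostic.

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve: thresholds sweep the
#' unique score values in descending order and the area is
#' `sum (R_i - R_{i-1}) * P_i`. Ties in score enter the curve together.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive.
#' @param n_positives Total number of positives for the recall denominator;
#'   defaults to `sum(labels)`. Supply a larger value when `scores` covers
#'   only part of the positive universe (e.g. a truncated edge ranking).
#' @return AUC-PR in `[0, 1]`.
#' @export
auc_pr <- function(scores, labels, n_positives = NULL) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop_located("length mismatch")
  P <- n_positives %||% sum(labels)
  if (P == 0) stop_located("no positive examples: AUC-PR undefined")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores into single thresholds
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_group]
  n_pred <- seq_along(s)[last_of_group]
  precision <- tp / n_pred
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate with average ranks on ties.
#'
#' @inheritParams auc_pr
#' @return AUC-ROC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_located("need both classes for AUC-ROC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified folds: positives then negatives are shuffled and dealt
# round-robin, continuing the rotation across classes so total fold sizes
# differ by at most one while each class is spread as evenly as possible.
make_folds <- function(labels, n_folds, seed) {
  pos <- which(labels); neg <- which(!labels)
  with_rng(seed, {
    pos <- sample(pos); neg <- sample(neg)
  })
  units <- c(pos, neg)
  fold <- rep_len(seq_len(n_folds), length(units))
  out <- integer(length(labels))
  out[units] <- fold
  out
}

# Linear SVM fit returning an explicit hyperplane (w, b) oriented so that
# larger decision values mean "more positive". X rows are examples.
fit_linear_svm <- function(X, y, C, class_weights = NULL) {
  yf <- factor(ifelse(y, "positive", "negative"),
               levels = c("negative", "positive"))
  fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = C,
                    scale = FALSE, class.weights = class_weights)
  w <- drop(crossprod(fit$SV, fit$coefs))
  b <- -fit$rho
  d <- drop(X %*% w) + b
  if (mean(d[y]) < mean(d[!y])) { w <- -w; b <- -b }
  list(w = stats::setNames(w, colnames(X)), b = b)
}

svm_decision <- function(model, X) drop(X %*% model$w) + model$b

#' Tune the SVM cost parameter over a grid
#'
#' Evaluates every C on the grid `seq(lo, hi, by = step)` by stratified
#' `n_folds` cross-validated mean AUC-PR (the same fold split for every C)
#' and returns the maximizer; ties go to the smallest C.
#'
#' @param G TF x module feature matrix.
#' @param labels Label set; labeled TFs must have rows in `G` and both
#'   classes must be present.
#' @param grid Numeric `(lo, hi, step)`; default `c(0.001, 10, 0.1)` gives
#'   100 grid points.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param class_weights Optional named weights (`positive`, `negative`)
#'   for cost-sensitive training; `"inverse"` uses inverse class
#'   prevalence. Default `NULL` (unweighted).
#' @return List with `C` (chosen cost) and `grid` (data.frame C,
#'   mean_auc_pr).
#' @export
tune_c <- function(G, labels, grid = c(0.001, 10, 0.1), n_folds = 5, seed = 1,
                   class_weights = NULL) {
  prep <- prep_training(G, labels)
  cs <- grid[1] + grid[3] * (0:floor((grid[2] - grid[1]) / grid[3]))
  folds <- valid_folds(prep$y, n_folds, seed)
  res <- vapply(cs, function(C) {
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      m <- fit_linear_svm(prep$X[tr, , drop = FALSE], prep$y[tr], C,
                          resolve_weights(class_weights, prep$y[tr]))
      auc_pr(svm_decision(m, prep$X[!tr, , drop = FALSE]), prep$y[!tr])
    }, numeric(1)))
  }, numeric(1))
  list(C = cs[which.max(res)], grid = data.frame(C = cs, mean_auc_pr = res))
}

prep_training <- function(G, labels) {
  validate_label_set(labels)
  keep <- labels$tf_id %in% rownames(G)
  if (!all(keep)) {
    log_msg(sum(!keep), " labeled TF(s) have no feature row and are ignored")
  }
  labels <- labels[keep, , drop = FALSE]
  y <- labels$label == "positive"
  if (!any(y) || all(y)) {
    stop_located("training needs both classes among TFs with feature rows")
  }
  list(X = G[labels$tf_id, , drop = FALSE], y = y, labels = labels)
}

resolve_weights <- function(class_weights, y) {
  if (is.null(class_weights)) return(NULL)
  if (identical(class_weights, "inverse")) {
    n <- length(y)
    return(c(positive = n / (2 * sum(y)), negative = n / (2 * sum(!y))))
  }
  class_weights
}

# Folds where every fold contains both classes; redrawn (and logged) up to
# `max_tries` times.
valid_folds <- function(y, n_folds, seed, max_tries = 100) {
  seeds <- derive_seeds(seed, max_tries)
  for (i in seq_len(max_tries)) {
    folds <- make_folds(y, n_folds, seeds[i])
    ok <- all(vapply(seq_len(n_folds), function(f) {
      any(y[folds == f]) && any(!y[folds == f])
    }, logical(1)))
    if (ok) {
      if (i > 1) log_msg("fold split redrawn ", i - 1, " time(s)")
      return(folds)
    }
  }
  stop_located("could not build folds with both classes in every fold after ",
               max_tries, " attempts")
}

#' Repeated cross-validation of the classifier
#'
#' For each of `n_runs` runs a fresh stratified `n_folds` split is drawn;
#' the model is trained on the remaining folds and the held-out fold's
#' decision values yield the fold AUC-PR.
#'
#' @inheritParams tune_c
#' @param C SVM cost parameter.
#' @param n_runs Number of independent runs (default 10).
#' @return A `cv_report` list: `folds` (data.frame run, fold, auc_pr),
#'   `mean_auc_pr`, `run_means`, `C`, `seed`.
#' @export
crossvalidate <- function(G, labels, C = 1, n_folds = 5, n_runs = 10,
                          seed = 1, class_weights = NULL) {
  prep <- prep_training(G, labels)
  run_seeds <- derive_seeds(seed, max(n_runs, 1))
  rows <- list()
  for (r in seq_len(n_runs)) {
    folds <- valid_folds(prep$y, n_folds, run_seeds[r])
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      m <- fit_linear_svm(prep$X[tr, , drop = FALSE], prep$y[tr], C,
                          resolve_weights(class_weights, prep$y[tr]))
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, fold = f,
        auc_pr = auc_pr(svm_decision(m, prep$X[!tr, , drop = FALSE]),
                        prep$y[!tr]))
    }
  }
  folds_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = integer(), fold = integer(), auc_pr = numeric())
  run_means <- if (nrow(folds_df)) {
    tapply(folds_df$auc_pr, folds_df$run, mean)
  } else numeric(0)
  structure(list(folds = folds_df,
                 mean_auc_pr = if (nrow(folds_df)) mean(folds_df$auc_pr) else NA_real_,
                 run_means = as.numeric(run_means), C = C, seed = seed),
            class = "cv_report")
}

#' Randomized-label baselines for the classifier
#'
#' `uniform`: the positive class is replaced by a uniformly random TF set
#' of the same size, negatives are re-drawn from the remaining pool.
#' `family_matched`: random positives are drawn to match the original
#' positive set's family composition (families with too few members are
#' sampled with replacement, logged); negatives again come from the
#' remaining pool. Each run draws fresh labels and runs one stratified
#' `n_folds` cross-validation.
#'
#' @inheritParams crossvalidate
#' @param mode `"uniform"` or `"family_matched"`.
#' @return A `cv_report` as from [crossvalidate()] (empty when
#'   `n_runs = 0`), with the drawn positive sets in `$draws`.
#' @export
baseline <- function(G, labels, mode = c("uniform", "family_matched"),
                     C = 1, n_folds = 5, n_runs = 10, seed = 1,
                     class_weights = NULL) {
  mode <- match.arg(mode)
  prep <- prep_training(G, labels)
  lab <- prep$labels
  pool <- rownames(G)
  n_pos <- sum(prep$y)
  n_neg <- sum(!prep$y)
  run_seeds <- derive_seeds(seed, max(n_runs, 1))
  rows <- list()
  draws <- list()
  for (r in seq_len(n_runs)) {
    drawn <- with_rng(run_seeds[r], {
      if (mode == "uniform") {
        pos <- sample(pool, n_pos)
      } else {
        fam <- lab$family[prep$y]
        if (anyNA(fam)) stop_located("family_matched baseline needs family tags")
        fam_of <- stats::setNames(lab$family, lab$tf_id)
        pos <- character(0)
        for (fm in names(table(fam))) {
          members <- lab$tf_id[!is.na(fam_of[lab$tf_id]) & fam_of[lab$tf_id] == fm]
          need <- sum(fam == fm)
          if (length(members) < need) {
            log_msg("family ", fm, " has ", length(members),
                    " member(s) for ", need, " draws; sampling with replacement")
            pos <- c(pos, sample(members, need, replace = TRUE))
          } else {
            pos <- c(pos, sample(members, need))
          }
        }
        pos <- unique(pos)
      }
      neg_pool <- setdiff(pool, pos)
      neg <- sample(neg_pool, min(n_neg, length(neg_pool)))
      list(pos = pos, neg = neg)
    })
    rl <- label_set(c(drawn$pos, drawn$neg),
                    c(rep("positive", length(drawn$pos)),
                      rep("negative", length(drawn$neg))))
    cv <- crossvalidate(G, rl, C = C, n_folds = n_folds, n_runs = 1,
                        seed = run_seeds[r], class_weights = class_weights)
    cvf <- cv$folds
    if (nrow(cvf)) cvf$run <- r
    rows[[length(rows) + 1L]] <- cvf
    draws[[r]] <- drawn$pos
  }
  folds_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = integer(), fold = integer(), auc_pr = numeric())
  run_means <- if (nrow(folds_df)) tapply(folds_df$auc_pr, folds_df$run, mean) else numeric(0)
  structure(list(folds = folds_df,
                 mean_auc_pr = if (nrow(folds_df)) mean(folds_df$auc_pr) else NA_real_,
                 run_means = as.numeric(run_means), C = C, seed = seed,
                 mode = mode, draws = draws),
            class = "cv_report")
}

#' Score every TF with the final cross-validated model
#'
#' One final stratified `n_folds` split is drawn; each fold-model scores
#' every TF in `G`. A labeled TF's margin D is the mean over the
#' `n_folds - 1` models that had it in training; an unlabeled TF averages
#' all fold-models. TFs are ranked by descending D (ties lexicographic)
#' and the rank is scaled to `score = 1 - (rank - 1) / (N - 1)`, a strictly
#' decreasing function of rank with maximum 1 and minimum 0.
#'
#' @inheritParams crossvalidate
#' @return A `score_table` data frame (tf_id, margin, rank, score) with the
#'   fold-models attached as attribute `models`.
#' @export
score_all <- function(G, labels, C = 1, n_folds = 5, seed = 1,
                      class_weights = NULL) {
  prep <- prep_training(G, labels)
  folds <- valid_folds(prep$y, n_folds, seed)
  models <- lapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    fit_linear_svm(prep$X[tr, , drop = FALSE], prep$y[tr], C,
                   resolve_weights(class_weights, prep$y[tr]))
  })
  D_all <- vapply(models, function(m) svm_decision(m, G), numeric(nrow(G)))
  if (nrow(G) == 1) D_all <- matrix(D_all, nrow = 1)
  use <- matrix(TRUE, nrow(G), n_folds,
                dimnames = list(rownames(G), NULL))
  heldout_fold <- stats::setNames(folds, prep$labels$tf_id)
  for (tf in names(heldout_fold)) use[tf, heldout_fold[[tf]]] <- FALSE
  D <- rowSums(D_all * use) / rowSums(use)
  ord <- order(-D, rownames(G))
  rank <- integer(nrow(G)); rank[ord] <- seq_len(nrow(G))
  score <- if (nrow(G) > 1) 1 - (rank - 1) / (nrow(G) - 1) else rep(1, 1)
  out <- data.frame(tf_id = rownames(G), margin = D, rank = rank,
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "models") <- models
  attr(out, "C") <- C
  class(out) <- c("score_table", "data.frame")
  out
}

#' Module feature importance of the final model
#'
#' The importance of a module is the absolute hyperplane coefficient of its
#' feature, averaged across the fold-models of [score_all()]; modules are
#' ranked by decreasing importance.
#'
#' @param scores A `score_table` from [score_all()].
#' @return Data frame (module_id, importance, rank).
#' @export
feature_importance <- function(scores) {
  models <- attr(scores, "models")
  if (is.null(models)) stop_located("scores must come from score_all()")
  W <- vapply(models, function(m) abs(m$w), numeric(length(models[[1]]$w)))
  if (length(models[[1]]$w) == 1) W <- matrix(W, nrow = 1)
  imp <- rowMeans(W)
  ord <- order(-imp, names(imp))
  data.frame(module_id = names(imp)[ord], importance = imp[ord],
             rank = seq_along(imp), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Top modules by feature importance
#' @param importance Data frame from [feature_importance()].
#' @param fraction Fraction of modules to keep (default 0.1).
#' @return Character vector of module ids.
#' @export
top_modules <- function(importance, fraction = 0.1) {
  n <- max(1L, ceiling(nrow(importance) * fraction))
  importance$module_id[seq_len(n)]
}

#' Per-bin sample-classification diagnostic
#'
#' TFs are sorted by decreasing score and split into `n_bins` equal-size
#' bins (any remainder spread over the leading bins). For each bin, the
#' expression of its TFs serves as the feature set of a linear classifier
#' of the binary sample condition, evaluated by stratified `n_folds`
#' cross-validation; the held-out decision values pooled over folds give
#' the bin's AUC-ROC. If the scoring is informative, leading bins (highest
#' scores) should classify samples far better than trailing bins.
#'
#' @param scores A `score_table`.
#' @param expr Expression matrix carrying a binary `condition` attribute.
#' @param n_bins Number of score bins (default 100).
#' @param n_folds Cross-validation folds per bin (default 3).
#' @param group_size Bins per reporting group (default 10).
#' @param C Cost of the per-bin linear SVM.
#' @param seed Integer seed.
#' @return Data frame (bin, group, n_tfs, auc_roc); bins with no scored TF
#'   present in `expr` carry `NA` AUC-ROC.
#' @export
decile_diagnostic <- function(scores, expr, n_bins = 100, n_folds = 3,
                              group_size = 10, C = 1, seed = 1) {
  validate_expression_matrix(expr)
  cond <- attr(expr, "condition")
  if (is.null(cond)) stop_located("expr must carry a condition attribute")
  lev <- sort(unique(cond))
  if (length(lev) != 2) stop_located("condition must be binary, got: ",
                                     paste(lev, collapse = ", "))
  y <- cond == lev[2]
  tfs <- scores$tf_id[order(scores$rank)]
  n <- length(tfs)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + (seq_len(n_bins) <= extra)
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1
  bin_seeds <- derive_seeds(seed, n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    if (sizes[b] == 0) {
      return(data.frame(bin = b, group = (b - 1) %/% group_size + 1,
                        n_tfs = 0L, auc_roc = NA_real_))
    }
    bin_tfs <- intersect(tfs[starts[b]:stops[b]], rownames(expr))
    if (length(bin_tfs) == 0) {
      return(data.frame(bin = b, group = (b - 1) %/% group_size + 1,
                        n_tfs = 0L, auc_roc = NA_real_))
    }
    X <- t(expr[bin_tfs, , drop = FALSE])
    folds <- valid_folds(y, n_folds, bin_seeds[b])
    dec <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      m <- fit_linear_svm(X[tr, , drop = FALSE], y[tr], C)
      dec[!tr] <- svm_decision(m, X[!tr, , drop = FALSE])
    }
    data.frame(bin = b, group = (b - 1) %/% group_size + 1,
               n_tfs = length(bin_tfs), auc_roc = auc_roc(dec, y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
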