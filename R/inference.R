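# Single-algorithm network inference engines and the top-K edge filter.
#
# Edge universe convention shared by all methods: candidate edges are the
# ordered TF -> gene pairs over all genes in the matrix (regulator != target).
# Symmetric methods (correlation, CLR, ARACNe) emit a TF-TF pair in both
# orientations with the same score, so directed and undirected methods rank
# over one common universe and the consensus can align them.

#' Discretize an expression profile into equal-width bins
#'
#' Bins span `[min(x), max(x)]`; intervals are right-closed (the first bin
#' includes its left edge), so the maximum falls in the last bin. A
#' constant profile maps entirely to bin 0.
#'
#' @param x Finite numeric vector.
#' @param n_bins Number of bins, at least 2.
#' @return Integer vector of 0-based bin indices.
#' @export
#' @examples
#' discretize(c(0, 0.5, 1), 2)  # 0 0 1
discretize <- function(x, n_bins) {
  if (n_bins < 2) stop_located("n_bins must be at least 2")
  if (!all(is.finite(x))) stop_located("profile contains non-finite values")
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(integer(length(x)))
  b <- ceiling((x - lo) / (hi - lo) * n_bins)
  b[b < 1L] <- 1L
  b[b > n_bins] <- n_bins
  as.integer(b - 1L)
}

#' Plug-in mutual information of two discretized profiles
#'
#' Maximum-likelihood (plug-in) estimate from the empirical joint
#' frequencies, in bits:
#' `MI = sum p(a,b) * log2( p(a,b) / (p(a) p(b)) )`.
#'
#' @param x,y Integer vectors of equal length (0-based bin indices).
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop_located("x and y must have equal length")
  if (length(x) < 2) stop_located("need at least 2 observations")
  nb <- max(x, y) + 1L
  joint <- tabulate(x * nb + y + 1L, nbins = nb * nb) / length(x)
  jm <- matrix(joint, nb, nb, byrow = TRUE)
  px <- rowSums(jm); py <- colSums(jm)
  pos <- jm > 0
  sum(jm[pos] * log2(jm[pos] / outer(px, py)[pos]))
}

#' Default bin count for MI estimation
#'
#' Ceiling of the square root of the sample count, the usual rule of thumb
#' for plug-in estimators.
#' @param n_samples Number of samples.
#' @return Integer bin count (at least 2).
#' @export
default_mi_bins <- function(n_samples) {
  max(2L, as.integer(ceiling(sqrt(n_samples))))
}

# MI values for all row pairs of a discretized matrix. `rows` restricts the
# first index (e.g. to TFs), giving a rectangular matrix rows x all-genes;
# when NULL the full symmetric gene x gene matrix is returned. Diagonal
# (self) entries are set to 0 by convention.
mi_matrix <- function(expr, n_bins, rows = NULL) {
  genes <- rownames(expr)
  disc <- t(apply(expr, 1, discretize, n_bins = n_bins))
  nb <- max(disc) + 1L
  if (is.null(rows)) rows <- genes
  M <- matrix(0, length(rows), length(genes), dimnames = list(rows, genes))
  # Entropy-free pairwise loop; tabulate() keeps this O(pairs * n).
  for (i in seq_along(rows)) {
    xi <- disc[rows[i], ]
    for (j in seq_along(genes)) {
      if (genes[j] == rows[i]) next
      if (!is.null(rownames(M)) && genes[j] %in% rows &&
          match(genes[j], rows) < i && rows[i] %in% genes) {
        # symmetric entry already computed
        M[i, j] <- M[genes[j], rows[i]]
        next
      }
      joint <- tabulate(xi * nb + disc[genes[j], ] + 1L, nbins = nb * nb) /
        ncol(expr)
      jm <- matrix(joint, nb, nb, byrow = TRUE)
      px <- rowSums(jm); py <- colSums(jm)
      pos <- jm > 0
      M[i, j] <- sum(jm[pos] * log2(jm[pos] / outer(px, py)[pos]))
    }
  }
  M[M < 0] <- 0  # guard against -0 style round-off
  M
}

# Assemble a ranked edge list from a TF x gene score matrix.
edges_from_scores <- function(S, tfs, top_k, method) {
  genes <- colnames(S)
  reg <- rep(rownames(S), times = ncol(S))
  tgt <- rep(genes, each = nrow(S))
  score <- as.vector(S)  # column-major, aligned with reg/tgt above
  keep <- reg != tgt
  top_k_filter(data.frame(regulator = reg[keep], target = tgt[keep],
                          score = score[keep], stringsAsFactors = FALSE),
               top_k, method = method)
}

#' Keep the top-K edges of a scored edge list
#'
#' Orders by descending score with deterministic tie-breaking
#' (regulator, then target, lexicographically), truncates to `K` edges and
#' assigns dense ranks 1..K. If fewer than `K` edges exist, all are kept.
#'
#' @param edges Data frame with columns regulator, target, score.
#' @param K Positive edge budget.
#' @param method Provenance tag for the result.
#' @return A ranked edge list.
#' @export
top_k_filter <- function(edges, K, method = attr(edges, "method") %||% "unknown") {
  if (K < 1) stop_located("K must be at least 1")
  ord <- order(-edges$score, edges$regulator, edges$target)
  keep <- ord[seq_len(min(K, length(ord)))]
  out <- data.frame(regulator = edges$regulator[keep],
                    target = edges$target[keep],
                    score = edges$score[keep],
                    rank = seq_along(keep),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

#' Correlation-based network inference (PCC / SCC)
#'
#' Scores each TF -> gene edge by the absolute Pearson or Spearman
#' correlation of the two profiles (Spearman is Pearson on average-tie
#' ranks). Zero-variance profiles yield a correlation of 0 and are logged.
#'
#' @param expr Expression matrix.
#' @param tfs Character vector of regulator identifiers (subset of genes).
#' @param flavor `"pearson"` or `"spearman"`.
#' @param top_k Edge budget (default 500000).
#' @param absolute Rank by absolute correlation (default). Set `FALSE` to
#'   rank by the signed value, discarding negative regulation.
#' @return A ranked edge list with method tag `pcc` or `scc`.
#' @export
infer_correlation <- function(expr, tfs, flavor = c("pearson", "spearman"),
                              top_k = 500000, absolute = TRUE) {
  flavor <- match.arg(flavor)
  validate_expression_matrix(expr)
  tfs <- validate_regulators(unique(tfs), expr)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    log_msg("zero-variance profile(s), correlations set to 0: ",
            paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  }
  C <- suppressWarnings(
    stats::cor(t(expr[tfs, , drop = FALSE]), t(expr), method = flavor))
  C[!is.finite(C)] <- 0
  S <- if (absolute) abs(C) else C
  edges_from_scores(S, tfs, top_k,
                    method = if (flavor == "pearson") "pcc" else "scc")
}

#' CLR network inference
#'
#' Context likelihood of relatedness: mutual information rescaled against
#' each gene's background MI distribution. For edge (i, j),
#' `z_i = max(0, (MI_ij - mean_i) / sd_i)` where mean/sd are taken over
#' gene i's MI values across the TF-gene MI matrix (a TF's background is
#' its row over all genes; a target's background is its column over all
#' TFs), and the edge score is `sqrt(z_i^2 + z_j^2)`. Genes with a
#' degenerate (zero-sd) background contribute z = 0 and are logged.
#'
#' @inheritParams infer_correlation
#' @param n_bins MI bin count; `NULL` uses [default_mi_bins()].
#' @return A ranked edge list with method tag `clr`.
#' @export
infer_clr <- function(expr, tfs, n_bins = NULL, top_k = 500000) {
  validate_expression_matrix(expr)
  tfs <- validate_regulators(unique(tfs), expr)
  if (is.null(n_bins)) n_bins <- default_mi_bins(ncol(expr))
  M <- mi_matrix(expr, n_bins, rows = tfs)
  genes <- colnames(M)
  # Background statistics: per TF over its row (excluding self); per gene
  # over its column (excluding the gene itself when it is a TF).
  self <- outer(rownames(M), genes, "==")
  row_n <- rowSums(!self)
  row_mean <- rowSums(M) / row_n
  row_sd <- sqrt(pmax(0, rowSums((M - row_mean)^2 * !self) / row_n))
  col_n <- colSums(!self)
  col_mean <- colSums(M) / col_n
  col_sd <- sqrt(pmax(0, colSums((M - matrix(col_mean, nrow(M), ncol(M),
                                             byrow = TRUE))^2 * !self) / col_n))
  if (any(row_sd == 0) || any(col_sd == 0)) {
    deg <- unique(c(rownames(M)[row_sd == 0], genes[col_sd == 0]))
    log_msg("degenerate MI background, z set to 0 for: ",
            paste(utils::head(deg, 5), collapse = ", "))
  }
  zi <- (M - row_mean) / ifelse(row_sd == 0, Inf, row_sd)
  zj <- sweep(sweep(M, 2, col_mean), 2, ifelse(col_sd == 0, Inf, col_sd), "/")
  zi[zi < 0] <- 0; zj[zj < 0] <- 0
  S <- sqrt(zi^2 + zj^2)
  edges_from_scores(S, tfs, top_k, method = "clr")
}

#' ARACNe network inference
#'
#' Mutual information network pruned by the data processing inequality:
#' in every connected triplet (all three pairwise MI values positive), the
#' edge with the minimum MI is removed when
#' `MI_min < min(other two) * (1 - dpi_tolerance)`, being interpreted as an
#' indirect interaction. Triplets range over all genes (including
#' target-target pairs), so a TF -> gene edge can be explained away by an
#' intermediate of either kind. Surviving TF -> gene edges are scored by
#' their MI.
#'
#' @inheritParams infer_clr
#' @param dpi_tolerance DPI tolerance `>= 0`; 0 is the strict inequality.
#' @return A ranked edge list with method tag `aracne`.
#' @export
infer_aracne <- function(expr, tfs, n_bins = NULL, dpi_tolerance = 0,
                         top_k = 500000) {
  validate_expression_matrix(expr)
  tfs <- validate_regulators(unique(tfs), expr)
  if (dpi_tolerance < 0) stop_located("dpi_tolerance must be >= 0")
  if (is.null(n_bins)) n_bins <- default_mi_bins(ncol(expr))
  M <- mi_matrix(expr, n_bins)        # full symmetric gene x gene
  keep <- dpi_prune(M, dpi_tolerance) # logical matrix of surviving edges
  S <- M * keep
  S <- S[tfs, , drop = FALSE]
  edges_from_scores(S, tfs, top_k, method = "aracne")
}

# Data processing inequality on a symmetric MI matrix. Returns a logical
# matrix marking surviving entries. Vectorized over the intermediate node.
dpi_prune <- function(M, eps) {
  n <- nrow(M)
  removed <- matrix(FALSE, n, n)
  scale <- 1 - eps
  for (k in seq_len(n)) {
    mik <- M[, k]
    # threshold for edge (i,j) via intermediate k: min(M[i,k], M[j,k]) * (1-eps)
    thr <- outer(mik, mik, pmin) * scale
    removed <- removed | (M < thr & M > 0 & outer(mik > 0, mik > 0, "&"))
  }
  diag(removed) <- TRUE
  !removed & M > 0
}

#' GENIE3-style tree-ensemble network inference
#'
#' For every gene in turn as the target, a random forest of regression
#' trees predicts the (unit-variance standardized) target profile from the
#' candidate TF profiles; the importance of TF t for target g is the total
#' impurity (variance) reduction attributed to t across the ensemble.
#' Directed edges (t, g) are ranked globally by importance. Zero-variance
#' targets are skipped with a log entry. Trees are grown to purity with a
#' candidate-feature subset of size `ceiling(sqrt(#TFs))` per split.
#'
#' @inheritParams infer_correlation
#' @param n_trees Trees per target ensemble (default 1000).
#' @param seed Integer seed controlling all tree randomness.
#' @return A ranked edge list with method tag `genie3`.
#' @export
infer_genie3 <- function(expr, tfs, n_trees = 1000, seed = 1, top_k = 500000) {
  validate_expression_matrix(expr)
  tfs <- validate_regulators(unique(tfs), expr)
  if (n_trees < 1) stop_located("n_trees must be at least 1")
  genes <- rownames(expr)
  tf_expr <- t(expr[tfs, , drop = FALSE])
  target_seeds <- derive_seeds(seed, length(genes))
  S <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  skipped <- character(0)
  for (g in seq_along(genes)) {
    target <- genes[g]
    y <- expr[target, ]
    s <- stats::sd(y)
    if (s == 0) { skipped <- c(skipped, target); next }
    preds <- setdiff(tfs, target)
    if (length(preds) == 0) next
    x <- tf_expr[, preds, drop = FALSE]
    fit <- ranger::ranger(x = x, y = (y - mean(y)) / s,
                          num.trees = n_trees,
                          mtry = min(length(preds), ceiling(sqrt(length(preds)))),
                          min.node.size = 1,
                          importance = "impurity",
                          num.threads = 1,
                          seed = target_seeds[g])
    imp <- fit$variable.importance
    S[names(imp), target] <- pmax(0, imp)
  }
  if (length(skipped)) {
    log_msg("zero-variance target(s) skipped by genie3: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  edges_from_scores(S, tfs, top_k, method = "genie3")
}

#' Run one inference method by name
#'
#' Thin dispatcher used by the pipeline and the command line.
#'
#' @param expr Expression matrix.
#' @param tfs Regulator identifiers.
#' @param method One of `pcc`, `scc`, `clr`, `aracne`, `genie3`.
#' @param top_k Edge budget.
#' @param n_bins MI bins (`NULL` = automatic).
#' @param dpi_tolerance ARACNe tolerance.
#' @param n_trees GENIE3 ensemble size.
#' @param seed Seed for stochastic methods.
#' @return A ranked edge list.
#' @export
infer_network <- function(expr, tfs,
                          method = c("pcc", "scc", "clr", "aracne", "genie3"),
                          top_k = 500000, n_bins = NULL, dpi_tolerance = 0,
                          n_trees = 1000, seed = 1) {
  method <- match.arg(method)
  switch(method,
         pcc = infer_correlation(expr, tfs, "pearson", top_k),
         scc = infer_correlation(expr, tfs, "spearman", top_k),
         clr = infer_clr(expr, tfs, n_bins, top_k),
         aracne = infer_aracne(expr, tfs, n_bins, dpi_tolerance, top_k),
         genie3 = infer_genie3(expr, tfs, n_trees, seed, top_k))
}
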