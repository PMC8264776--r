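# Reference-network builders and network-quality metrics.

as_edge_keys <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("regulator", "target"), names(x))
    if (length(cols) == 2) return(unique(edge_key(x$regulator, x$target)))
    stop_located("edge set data frame needs columns regulator, target")
  }
  unique(as.character(x))
}

#' Precision, recall and F1 of a predicted edge set
#'
#' Precision is the fraction of predicted edges present in the reference
#' (0 when nothing is predicted); recall is the fraction of reference
#' edges predicted; F1 is their harmonic mean (0 when both are 0).
#'
#' @param predicted,reference Edge sets: data frames with
#'   regulator/target columns, or vectors of edge keys.
#' @return Data frame (precision, recall, f1, n_true_positive,
#'   n_predicted, n_reference).
#' @export
edge_metrics <- function(predicted, reference) {
  ref <- as_edge_keys(reference)
  if (length(ref) == 0) stop_located("reference edge set must be nonempty")
  pred <- as_edge_keys(predicted)
  tp <- length(intersect(pred, ref))
  precision <- if (length(pred)) tp / length(pred) else 0
  recall <- tp / length(ref)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  data.frame(precision = precision, recall = recall, f1 = f1,
             n_true_positive = tp, n_predicted = length(pred),
             n_reference = length(ref))
}

#' Per-TF benchmark against known (e.g. ChIP) target sets
#'
#' For every benchmark TF, the predicted target set in the network is
#' compared with its known target set; a TF is "recovered" when at least
#' one known target is predicted. TFs absent from the network get
#' precision 0 and are flagged.
#'
#' @param network Ranked edge list.
#' @param benchmark Named list mapping TF id -> character vector of known
#'   targets.
#' @return Data frame (tf_id, precision, recall, f1, n_true_positive,
#'   n_predicted, n_reference, recovered, in_network).
#' @export
per_tf_benchmark <- function(network, benchmark) {
  pred_targets <- split(network$target, network$regulator)
  rows <- lapply(names(benchmark), function(tf) {
    known <- unique(benchmark[[tf]])
    if (length(known) == 0) stop_located("benchmark TF ", tf, " has no targets")
    pred <- unique(pred_targets[[tf]] %||% character(0))
    tp <- length(intersect(pred, known))
    precision <- if (length(pred)) tp / length(pred) else 0
    recall <- tp / length(known)
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(tf_id = tf, precision = precision, recall = recall, f1 = f1,
               n_true_positive = tp, n_predicted = length(pred),
               n_reference = length(known), recovered = tp >= 1,
               in_network = length(pred) > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Co-annotation reference network from a gene-set collection
#'
#' Annotation sets with `max_set_size` or more genes are dropped (large,
#' unspecific categories would link minimally related genes); each
#' surviving set contributes a (TF, gene) pair for every TF / non-TF pair
#' co-annotated in it. Pairs are deduplicated.
#'
#' @param collection Gene-set collection.
#' @param tfs Character vector of regulator identifiers.
#' @param max_set_size Exclusive upper size bound (default 200: only sets
#'   with fewer than 200 genes are used).
#' @return Data frame (regulator, target) with attribute `source =
#'   "coannotation"`.
#' @export
build_coannotation_reference <- function(collection, tfs, max_set_size = 200) {
  if (length(collection) == 0) stop_located("collection must be nonempty")
  rows <- list()
  for (s in names(collection)) {
    genes <- unique(collection[[s]])
    if (length(genes) >= max_set_size) next
    set_tfs <- intersect(genes, tfs)
    others <- setdiff(genes, tfs)
    if (length(set_tfs) == 0 || length(others) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      regulator = rep(set_tfs, each = length(others)),
      target = rep(others, times = length(set_tfs)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(regulator = character(), target = character())
  rownames(out) <- NULL
  attr(out, "source") <- "coannotation"
  out
}

#' Motif-hit reference network
#'
#' TF motifs occurring in more than `constitutive_fraction` of all genes
#' are treated as constitutive elements and removed entirely; the
#' remaining hits are kept only at `p_value < p_max` (strict). Surviving
#' (TF, gene) pairs are deduplicated.
#'
#' @param hits Data frame with columns `tf`, `gene`, `p_value`.
#' @param n_genes_total Total number of genes scanned; must be at least the
#'   number of distinct genes in `hits`.
#' @param constitutive_fraction Occurrence fraction above which a motif is
#'   constitutive (default 0.5).
#' @param p_max Strict p-value cutoff (default 1e-10).
#' @return Data frame (regulator, target) with attribute `source = "motif"`.
#' @export
build_motif_reference <- function(hits, n_genes_total,
                                  constitutive_fraction = 0.5,
                                  p_max = 1e-10) {
  need <- c("tf", "gene", "p_value")
  if (!all(need %in% names(hits))) {
    stop_located("hits must have columns ", paste(need, collapse = ", "))
  }
  n_distinct <- length(unique(hits$gene))
  if (n_genes_total < n_distinct) {
    stop_located("n_genes_total (", n_genes_total, ") below the ",
                 n_distinct, " distinct genes in hits")
  }
  per_tf <- tapply(hits$gene, hits$tf, function(g) length(unique(g)))
  constitutive <- names(per_tf)[per_tf / n_genes_total > constitutive_fraction]
  keep <- !(hits$tf %in% constitutive) & hits$p_value < p_max
  out <- unique(data.frame(regulator = hits$tf[keep], target = hits$gene[keep],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "source") <- "motif"
  out
}

#' Exact-subset edge overlap counts across methods
#'
#' For every nonempty subset S of the input methods, counts the edges
#' present in exactly the methods of S (the numbers behind an UpSet plot).
#' Counts sum to the size of the union.
#'
#' @param lists Named list (or list with method attributes) of at least two
#'   ranked edge lists.
#' @return Data frame (methods, n_methods, count) with `methods` a
#'   comma-joined method subset.
#' @export
edge_overlap_counts <- function(lists) {
  if (length(lists) < 2) stop_located("need at least 2 edge lists")
  tags <- names(lists)
  if (is.null(tags)) {
    tags <- vapply(lists, function(x) attr(x, "method") %||% "unknown",
                   character(1))
  }
  tags <- make.unique(tags, sep = "_")
  keys <- lapply(lists, function(x) unique(edge_key(x$regulator, x$target)))
  universe <- unique(unlist(keys, use.names = FALSE))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(m) paste(tags[m], collapse = ","))
  tab <- table(pattern)
  out <- data.frame(methods = names(tab),
                    n_methods = lengths(strsplit(names(tab), ",", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$n_methods, out$methods), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' AUPR of a ranked edge list against a true edge set
#'
#' Precision-recall area over the ranking, with the recall denominator set
#' to the full number of true edges (so edges truncated out of the list
#' count as missed).
#'
#' @param edges Ranked edge list.
#' @param truth Edge set (data frame or key vector) of true edges.
#' @return AUPR in `[0, 1]`.
#' @export
edge_aupr <- function(edges, truth) {
  truth_keys <- as_edge_keys(truth)
  if (length(truth_keys) == 0) stop_located("truth edge set must be nonempty")
  keys <- edge_key(edges$regulator, edges$target)
  auc_pr(edges$score, keys %in% truth_keys, n_positives = length(truth_keys))
}
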