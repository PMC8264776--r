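# Domain types and their invariant checks.
#
# The package keeps its containers deliberately plain:
#   - an expression matrix is a numeric genes x samples matrix with unique
#     dimnames and an optional per-sample `condition` attribute;
#   - a ranked edge list is a data.frame (regulator, target, score, rank)
#     with a `method` attribute;
#   - a label set is a data.frame (tf_id, label, family);
#   - a gene-set collection is a named list of character vectors with a
#     `descriptions` attribute.
# Validators are exported so that any object entering the pipeline can be
# checked against the same invariants the readers enforce.

#' Construct and validate an expression matrix
#'
#' An expression matrix holds normalized expression values (any log-like
#' scale) for genes in rows and samples in columns. Gene and sample
#' identifiers must be unique, all values finite, and at least two genes
#' and four samples must be present: smaller designs carry too little
#' information for network inference and are rejected up front.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param condition Optional character vector of per-sample condition
#'   labels (e.g. `"control"`/`"stress"`), recycled checks apply: must have
#'   one label per sample.
#' @return The validated matrix, with `condition` stored as an attribute.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' em <- expression_matrix(m)
expression_matrix <- function(values, condition = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_located("expression matrix must be a numeric matrix")
  }
  if (!is.null(condition)) {
    if (length(condition) != ncol(values)) {
      stop_located("condition labels must match the number of samples (",
                   length(condition), " labels for ", ncol(values), " samples)")
    }
    attr(values, "condition") <- as.character(condition)
  }
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' @param x Numeric matrix as produced by [expression_matrix()].
#' @return Invisibly, `x`; errors describe the violated invariant.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_located("expression matrix must be a numeric matrix")
  }
  gid <- rownames(x)
  sid <- colnames(x)
  if (is.null(gid) || is.null(sid)) {
    stop_located("expression matrix must carry gene rownames and sample colnames")
  }
  dup_g <- gid[duplicated(gid)]
  if (length(dup_g)) {
    stop_located("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  }
  dup_s <- sid[duplicated(sid)]
  if (length(dup_s)) {
    stop_located("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop_located("non-finite expression value at gene '", gid[bad[1]],
                 "', sample '", sid[bad[2]], "'")
  }
  if (nrow(x) < 2) stop_located("expression matrix needs at least 2 genes")
  if (ncol(x) < 4) {
    stop_located("expression matrix needs at least 4 samples (got ", ncol(x), ")")
  }
  cond <- attr(x, "condition")
  if (!is.null(cond) && length(cond) != ncol(x)) {
    stop_located("condition attribute length does not match sample count")
  }
  invisible(x)
}

#' Construct and validate a ranked edge list
#'
#' Directed regulator -> target edges with a confidence score and a dense
#' rank. Ranks must be the permutation 1..n consistent with non-increasing
#' score order (ties broken by regulator then target, lexicographically),
#' and self-edges are forbidden.
#'
#' @param regulator,target Character vectors of gene identifiers.
#' @param score Numeric confidence, larger = more confident.
#' @param rank Integer ranks 1..n; if `NULL`, computed from the scores.
#' @param method Provenance tag, one of `pcc`, `scc`, `clr`, `aracne`,
#'   `genie3`, `consensus` (free-form tags are accepted for user edge lists).
#' @return A `data.frame` with columns regulator, target, score, rank and a
#'   `method` attribute.
#' @export
ranked_edge_list <- function(regulator, target, score, rank = NULL,
                             method = "unknown") {
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (is.null(rank)) {
    ord <- order(-df$score, df$regulator, df$target)
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
  } else {
    df$rank <- as.integer(rank)
    df <- df[order(df$rank), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "method") <- method
  validate_edge_list(df)
  df
}

#' Validate a ranked edge list
#'
#' @param x Data frame with columns regulator, target, score, rank.
#' @param regulators Optional character vector; when given, every edge's
#'   regulator must belong to it.
#' @return Invisibly, `x`.
#' @export
validate_edge_list <- function(x, regulators = NULL) {
  need <- c("regulator", "target", "score", "rank")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop_located("edge list must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  self <- x$regulator == x$target
  if (any(self)) {
    stop_located("self-edge not allowed: ", x$regulator[which(self)[1]])
  }
  key <- edge_key(x$regulator, x$target)
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE][1, ]
    stop_located("duplicate edge: (", d$regulator, ", ", d$target, ")")
  }
  r <- sort(x$rank)
  if (!identical(as.integer(r), seq_len(nrow(x)))) {
    stop_located("ranks must be a permutation of 1..", nrow(x))
  }
  ord <- order(x$rank)
  s <- x$score[ord]
  if (any(diff(s) > 1e-12)) {
    stop_located("rank order must follow non-increasing score order")
  }
  if (!is.null(regulators)) {
    bad <- setdiff(unique(x$regulator), regulators)
    if (length(bad)) {
      stop_located("edge regulator(s) outside the regulator set: ",
                   paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  invisible(x)
}

#' Construct and validate a TF label set
#'
#' Positive and negative marker labels for regulators, with an optional
#' family tag per TF (used by the family-matched baseline). The two classes
#' must be disjoint; both must be nonempty for the set to be usable as
#' training data.
#'
#' @param tf_id Character TF identifiers.
#' @param label `"positive"` or `"negative"` per TF.
#' @param family Optional family tag per TF (`NA` allowed).
#' @param require_both_classes If `TRUE` (default), error when either class
#'   is empty.
#' @return A `data.frame` with columns tf_id, label, family.
#' @export
label_set <- function(tf_id, label, family = NA_character_,
                      require_both_classes = TRUE) {
  df <- data.frame(tf_id = as.character(tf_id),
                   label = as.character(label),
                   family = rep_len(as.character(family), length(tf_id)),
                   stringsAsFactors = FALSE)
  validate_label_set(df, require_both_classes = require_both_classes)
  df
}

#' Validate a TF label set
#' @param x Data frame with columns tf_id, label and optionally family.
#' @param require_both_classes Require at least one positive and one
#'   negative label.
#' @return Invisibly, `x`.
#' @export
validate_label_set <- function(x, require_both_classes = TRUE) {
  if (!is.data.frame(x) || !all(c("tf_id", "label") %in% names(x))) {
    stop_located("label set must have columns tf_id, label")
  }
  if (anyDuplicated(x$tf_id)) {
    stop_located("duplicate tf_id in label set: ",
                 x$tf_id[duplicated(x$tf_id)][1])
  }
  bad <- setdiff(unique(x$label), c("positive", "negative"))
  if (length(bad)) {
    stop_located("labels must be 'positive' or 'negative', got: ",
                 paste(bad, collapse = ", "))
  }
  if (require_both_classes) {
    if (!any(x$label == "positive") || !any(x$label == "negative")) {
      stop_located("label set must contain both a positive and a negative class")
    }
  }
  invisible(x)
}

#' Construct and validate a gene-set collection
#'
#' @param sets Named list of character vectors (set id -> gene ids).
#' @param descriptions Optional character vector of descriptions, one per
#'   set (defaults to empty strings).
#' @return The named list with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop_located("gene-set collection must be a named list")
  }
  if (anyDuplicated(names(sets))) {
    stop_located("duplicate set id: ", names(sets)[duplicated(names(sets))][1])
  }
  if (any(lengths(sets) == 0)) {
    stop_located("empty gene set: ", names(sets)[lengths(sets) == 0][1])
  }
  sets <- lapply(sets, as.character)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets)) {
    stop_located("need one description per set")
  }
  attr(sets, "descriptions") <- stats::setNames(as.character(descriptions),
                                                names(sets))
  sets
}

#' Validate a regulator set against an expression matrix
#'
#' @param tfs Character vector of TF identifiers.
#' @param expr Optional expression matrix; when given, every TF must be one
#'   of its genes.
#' @return Invisibly, the unique TF ids.
#' @export
validate_regulators <- function(tfs, expr = NULL) {
  tfs <- as.character(tfs)
  if (length(tfs) == 0) stop_located("regulator set must be nonempty")
  if (anyDuplicated(tfs)) tfs <- unique(tfs)
  if (!is.null(expr)) {
    missing <- setdiff(tfs, rownames(expr))
    if (length(missing)) {
      stop_located("TF(s) absent from the expression matrix: ",
                   paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  invisible(tfs)
}
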