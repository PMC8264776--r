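# Average-rank aggregation of per-algorithm edge lists into a consensus.

#' Build the edge-rank matrix across methods
#'
#' Rows are the union of edges across the input lists (in lexicographic
#' regulator/target order), columns are the method tags. The entry for an
#' edge present in method m is that method's rank; an edge absent from m is
#' assigned m's worst (numerically largest) rank plus one, so absence is
#' penalized rather than rewarded.
#'
#' @param lists List of at least two ranked edge lists.
#' @return Integer matrix with `regulator`/`target` data-frame attribute
#'   `edges` describing the rows.
#' @export
build_rank_matrix <- function(lists) {
  if (length(lists) < 2) stop_located("need at least 2 edge lists to aggregate")
  for (x in lists) validate_edge_list(x)
  tags <- vapply(lists, function(x) attr(x, "method") %||% "unknown",
                 character(1))
  tags <- make.unique(tags, sep = "_")
  keys <- lapply(lists, function(x) edge_key(x$regulator, x$target))
  all_edges <- unique(do.call(rbind, lapply(lists, function(x) {
    x[, c("regulator", "target")]
  })))
  ord <- order(all_edges$regulator, all_edges$target)
  all_edges <- all_edges[ord, , drop = FALSE]
  rownames(all_edges) <- NULL
  universe <- edge_key(all_edges$regulator, all_edges$target)
  E <- matrix(NA_integer_, length(universe), length(lists),
              dimnames = list(NULL, tags))
  for (m in seq_along(lists)) {
    idx <- match(keys[[m]], universe)
    worst <- if (nrow(lists[[m]])) max(lists[[m]]$rank) else 0L
    E[, m] <- worst + 1L
    E[idx, m] <- lists[[m]]$rank
  }
  attr(E, "edges") <- all_edges
  E
}

#' Aggregate an edge-rank matrix into the consensus network
#'
#' Computes each edge's mean rank across methods, re-ranks edges ascending
#' by that mean (smaller mean = more confident), and keeps the first
#' `min(K, n)` edges. The consensus score is the negated mean rank so that
#' "larger score = better" holds like in every other edge list. Ties in
#' mean rank are broken lexicographically by (regulator, target).
#'
#' @param E Edge-rank matrix from [build_rank_matrix()].
#' @param K Edge budget (default 500000).
#' @return A ranked edge list with method tag `consensus`.
#' @export
aggregate_ranks <- function(E, K = 500000) {
  if (K < 1) stop_located("K must be at least 1")
  edges <- attr(E, "edges")
  if (is.null(edges)) stop_located("E must come from build_rank_matrix()")
  mean_rank <- rowMeans(E)
  ord <- order(mean_rank, edges$regulator, edges$target)
  keep <- ord[seq_len(min(K, length(ord)))]
  out <- data.frame(regulator = edges$regulator[keep],
                    target = edges$target[keep],
                    score = -mean_rank[keep],
                    rank = seq_along(keep),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "consensus"
  out
}

#' Consensus network straight from per-method edge lists
#'
#' Convenience wrapper: [build_rank_matrix()] followed by
#' [aggregate_ranks()], with optional method exclusion (e.g. dropping the
#' two correlation-based methods).
#'
#' @param lists List of ranked edge lists.
#' @param K Edge budget.
#' @param exclude Character vector of method tags to leave out.
#' @return A ranked edge list with method tag `consensus`.
#' @export
consensus_network <- function(lists, K = 500000, exclude = character()) {
  if (length(exclude)) {
    tags <- vapply(lists, function(x) attr(x, "method") %||% "unknown",
                   character(1))
    lists <- lists[!tags %in% exclude]
  }
  aggregate_ranks(build_rank_matrix(lists), K)
}
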