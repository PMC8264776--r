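# Module detection: Jaccard projection of the consensus network onto a
# co-regulation graph, Markov clustering, the TF x module feature matrix,
# and hypergeometric module annotation.

#' Predicted regulator sets per target gene
#'
#' @param consensus Ranked edge list (typically the consensus network).
#' @return Named list mapping each target gene to the character vector of
#'   its predicted regulators.
#' @export
regulator_sets <- function(consensus) {
  if (nrow(consensus) == 0) stop_located("consensus network is empty")
  lapply(split(consensus$regulator, consensus$target), unique)
}

#' Jaccard index of two identifier sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param a,b Character vectors (duplicates ignored).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Build the co-regulation graph from regulator sets
#'
#' Links pairs of target genes whose predicted regulator sets overlap
#' strongly: all pairwise Jaccard indices are computed and pairs at or
#' above the `q`-quantile of the nonzero values are kept as weighted,
#' undirected edges. Genes left without a surviving edge are reported as
#' unassigned.
#'
#' @param reg_sets Named list from [regulator_sets()].
#' @param q Quantile in (0, 1) defining "high overlap" (default 0.95).
#' @return A `coreg_graph` list: `nodes`, `edges` (data.frame gene1, gene2,
#'   weight), `unassigned`, `threshold`.
#' @export
coregulation_graph <- function(reg_sets, q = 0.95) {
  if (q <= 0 || q >= 1) stop_located("q must lie strictly between 0 and 1")
  genes <- names(reg_sets)
  genes <- genes[lengths(reg_sets) > 0]
  tf_universe <- unique(unlist(reg_sets[genes], use.names = FALSE))
  # 0/1 incidence genes x TFs; intersections via crossprod.
  B <- matrix(0L, length(genes), length(tf_universe),
              dimnames = list(genes, tf_universe))
  for (g in genes) B[g, reg_sets[[g]]] <- 1L
  inter <- tcrossprod(B)
  sizes <- rowSums(B)
  uni <- outer(sizes, sizes, "+") - inter
  J <- inter / uni
  J[upper.tri(J, diag = TRUE)] <- 0
  nz <- J[J > 0]
  if (length(nz) == 0) {
    stop_located("degenerate consensus: no pair of genes shares a regulator")
  }
  thr <- stats::quantile(nz, q, names = FALSE, type = 7)
  idx <- which(J >= thr & J > 0, arr.ind = TRUE)
  edges <- data.frame(gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
                      weight = J[idx], stringsAsFactors = FALSE)
  swap <- edges$gene1 > edges$gene2
  tmp <- edges$gene1[swap]; edges$gene1[swap] <- edges$gene2[swap]
  edges$gene2[swap] <- tmp
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  connected <- union(edges$gene1, edges$gene2)
  structure(list(nodes = genes, edges = edges,
                 unassigned = setdiff(genes, connected), threshold = thr),
            class = "coreg_graph")
}

#' Markov clustering of a weighted, undirected graph
#'
#' A full in-repo Markov-clustering iteration: self-loops with the node's
#' maximum incident edge weight are added, the adjacency matrix is column
#' normalized to a stochastic matrix, and expansion (matrix squaring)
#' alternates with inflation (entrywise power `inflation`, renormalize)
#' plus pruning of entries below `prune` until the largest entry change
#' falls below `tol` or `max_iter` iterations pass. Clusters are read from
#' the attractor rows of the limit matrix; a gene claimed by several
#' clusters goes to the one holding more of its attractor mass (ties
#' lexicographic). Modules are labeled M0001, M0002, ... in order of
#' decreasing size; singletons are reported as unassigned.
#'
#' @param graph A `coreg_graph` from [coregulation_graph()], or any list
#'   with `nodes` and `edges` of the same shape.
#' @param inflation Inflation exponent, must exceed 1 (default 2).
#' @param prune Entries below this value are dropped each iteration.
#' @param tol Convergence tolerance on the max entry change.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   last residual.
#' @param min_module_size Modules smaller than this are folded into the
#'   unassigned list (default 2, i.e. singletons are unassigned).
#' @return A `module_partition` list: `modules` (named list of gene sets)
#'   and `unassigned` (character vector).
#' @export
mcl_cluster <- function(graph, inflation = 2, prune = 1e-5, tol = 1e-8,
                        max_iter = 200, min_module_size = 2) {
  if (inflation <= 1) stop_located("inflation must exceed 1")
  nodes <- sort(setdiff(graph$nodes, graph$unassigned))
  if (length(nodes) == 0) stop_located("graph has no connected nodes")
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  A[cbind(match(e$gene1, nodes), match(e$gene2, nodes))] <- e$weight
  A[cbind(match(e$gene2, nodes), match(e$gene1, nodes))] <- e$weight
  diag(A) <- apply(A, 1, max)  # self-loop = max incident weight
  M <- sweep(A, 2, colSums(A), "/")
  residual <- Inf
  for (it in seq_len(max_iter)) {
    M_prev <- M
    M <- M %*% M                       # expansion
    M <- M^inflation                   # inflation
    M[M < prune] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    residual <- max(abs(M - M_prev))
    if (residual < tol) break
    if (it == max_iter) {
      stop_located("Markov clustering did not converge in ", max_iter,
                   " iterations (last residual ", signif(residual, 3), ")")
    }
  }
  # Attractors: nodes with positive diagonal mass in the limit matrix.
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # Merge attractor rows with identical support into one cluster each.
  support <- lapply(attractors, function(i) which(M[i, ] > 0))
  sig <- vapply(support, paste, character(1), collapse = ",")
  groups <- split(attractors, sig)
  raw <- lapply(groups, function(rows) {
    mass <- colSums(M[rows, , drop = FALSE])
    list(rows = rows, members = which(mass > 0), mass = mass)
  })
  # Resolve overlaps: a node goes to the cluster with the larger mass.
  assign <- rep(NA_integer_, n)
  best <- rep(-Inf, n)
  cluster_names <- names(raw)
  for (ci in order(cluster_names)) {  # lexicographic tie-break: first wins
    cl <- raw[[ci]]
    take <- cl$members[cl$mass[cl$members] > best[cl$members]]
    assign[take] <- ci
    best[take] <- cl$mass[take]
  }
  orphan <- which(is.na(assign))
  clusters <- split(nodes[!is.na(assign)], assign[!is.na(assign)])
  small <- lengths(clusters) < min_module_size
  unassigned <- c(graph$unassigned, nodes[orphan],
                  unlist(clusters[small], use.names = FALSE))
  clusters <- clusters[!small]
  # Stable module ids: decreasing size, ties by smallest member id.
  first <- vapply(clusters, function(g) sort(g)[1], character(1))
  ord <- order(-lengths(clusters), first)
  clusters <- lapply(clusters[ord], sort)
  names(clusters) <- sprintf("M%04d", seq_along(clusters))
  structure(list(modules = clusters, unassigned = sort(unique(unassigned))),
            class = "module_partition")
}

#' TF-by-module connectivity feature matrix
#'
#' Entry (t, m) is the Jaccard index between TF t's predicted target set in
#' the consensus network and module m's gene set. Rows exist for every TF
#' with at least one consensus target; TFs without targets are dropped with
#' a log entry.
#'
#' @param consensus Ranked edge list.
#' @param partition Module partition from [mcl_cluster()].
#' @return Numeric matrix in `[0, 1]`, TFs in rows, module ids in columns.
#' @export
tf_module_matrix <- function(consensus, partition) {
  tf_targets <- lapply(split(consensus$target, consensus$regulator), unique)
  tf_targets <- tf_targets[lengths(tf_targets) > 0]
  mods <- partition$modules
  G <- matrix(0, length(tf_targets), length(mods),
              dimnames = list(names(tf_targets), names(mods)))
  for (t in names(tf_targets)) {
    tg <- tf_targets[[t]]
    for (m in names(mods)) {
      G[t, m] <- jaccard(tg, mods[[m]])
    }
  }
  G
}

#' Hypergeometric enrichment of modules in annotation sets
#'
#' Tests every (module, annotation set) pair for over-representation with
#' the hypergeometric upper tail `P(X >= overlap)`, after dropping sets
#' whose size within the universe lies outside `[min_size, max_size]`.
#' p-values are Benjamini-Hochberg corrected across all performed tests
#' jointly, and significance is declared at `q < q_threshold`.
#'
#' @param partition Module partition.
#' @param collection Gene-set collection of annotation terms.
#' @param universe Character vector of all genes under consideration; must
#'   contain every module gene.
#' @param min_size,max_size Inclusive size bounds for tested sets
#'   (defaults 3 and 500).
#' @param q_threshold Significance threshold on the BH-adjusted p-value.
#' @return Data frame (module_id, set_id, overlap, module_size, set_size,
#'   universe_size, p_value, q_value, significant).
#' @export
enrich_modules <- function(partition, collection, universe,
                           min_size = 3, max_size = 500, q_threshold = 0.05) {
  universe <- unique(as.character(universe))
  mod_genes <- unlist(partition$modules, use.names = FALSE)
  outside <- setdiff(mod_genes, universe)
  if (length(outside)) {
    stop_located("module gene(s) outside the universe: ",
                 paste(utils::head(outside, 5), collapse = ", "))
  }
  sets <- lapply(collection, function(g) intersect(unique(g), universe))
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets <- sets[keep]
  N <- length(universe)
  rows <- list()
  for (m in names(partition$modules)) {
    mg <- intersect(partition$modules[[m]], universe)
    for (s in names(sets)) {
      ov <- length(intersect(mg, sets[[s]]))
      p <- stats::phyper(ov - 1, length(sets[[s]]), N - length(sets[[s]]),
                         length(mg), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = m, set_id = s, overlap = ov,
        module_size = length(mg), set_size = length(sets[[s]]),
        universe_size = N, p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(module_id = character(), set_id = character(),
                      overlap = integer(), module_size = integer(),
                      set_size = integer(), universe_size = integer(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < q_threshold
  out[order(out$q_value, out$p_value, out$module_id, out$set_id), ]
}

#' Propagate annotations up an ontology (true-path rule)
#'
#' Each term's gene set becomes the union of its own genes and those of all
#' its descendants: a gene annotated to a child term is implicitly
#' annotated to every ancestor. The edge set must be acyclic.
#'
#' @param collection Gene-set collection (terms may be missing: terms that
#'   appear only in `ontology_edges` start with an empty gene set).
#' @param ontology_edges Data frame with columns `child`, `parent`.
#' @return A gene-set collection covering every term seen in the collection
#'   or the ontology; terms left empty after propagation are dropped.
#' @export
propagate_annotations <- function(collection, ontology_edges) {
  if (!all(c("child", "parent") %in% names(ontology_edges))) {
    stop_located("ontology_edges must have columns child, parent")
  }
  terms <- union(names(collection),
                 union(ontology_edges$child, ontology_edges$parent))
  genes <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) genes[[t]] <- unique(collection[[t]] %||% character(0))
  children_of <- split(ontology_edges$child, ontology_edges$parent)
  # Kahn topological order on child -> parent edges; parents come after
  # their children, so one pass suffices.
  n_unresolved <- stats::setNames(integer(length(terms)), terms)
  for (p in names(children_of)) {
    n_unresolved[p] <- length(unique(children_of[[p]]))
  }
  queue <- terms[n_unresolved == 0]
  done <- character(0)
  parent_of <- split(ontology_edges$parent, ontology_edges$child)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    done <- c(done, t)
    for (p in unique(parent_of[[t]] %||% character(0))) {
      genes[[p]] <- union(genes[[p]], genes[[t]])
      n_unresolved[p] <- n_unresolved[p] - 1L
      if (n_unresolved[p] == 0) queue <- c(queue, p)
    }
  }
  if (length(done) < length(terms)) {
    cyc <- setdiff(terms, done)[1]
    stop_located("ontology contains a cycle involving term '", cyc, "'")
  }
  genes <- lapply(genes, sort)
  genes <- genes[lengths(genes) > 0]
  desc <- attr(collection, "descriptions")
  gene_set_collection(genes,
                      ifelse(names(genes) %in% names(desc %||% character(0)),
                             desc[names(genes)], ""))
}
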