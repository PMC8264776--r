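# Small in-code fixtures shared across test files.

tiny_expr <- function(n_genes = 5, n_samples = 6, seed = 42,
                      condition = NULL) {
  withr::with_seed(seed, {
    m <- matrix(round(rnorm(n_genes * n_samples), 4), n_genes, n_samples,
                dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                sprintf("s%d", seq_len(n_samples))))
  })
  expression_matrix(m, condition = condition)
}

tiny_edges <- function(n = 10, method = "pcc", seed = 1) {
  withr::with_seed(seed, {
    reg <- sprintf("tf%d", sample(1:4, n, replace = TRUE))
    tgt <- sprintf("g%d", seq_len(n))
    ranked_edge_list(reg, tgt, score = round(runif(n), 4), method = method)
  })
}

# A ranked edge list with the given regulator/target pairs, ranked in the
# order supplied (scores descend with position).
edges_in_order <- function(pairs, method = "x") {
  reg <- vapply(pairs, `[[`, character(1), 1)
  tgt <- vapply(pairs, `[[`, character(1), 2)
  ranked_edge_list(reg, tgt, score = rev(seq_along(pairs)),
                   rank = seq_along(pairs), method = method)
}

# Disjoint-clique co-regulation graph (weight 1 within cliques).
clique_graph <- function(sizes, weight = 1) {
  nodes <- character(0); g1 <- character(0); g2 <- character(0)
  w <- numeric(0)
  for (k in seq_along(sizes)) {
    members <- sprintf("c%d_n%02d", k, seq_len(sizes[k]))
    nodes <- c(nodes, members)
    idx <- utils::combn(members, 2)
    g1 <- c(g1, idx[1, ]); g2 <- c(g2, idx[2, ])
    w <- c(w, rep(weight, ncol(idx)))
  }
  list(nodes = nodes,
       edges = data.frame(gene1 = g1, gene2 = g2, weight = w,
                          stringsAsFactors = FALSE),
       unassigned = character(0))
}
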