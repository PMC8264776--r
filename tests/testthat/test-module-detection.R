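# Jaccard projection, Markov clustering, the TF-by-module feature matrix,
# enrichment statistics and ontology propagation.

test_that("regulator sets group the consensus by target", {
  cons <- edges_in_order(list(c("t1", "g1"), c("t2", "g1"), c("t1", "g2"),
                              c("t1", "t2")), "consensus")
  rs <- regulator_sets(cons)
  expect_setequal(rs$g1, c("t1", "t2"))
  expect_identical(rs$g2, "t1")
  # a TF appearing as a target is a node like any gene
  expect_identical(rs$t2, "t1")
  expect_error(regulator_sets(cons[0, ]), "empty")
})

test_that("the Jaccard index matches set arithmetic", {
  expect_equal(jaccard(c("a", "b", "c"), c("a", "b", "c")), 1.0)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 0)
})

test_that("co-regulation edges are thresholded at the quantile of nonzero overlaps", {
  # 20 gene pairs with distinct Jaccard values i/(i+2)
  reg_sets <- list()
  for (i in 1:20) {
    shared <- sprintf("p%d_s%d", i, seq_len(i))
    reg_sets[[sprintf("gA%02d", i)]] <- c(shared, sprintf("p%d_ua", i))
    reg_sets[[sprintf("gB%02d", i)]] <- c(shared, sprintf("p%d_ub", i))
  }
  gr <- coregulation_graph(reg_sets, q = 0.9)
  ji <- (1:20) / (1:20 + 2)
  expect_equal(nrow(gr$edges), sum(ji >= quantile(ji, 0.9)))
  expect_setequal(gr$unassigned,
                  names(reg_sets)[rep(ji < quantile(ji, 0.9), each = 2)])

  # identical regulator sets always survive with weight 1
  rs2 <- list(g1 = c("t1", "t2"), g2 = c("t1", "t2"), g3 = "t9", g4 = "t8")
  gr2 <- coregulation_graph(rs2, q = 0.95)
  expect_equal(gr2$edges$weight, 1.0)
  expect_setequal(c(gr2$edges$gene1, gr2$edges$gene2), c("g1", "g2"))

  expect_error(coregulation_graph(list(g1 = "t1", g2 = "t2"), 0.95),
               "degenerate")
})

test_that("Markov clustering recovers disjoint cliques exactly", {
  withr::with_seed(31, {
    for (k in c(2, 5, 10)) {
      sizes <- sample(3:8, k, replace = TRUE)
      gr <- clique_graph(sizes)
      part <- mcl_cluster(gr, inflation = 2)
      expect_length(part$modules, k)
      got <- sort(vapply(part$modules, function(g) paste(sort(g), collapse = ","),
                         character(1)))
      want <- sort(vapply(seq_len(k), function(i) {
        paste(sort(sprintf("c%d_n%02d", i, seq_len(sizes[i]))), collapse = ",")
      }, character(1)))
      expect_identical(unname(got), want)
      expect_length(part$unassigned, 0)
    }
  })
})

test_that("a weak bridge between two cliques does not merge them", {
  gr <- clique_graph(c(5, 5))
  gr$edges <- rbind(gr$edges,
                    data.frame(gene1 = "c1_n01", gene2 = "c2_n01",
                               weight = 0.05))
  part <- mcl_cluster(gr, inflation = 2)
  expect_length(part$modules, 2)
  expect_setequal(part$modules$M0001, sprintf("c1_n%02d", 1:5))
  expect_setequal(part$modules$M0002, sprintf("c2_n%02d", 1:5))
})

test_that("a complete uniform graph is a single module and MCL is deterministic", {
  gr <- clique_graph(8)
  expect_length(mcl_cluster(gr)$modules, 1)
  gr2 <- clique_graph(c(4, 6, 3))
  expect_identical(mcl_cluster(gr2), mcl_cluster(gr2))
  expect_error(mcl_cluster(gr, inflation = 1), "exceed 1")
})

test_that("feature-matrix entries equal the set-arithmetic oracle to 1e-15", {
  withr::with_seed(57, {
    cons_pairs <- list()
    for (t in sprintf("t%d", 1:6)) {
      for (g in sample(sprintf("g%02d", 1:30), 12)) {
        cons_pairs[[length(cons_pairs) + 1]] <- c(t, g)
      }
    }
  })
  cons <- edges_in_order(cons_pairs, "consensus")
  part <- list(modules = list(M0001 = sprintf("g%02d", 1:10),
                              M0002 = sprintf("g%02d", 11:25)),
               unassigned = character(0))
  G <- tf_module_matrix(cons, part)
  targets_of <- split(cons$target, cons$regulator)
  for (t in rownames(G)) {
    for (m in colnames(G)) {
      A <- unique(targets_of[[t]]); B <- part$modules[[m]]
      expect_equal(G[t, m],
                   length(intersect(A, B)) / length(union(A, B)),
                   tolerance = 1e-15)
    }
  }
  expect_true(all(G >= 0 & G <= 1))
})

test_that("feature-matrix limit cases: exact match, partial overlap, no overlap", {
  cons <- edges_in_order(list(c("t1", "a"), c("t1", "b"),
                              c("t2", "a"), c("t2", "b"), c("t2", "c"),
                              c("t2", "d"), c("t3", "z1"), c("t3", "z2")),
                         "consensus")
  part <- list(modules = list(M0001 = c("a", "b"),
                              M0002 = c("c", "d", "e", "f")),
               unassigned = character(0))
  G <- tf_module_matrix(cons, part)
  expect_equal(G["t1", "M0001"], 1.0)
  expect_equal(G["t2", "M0002"], 2 / 6)
  expect_equal(unname(G["t3", ]), c(0, 0))
})

test_that("hypergeometric enrichment matches enumeration and honors size filters", {
  part <- list(modules = list(M0001 = c("a", "b")), unassigned = character(0))
  coll <- gene_set_collection(list(hit = c("a", "b"),
                                   off = c("c", "d"),
                                   big = sprintf("x%03d", 1:600)))
  universe <- c("a", "b", "c", "d", sprintf("x%03d", 1:600))
  res <- enrich_modules(part, coll, universe, min_size = 2, max_size = 500,
                        q_threshold = 0.05)
  # the 600-gene set is dropped before testing
  expect_setequal(res$set_id, c("hit", "off"))
  p_hit <- res$p_value[res$set_id == "hit"]
  expect_equal(p_hit, hyper_tail_oracle(2, 2, length(universe), 2),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$set_id == "off"],
               hyper_tail_oracle(0, 2, length(universe), 2))
  # module disjoint from set: P(X >= 0) = 1
  expect_equal(res$p_value[res$set_id == "off"], 1)

  # worked 4-gene example: p = C(2,2) C(2,0) / C(4,2) = 1/6
  res2 <- enrich_modules(part, gene_set_collection(list(s = c("a", "b"))),
                         c("a", "b", "c", "d"), min_size = 1, max_size = 10)
  expect_equal(res2$p_value, 1 / 6, tolerance = 1e-12)

  expect_error(enrich_modules(part, coll, c("a")), "outside the universe")
})

test_that("BH correction matches the hand-rolled step-up oracle and is monotone", {
  withr::with_seed(91, {
    for (rep in 1:10) {
      p <- runif(sample(5:20, 1))^2
      q <- p.adjust(p, "BH")  # the package uses p.adjust internally
      expect_equal(q, bh_oracle(p), tolerance = 1e-12)
      ord <- order(p)
      expect_true(all(diff(q[ord]) >= -1e-15))
    }
  })
  # and through the enrichment interface
  part <- list(modules = list(M0001 = c("a", "b"), M0002 = c("c", "d")),
               unassigned = character(0))
  coll <- gene_set_collection(list(s1 = c("a", "b"), s2 = c("a", "c"),
                                   s3 = c("b", "d")))
  res <- enrich_modules(part, coll, letters[1:8], min_size = 1, max_size = 10)
  expect_equal(res$q_value, bh_oracle(res$p_value)[order(bh_oracle(res$p_value))],
               tolerance = 1e-12)
  expect_true(all(res$q_value >= res$p_value - 1e-15))
})

test_that("annotation propagation follows the child-to-ancestor union rule", {
  coll <- gene_set_collection(list(C = "g1"))
  edges <- data.frame(child = c("C", "B"), parent = c("B", "A"))
  out <- propagate_annotations(coll, edges)
  expect_identical(out$A, "g1")
  expect_identical(out$B, "g1")
  expect_identical(out$C, "g1")

  coll2 <- gene_set_collection(list(P = "p1", C = c("g1", "g2")))
  out2 <- propagate_annotations(coll2, data.frame(child = "C", parent = "P"))
  expect_setequal(out2$P, c("p1", "g1", "g2"))

  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"))
  expect_error(propagate_annotations(coll, cyc), "cycle")
})
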