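# Inference engines: discretization, MI estimation against a brute-force
# oracle, CLR z-scoring, ARACNe/DPI pruning, tree-ensemble importances,
# correlations and the top-K filter.

test_that("discretization uses right-closed equal-width bins", {
  expect_identical(discretize(c(0, 0.5, 1), 2), c(0L, 0L, 1L))
  expect_identical(discretize(rep(3.7, 5), 4), rep(0L, 5))
  expect_identical(discretize(c(-2, -1, 0, 1, 2), 4), c(0L, 0L, 1L, 2L, 3L))
  expect_error(discretize(1:5, 1), "at least 2")
})

test_that("mutual information matches hand values and the identity case", {
  expect_equal(mutual_information(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L)), 1.0)
  expect_equal(mutual_information(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)), 0.0)
  x <- c(0L, 1L, 2L, 1L, 0L, 2L, 2L)
  expect_equal(mutual_information(x, x), entropy_oracle(x))
  expect_error(mutual_information(0:2, 0:3), "equal length")
})

test_that("MI estimator equals the brute-force plug-in oracle to 1e-12", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      n_bins <- sample(2:8, 1)
      x <- discretize(rnorm(20), n_bins)
      y <- discretize(rnorm(20), n_bins)
      expect_equal(mutual_information(x, y), mi_oracle(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("CLR scores equal an independent z-combination of the MI table", {
  em <- tiny_expr(6, 12, seed = 7)
  tfs <- c("g1", "g2")
  n_bins <- 3
  net <- infer_clr(em, tfs, n_bins = n_bins, top_k = 1000)
  # independent recomputation: MI table by oracle, then explicit z loops
  genes <- rownames(em)
  disc <- lapply(genes, function(g) discretize(em[g, ], n_bins))
  names(disc) <- genes
  M <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  for (t in tfs) for (g in genes) {
    if (t != g) M[t, g] <- mi_oracle(disc[[t]], disc[[g]])
  }
  zfun <- function(v, self_mask) {
    v <- v[!self_mask]
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    function(x) if (s == 0) 0 else max(0, (x - m) / s)
  }
  for (k in seq_len(nrow(net))) {
    t <- net$regulator[k]; g <- net$target[k]
    zt <- zfun(M[t, ], genes == t)(M[t, g])
    zg <- zfun(M[, g], tfs == g)(M[t, g])
    expect_equal(net$score[k], sqrt(zt^2 + zg^2), tolerance = 1e-12)
  }
  # any edge at or below both backgrounds' means scores 0
  expect_true(all(net$score >= 0))
})

test_that("DPI removes exactly the triplet-minimum edge, honoring the tolerance", {
  M <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  M["A", "B"] <- M["B", "A"] <- 0.9
  M["B", "C"] <- M["C", "B"] <- 0.8
  M["A", "C"] <- M["C", "A"] <- 0.5
  keep0 <- grnscore:::dpi_prune(M, 0)
  expect_false(keep0["A", "C"])
  expect_true(keep0["A", "B"] && keep0["B", "C"])
  # 0.5 >= 0.8 * (1 - 0.4) = 0.48: nothing removed at eps = 0.4
  keep4 <- grnscore:::dpi_prune(M, 0.4)
  expect_true(all(keep4[upper.tri(keep4)]))
})

test_that("DPI matches the triangle enumeration oracle on random triangles", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      mis <- runif(3, 0.01, 1)
      eps <- sample(c(0, 0.1, 0.4), 1)
      M <- matrix(0, 3, 3)
      M[1, 2] <- M[2, 1] <- mis[1]
      M[1, 3] <- M[3, 1] <- mis[2]
      M[2, 3] <- M[3, 2] <- mis[3]
      keep <- grnscore:::dpi_prune(M, eps)
      removed <- c(!keep[1, 2], !keep[1, 3], !keep[2, 3])
      oracle <- unname(dpi_triangle_oracle(mis[1], mis[2], mis[3], eps))
      expect_identical(removed, oracle)
      expect_lte(sum(removed), 1)
      if (any(removed)) expect_equal(mis[which(removed)], min(mis))
    }
  })
})

test_that("ARACNe prunes the indirect edge of a regulatory chain", {
  # ground truth A -> B -> C with no direct A-C dependence
  removed_ac <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      a <- rnorm(120)
      b <- a + rnorm(120, sd = 0.3)
      cc <- b + rnorm(120, sd = 0.3)
    })
    m <- rbind(A = a, B = b, C = cc)
    colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
    em <- expression_matrix(m)
    net <- infer_aracne(em, tfs = c("A", "B"), n_bins = 4, top_k = 100)
    !"C" %in% net$target[net$regulator == "A" & net$score > 0]
  }, logical(1))
  expect_gte(sum(removed_ac), 9)
})

test_that("tree-ensemble importances identify the true regulator", {
  # single TF whose target is an exact copy
  withr::with_seed(5, {
    tf <- rnorm(50)
  })
  m <- rbind(TF1 = tf, TGT = tf)
  colnames(m) <- sprintf("s%d", 1:50)
  net <- infer_genie3(expression_matrix(m), "TF1", n_trees = 50, seed = 2,
                      top_k = 10)
  expect_identical(net$regulator[1], "TF1")
  expect_identical(net$target[1], "TGT")
  expect_gt(net$score[1], 0)

  # informative vs independent TF, over 20 seeds
  wins <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      tf1 <- rnorm(60); tf2 <- rnorm(60)
      tgt <- tf1 + rnorm(60, sd = 0.5)
    })
    m <- rbind(TF1 = tf1, TF2 = tf2, TGT = tgt)
    colnames(m) <- sprintf("s%d", 1:60)
    net <- infer_genie3(expression_matrix(m), c("TF1", "TF2"),
                        n_trees = 100, seed = seed, top_k = 100)
    s <- function(r, t) {
      v <- net$score[net$regulator == r & net$target == t]
      if (length(v)) v else 0
    }
    s("TF1", "TGT") > s("TF2", "TGT")
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  # seeded determinism
  em <- tiny_expr(6, 20, seed = 30)
  n1 <- infer_genie3(em, c("g1", "g2"), n_trees = 50, seed = 9, top_k = 50)
  n2 <- infer_genie3(em, c("g1", "g2"), n_trees = 50, seed = 9, top_k = 50)
  expect_identical(n1, n2)
})

test_that("correlation scoring handles affine, monotone and null cases", {
  x <- c(-2, -1, 0, 1, 2)
  m <- rbind(TF = x, LIN = 2 * x + 3, CUBE = x^3)
  colnames(m) <- sprintf("s%d", 1:5)
  em <- expression_matrix(m)
  pcc <- infer_correlation(em, "TF", "pearson", top_k = 10)
  scc <- infer_correlation(em, "TF", "spearman", top_k = 10)
  get <- function(net, t) net$score[net$target == t]
  expect_equal(get(pcc, "LIN"), 1.0)
  expect_equal(get(scc, "CUBE"), 1.0)
  expect_lt(get(pcc, "CUBE"), 1.0)

  nulls <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      m <- rbind(TF = rnorm(200), G = rnorm(200))
    })
    colnames(m) <- sprintf("s%d", 1:200)
    net <- infer_correlation(expression_matrix(m), "TF", "pearson", top_k = 5)
    net$score[net$target == "G"] < 0.2
  }, logical(1))
  expect_gte(mean(nulls), 0.95)
})

test_that("top-K filtering truncates with deterministic tie-breaking", {
  edges <- data.frame(
    regulator = c("t2", "t1", "t1", "t3", "t2"),
    target = c("g1", "g2", "g1", "g1", "g2"),
    score = c(0.9, 0.9, 0.5, 0.4, 0.3))
  out <- top_k_filter(edges, 3, method = "x")
  expect_identical(out$rank, 1:3)
  # tie at 0.9 broken lexicographically by regulator
  expect_identical(out$regulator[1:2], c("t1", "t2"))
  expect_identical(top_k_filter(edges, 99, "x")$rank, 1:5)
  expect_identical(top_k_filter(edges, 3, "x"), top_k_filter(edges, 3, "x"))
})

test_that("every method emits only TF-sourced, self-free edges at benchmark scale", {
  gt <- simulate_grn(2, 2, 10, p_bg = 0.05, seed = 41)
  expr <- simulate_expression(gt, 30, 30, seed = 42)
  nets <- list(
    infer_correlation(expr, gt$tfs, "pearson", top_k = 50),
    infer_correlation(expr, gt$tfs, "spearman", top_k = 50),
    infer_clr(expr, gt$tfs, top_k = 50),
    infer_aracne(expr, gt$tfs, top_k = 50),
    infer_genie3(expr, gt$tfs, n_trees = 50, seed = 1, top_k = 50))
  for (net in nets) {
    expect_true(all(net$regulator %in% gt$tfs))
    expect_true(all(net$regulator != net$target))
    expect_silent(validate_edge_list(net, regulators = gt$tfs))
  }
})
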