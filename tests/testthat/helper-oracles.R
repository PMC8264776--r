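# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (explicit loops, direct enumeration) so that agreement is
# evidence, not tautology.

# Plug-in mutual information in bits by explicit triple loop over bin pairs.
mi_oracle <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        pa <- sum(x == a) / n
        pb <- sum(y == b) / n
        mi <- mi + pab * log2(pab / (pa * pb))
      }
    }
  }
  mi
}

# Marginal entropy in bits.
entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# DPI on a single weighted triangle: which of the three edges (12, 13, 23)
# would be removed at tolerance eps.
dpi_triangle_oracle <- function(m12, m13, m23, eps) {
  removed <- c(`12` = FALSE, `13` = FALSE, `23` = FALSE)
  if (m12 > 0 && m13 > 0 && m23 > 0) {
    if (m12 < min(m13, m23) * (1 - eps)) removed["12"] <- TRUE
    if (m13 < min(m12, m23) * (1 - eps)) removed["13"] <- TRUE
    if (m23 < min(m12, m13) * (1 - eps)) removed["23"] <- TRUE
  }
  removed
}

# Hypergeometric upper tail P(X >= k) by direct enumeration of the pmf.
hyper_tail_oracle <- function(k, set_size, universe_size, module_size) {
  total <- 0
  for (i in k:min(set_size, module_size)) {
    total <- total + choose(set_size, i) *
      choose(universe_size - set_size, module_size - i) /
      choose(universe_size, module_size)
  }
  total
}

# Benjamini-Hochberg step-up adjusted p-values, written out longhand.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    idx <- ord[i]
    val <- min(1, p[idx] * n / i)
    running_min <- min(running_min, val)
    adj[idx] <- running_min
  }
  adj
}

# AUC-PR by explicit enumeration of every distinct threshold.
aucpr_oracle <- function(scores, labels, n_positives = sum(labels)) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    precision <- tp / sum(sel)
    recall <- tp / n_positives
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Mean-rank consensus by naive loops, no matrix machinery.
consensus_oracle <- function(lists) {
  all_edges <- unique(unlist(lapply(lists, function(l) {
    paste(l$regulator, l$target, sep = "|")
  })))
  means <- numeric(length(all_edges))
  for (i in seq_along(all_edges)) {
    total <- 0
    for (l in lists) {
      key <- paste(l$regulator, l$target, sep = "|")
      hit <- match(all_edges[i], key)
      total <- total + if (is.na(hit)) max(l$rank) + 1 else l$rank[hit]
    }
    means[i] <- total / length(lists)
  }
  parts <- strsplit(all_edges, "|", fixed = TRUE)
  reg <- vapply(parts, `[[`, character(1), 1)
  tgt <- vapply(parts, `[[`, character(1), 2)
  ord <- order(means, reg, tgt)
  data.frame(regulator = reg[ord], target = tgt[ord], mean_rank = means[ord],
             stringsAsFactors = FALSE)
}

# Adjusted Rand index between two partitions given as membership vectors.
ari_oracle <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
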