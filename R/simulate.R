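# Synthetic ground-truth networks and expression data.
#
# The generator emulates the statistical structure the pipeline assumes in
# real compendia: a modular regulatory program layout (each program's TFs
# regulate every target in the program's block), linear additive target
# expression with Gaussian noise, a sprinkling of cross-program background
# edges, and a condition-responsive positive TF class whose expression
# shifts under stress. TF families are assigned independently of programs
# (round-robin across the TF list) so that family membership, as in real
# TF repertoires, does not by itself determine the stress-responsive class;
# this is what gives the family-matched baseline its meaning.

#' Simulate a modular ground-truth regulatory network
#'
#' @param n_programs Number of regulatory programs (>= 1).
#' @param tfs_per_program TFs per program (>= 1).
#' @param targets_per_program Target genes per program block (>= 1).
#' @param p_bg Probability of a cross-program background edge, in `[0, 1)`.
#' @param weight_scale Mean absolute regulatory weight; weights are drawn
#'   `Normal(weight_scale, 0.1 * weight_scale)` with a random sign.
#' @param n_stress_programs Number of leading programs designated as
#'   stress-responsive; their TFs form the positive class.
#' @param n_families Number of TF family tags, assigned round-robin across
#'   all TFs irrespective of program.
#' @param delta Mean expression shift of positive-class TFs in stress
#'   samples (condition effect).
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   target expression.
#' @param tf_tf_edges If `TRUE`, background edges may also point at TFs of
#'   other programs (off by default: the consensus model assumes no
#'   combinatorial regulation or feedback loops).
#' @param seed Integer seed; identical seeds give identical ground truths.
#' @return A `grn_truth` list with elements `edges` (data.frame regulator,
#'   target, weight), `tfs`, `targets`, `program_of_tf`,
#'   `targets_of_program`, `positive_tfs`, `family_of_tf`, `delta`,
#'   `noise_sd`, `p_bg`.
#' @export
#' @examples
#' gt <- simulate_grn(2, 2, 10, p_bg = 0, seed = 7)
#' nrow(gt$edges)  # 2 programs x 2 TFs x 10 targets = 40 true edges
simulate_grn <- function(n_programs = 4, tfs_per_program = 5,
                         targets_per_program = 50, p_bg = 0.01,
                         weight_scale = 1, n_stress_programs = 1,
                         n_families = 4, delta = 2,
                         noise_sd = 0.5 * weight_scale,
                         tf_tf_edges = FALSE, seed = 1) {
  if (n_programs < 1 || targets_per_program < 1 || tfs_per_program < 1) {
    stop_located("n_programs, tfs_per_program and targets_per_program must all be >= 1")
  }
  if (p_bg < 0 || p_bg >= 1) stop_located("p_bg must lie in [0, 1)")
  if (n_stress_programs < 1 || n_stress_programs > n_programs) {
    stop_located("n_stress_programs must lie in 1..n_programs")
  }
  if (noise_sd <= 0) stop_located("noise_sd must be positive")

  n_tfs <- n_programs * tfs_per_program
  n_targets <- n_programs * targets_per_program
  tfs <- sprintf("TF%04d", seq_len(n_tfs))
  targets <- sprintf("G%05d", seq_len(n_targets))
  programs <- sprintf("P%02d", seq_len(n_programs))
  program_of_tf <- stats::setNames(rep(programs, each = tfs_per_program), tfs)
  targets_of_program <- split(targets, rep(programs, each = targets_per_program))
  family_of_tf <- stats::setNames(
    sprintf("F%02d", ((seq_len(n_tfs) - 1L) %% n_families) + 1L), tfs)
  positive_tfs <- tfs[program_of_tf %in% programs[seq_len(n_stress_programs)]]

  draw_weight <- function(n) {
    w <- stats::rnorm(n, mean = weight_scale, sd = 0.1 * weight_scale)
    w * sample(c(-1, 1), n, replace = TRUE)
  }

  edges <- with_rng(seed, {
    # Program edges: every program TF regulates every target in its block.
    reg <- character(0); tgt <- character(0)
    for (p in programs) {
      ptfs <- tfs[program_of_tf == p]
      ptargets <- targets_of_program[[p]]
      reg <- c(reg, rep(ptfs, each = length(ptargets)))
      tgt <- c(tgt, rep(ptargets, times = length(ptfs)))
    }
    w <- draw_weight(length(reg))
    # Background edges: TF x out-of-program target, each with prob p_bg.
    if (p_bg > 0) {
      cand_tgt <- if (tf_tf_edges) c(targets, tfs) else targets
      for (tf in tfs) {
        own <- targets_of_program[[program_of_tf[[tf]]]]
        pool <- setdiff(cand_tgt, c(own, tf))
        hit <- pool[stats::runif(length(pool)) < p_bg]
        if (length(hit)) {
          reg <- c(reg, rep(tf, length(hit)))
          tgt <- c(tgt, hit)
          w <- c(w, draw_weight(length(hit)))
        }
      }
    }
    data.frame(regulator = reg, target = tgt, weight = w,
               stringsAsFactors = FALSE)
  })

  structure(list(edges = edges, tfs = tfs, targets = targets,
                 program_of_tf = program_of_tf,
                 targets_of_program = targets_of_program,
                 positive_tfs = positive_tfs, family_of_tf = family_of_tf,
                 delta = delta, noise_sd = noise_sd, p_bg = p_bg),
            class = "grn_truth")
}

#' Simulate an expression matrix from a ground-truth network
#'
#' TF profiles are i.i.d. `Normal(0, 1)` per sample; positive-class TFs
#' additionally receive the condition effect `delta` in stress samples.
#' Each target is the weighted sum of its regulators' profiles plus
#' `Normal(0, noise_sd)` noise. Samples carry `control`/`stress` condition
#' labels.
#'
#' @param gt Ground truth from [simulate_grn()].
#' @param n_control,n_stress Sample counts per condition; their sum must be
#'   at least 4.
#' @param seed Integer seed.
#' @return An expression matrix (genes x samples) with a `condition`
#'   attribute.
#' @export
simulate_expression <- function(gt, n_control = 75, n_stress = 75, seed = 1) {
  if (!inherits(gt, "grn_truth")) stop_located("gt must come from simulate_grn()")
  if (length(gt$tfs) == 0 || length(gt$targets) == 0) {
    stop_located("ground truth has no genes")
  }
  n <- n_control + n_stress
  if (n < 4) stop_located("n_control + n_stress must be at least 4")
  condition <- c(rep("control", n_control), rep("stress", n_stress))
  genes <- c(gt$tfs, gt$targets)
  with_rng(seed, {
    tf_mat <- matrix(stats::rnorm(length(gt$tfs) * n), length(gt$tfs), n,
                     dimnames = list(gt$tfs, NULL))
    if (length(gt$positive_tfs) && gt$delta != 0) {
      tf_mat[gt$positive_tfs, condition == "stress"] <-
        tf_mat[gt$positive_tfs, condition == "stress"] + gt$delta
    }
    vals <- matrix(0, length(genes), n,
                   dimnames = list(genes, sprintf("S%04d", seq_len(n))))
    vals[gt$tfs, ] <- tf_mat
    # Targets: linear additive model over their regulators.
    by_target <- split(seq_len(nrow(gt$edges)), gt$edges$target)
    noise <- matrix(stats::rnorm(length(genes) * n, sd = gt$noise_sd),
                    length(genes), n, dimnames = list(genes, NULL))
    for (tg in names(by_target)) {
      idx <- by_target[[tg]]
      w <- gt$edges$weight[idx]
      vals[tg, ] <- drop(w %*% tf_mat[gt$edges$regulator[idx], , drop = FALSE]) +
        noise[tg, ]
    }
    orphan <- setdiff(gt$targets, names(by_target))
    if (length(orphan)) vals[orphan, ] <- noise[orphan, ]
    expression_matrix(vals, condition = condition)
  })
}

#' Export TF labels from a ground truth
#'
#' Positive-class TFs are labeled `positive`, all others `negative`; the
#' family tag is carried along so the family-matched baseline can be run.
#'
#' @param gt Ground truth from [simulate_grn()].
#' @param require_both_classes Error when one class is empty (default);
#'   set `FALSE` to inspect degenerate designs.
#' @return A label set data frame.
#' @export
export_labels <- function(gt, require_both_classes = TRUE) {
  if (!inherits(gt, "grn_truth")) stop_located("gt must come from simulate_grn()")
  lab <- ifelse(gt$tfs %in% gt$positive_tfs, "positive", "negative")
  label_set(gt$tfs, lab, family = gt$family_of_tf[gt$tfs],
            require_both_classes = require_both_classes)
}

#' Ground-truth modules as a gene-set collection
#' @param gt Ground truth from [simulate_grn()].
#' @return Gene-set collection of the target blocks, one set per program.
#' @export
true_modules <- function(gt) {
  gene_set_collection(gt$targets_of_program,
                      paste("targets of program", names(gt$targets_of_program)))
}

#' Write a full simulated study to a directory
#'
#' Materializes `expr.tsv`, `tfs.txt`, `labels.tsv`, `truth_edges.tsv` and
#' `modules_true.gmt` in `dir`.
#'
#' @param gt Ground truth from [simulate_grn()].
#' @param expr Expression matrix from [simulate_expression()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_simulation <- function(gt, expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expr.tsv"),
             tfs = file.path(dir, "tfs.txt"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth_edges.tsv"),
             modules = file.path(dir, "modules_true.gmt"))
  write_expression_matrix(expr, paths[["expr"]])
  write_tf_list(gt$tfs, paths[["tfs"]])
  write_labels(export_labels(gt), paths[["labels"]])
  truth <- ranked_edge_list(gt$edges$regulator, gt$edges$target,
                            score = abs(gt$edges$weight), method = "truth")
  write_edge_list(truth, paths[["truth"]])
  write_gmt(true_modules(gt), paths[["modules"]])
  invisible(paths)
}
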