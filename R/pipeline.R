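# One-command orchestration: simulate -> infer x methods -> aggregate ->
# cluster -> score -> evaluate, with a JSON run manifest for provenance.
# Every intermediate artifact is materialized in the standard text formats
# so any stage can be rerun or swapped from the command line.

#' Run the full pipeline on a simulated study
#'
#' Executes all stages with the parameters of `config` inside `workdir`,
#' writing every intermediate file plus `manifest.json`. All randomness
#' derives from `config$seed`, so a rerun with the same configuration
#' reproduces every output byte for byte (manifest timestamps aside).
#'
#' @param config Configuration list from [validate_config()] /
#'   [default_config()].
#' @param workdir Writable working directory (created if missing).
#' @param exclude Method tags to drop from inference and aggregation (e.g.
#'   `c("pcc", "scc")` for the aggregate-sans-correlation consensus).
#' @return The run manifest, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config = default_config(), workdir,
                         exclude = character()) {
  cfg <- check_config(config)
  methods <- setdiff(cfg$methods, exclude)
  if (length(methods) < 2) {
    stop_located("pipeline needs at least 2 inference methods after exclusion")
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 6)
  manifest <- list(config = cfg, exclude = exclude, stages = list())
  t_all <- Sys.time()

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    log_msg("stage ", name, " ...")
    result <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, workdir, t_all)
      stop_located("stage '", name, "' failed: ", conditionMessage(e))
    })
    outs <- result$outputs
    manifest$stages[[name]] <<- list(
      status = "ok",
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(outs)), basename(outs))))
    result$value
  }

  sim <- run_stage("simulate", function() {
    gt <- simulate_grn(n_programs = cfg$n_programs,
                       tfs_per_program = cfg$tfs_per_program,
                       targets_per_program = cfg$targets_per_program,
                       p_bg = cfg$p_bg, weight_scale = cfg$weight_scale,
                       n_stress_programs = cfg$n_stress_programs,
                       n_families = cfg$n_families, delta = cfg$delta,
                       noise_sd = cfg$noise_sd, seed = seeds[1])
    expr <- simulate_expression(gt, cfg$n_control, cfg$n_stress,
                                seed = seeds[2])
    paths <- write_simulation(gt, expr, workdir)
    list(value = list(gt = gt, expr = expr, labels = export_labels(gt)),
         outputs = paths)
  })

  nets <- run_stage("infer", function() {
    n_bins <- if (cfg$mi_bins > 0) cfg$mi_bins else NULL
    nets <- lapply(methods, function(m) {
      infer_network(sim$expr, sim$gt$tfs, method = m, top_k = cfg$top_k,
                    n_bins = n_bins, dpi_tolerance = cfg$dpi_tolerance,
                    n_trees = cfg$n_trees, seed = seeds[3])
    })
    names(nets) <- methods
    paths <- vapply(methods, function(m) {
      p <- file.path(workdir, paste0(m, ".tsv"))
      write_edge_list(nets[[m]], p)
      p
    }, character(1))
    list(value = nets, outputs = paths)
  })

  consensus <- run_stage("aggregate", function() {
    cons <- consensus_network(nets, K = cfg$top_k)
    p <- file.path(workdir, "consensus.tsv")
    write_edge_list(cons, p)
    list(value = cons, outputs = p)
  })

  clust <- run_stage("cluster", function() {
    graph <- coregulation_graph(regulator_sets(consensus),
                                q = cfg$coreg_quantile)
    partition <- mcl_cluster(graph, inflation = cfg$inflation)
    G <- tf_module_matrix(consensus, partition)
    p_mod <- file.path(workdir, "modules.gmt")
    p_g <- file.path(workdir, "G.tsv")
    write_gmt(gene_set_collection(
      partition$modules, paste0("module of ", lengths(partition$modules),
                                " co-regulated genes")), p_mod)
    write_feature_matrix(G, p_g)
    list(value = list(partition = partition, G = G),
         outputs = c(p_mod, p_g))
  })

  scoretab <- run_stage("score", function() {
    tuned <- tune_c(clust$G, sim$labels, grid = cfg$c_grid,
                    n_folds = cfg$n_folds, seed = seeds[4])
    cv <- crossvalidate(clust$G, sim$labels, C = tuned$C,
                        n_folds = cfg$n_folds, n_runs = cfg$n_runs,
                        seed = seeds[4])
    st <- score_all(clust$G, sim$labels, C = tuned$C,
                    n_folds = cfg$n_folds, seed = seeds[5])
    imp <- feature_importance(st)
    p_scores <- file.path(workdir, "scores.tsv")
    p_cv <- file.path(workdir, "cv.tsv")
    p_imp <- file.path(workdir, "importance.tsv")
    write_table_tsv(as.data.frame(st), p_scores)
    cv_df <- cv$folds
    cv_df$C <- tuned$C
    write_table_tsv(cv_df, p_cv)
    write_table_tsv(imp, p_imp)
    list(value = list(scores = st, cv = cv, C = tuned$C, importance = imp),
         outputs = c(p_scores, p_cv, p_imp))
  })

  run_stage("diagnose", function() {
    dd <- decile_diagnostic(scoretab$scores, sim$expr,
                            n_bins = cfg$n_bins_decile, n_folds = 3,
                            group_size = max(1L, cfg$n_bins_decile %/% 10L),
                            seed = seeds[6])
    p <- file.path(workdir, "bins.tsv")
    write_table_tsv(dd, p)
    list(value = dd, outputs = p)
  })

  run_stage("evaluate", function() {
    truth <- sim$gt$edges
    per_method <- lapply(nets, edge_aupr, truth = truth)
    rows <- data.frame(method = c(names(per_method), "consensus"),
                       aupr = c(unlist(per_method),
                                edge_aupr(consensus, truth)),
                       stringsAsFactors = FALSE)
    cons_metrics <- edge_metrics(
      consensus[consensus$rank <= nrow(truth), ], truth)
    p_m <- file.path(workdir, "metrics.tsv")
    write_table_tsv(cbind(rows,
                          consensus_precision_at_truth = cons_metrics$precision,
                          consensus_recall_at_truth = cons_metrics$recall),
                    p_m)
    list(value = rows, outputs = p_m)
  })

  manifest <- write_manifest(manifest, workdir, t_all)
  log_msg("pipeline complete in ",
          round(manifest$elapsed_s, 1), " s")
  invisible(manifest)
}

write_manifest <- function(manifest, workdir, t_start) {
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start,
                                            units = "secs"))
  manifest$finished_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
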