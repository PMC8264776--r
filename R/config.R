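# Pipeline configuration: a flat YAML key-value file with strict key
# checking (unknown keys are an error, catching typos in experiment
# configs) and defaults filled for anything omitted.

#' Default pipeline configuration
#'
#' @return Named list of every configuration key with its default value.
#' @export
default_config <- function() {
  list(
    # network inference
    top_k = 500000L,
    mi_bins = 0L,          # 0 = ceiling(sqrt(n_samples))
    dpi_tolerance = 0,
    n_trees = 1000L,
    methods = c("pcc", "scc", "clr", "aracne", "genie3"),
    # module detection
    inflation = 2.0,
    coreg_quantile = 0.95,
    # classifier
    c_grid = c(0.001, 10, 0.1),
    n_folds = 5L,
    n_runs = 10L,
    n_bins_decile = 100L,
    q_threshold = 0.05,
    # synthetic study design
    n_programs = 4L,
    tfs_per_program = 5L,
    targets_per_program = 50L,
    n_stress_programs = 1L,
    n_families = 4L,
    p_bg = 0.01,
    weight_scale = 1,
    delta = 2,
    noise_sd = 0.5,
    n_control = 75L,
    n_stress = 75L,
    seed = 1L
  )
}

#' Configuration for the built-in synthetic benchmark
#'
#' The default configuration targets compendium-scale inputs, where an
#' edge budget of 500,000 is well under 1% of the candidate edge space.
#' The synthetic benchmark is four orders of magnitude smaller, so this
#' helper rescales the budget-like parameters to the benchmark's edge
#' universe while leaving the study design itself (programs, sample sizes,
#' noise, condition effect) at its defaults: `top_k` becomes 1.5 x the
#' expected number of planted edges, the tree ensembles use 200 trees, the
#' score-bin diagnostic uses 10 bins of the 20 simulated TFs, and the
#' co-regulation quantile drops to 0.75 because the benchmark's overlap
#' distribution, unlike a sparse compendium-scale consensus, is dominated
#' by genuinely co-regulated pairs (see the methods vignette for the
#' sensitivity of this parameter).
#'
#' @return A configuration list (see [default_config()]).
#' @export
benchmark_config <- function() {
  cfg <- default_config()
  n_true <- cfg$n_programs * cfg$tfs_per_program * cfg$targets_per_program
  cfg$top_k <- as.integer(ceiling(1.5 * n_true))
  cfg$n_trees <- 200L
  cfg$n_bins_decile <- 10L
  cfg$coreg_quantile <- 0.75
  cfg
}

#' Read and validate a pipeline configuration file
#'
#' The file is flat YAML (`key: value`); omitted keys take their defaults,
#' unknown keys and out-of-range values are located errors. An empty file
#' yields the full default configuration.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A validated configuration list (see [default_config()]).
#' @export
validate_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_located("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop_located("config must be a key-value document")
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop_located("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  check_config(cfg)
}

# Invariant checks shared by validate_config() and run_pipeline().
check_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(default_config()))
  if (length(unknown)) {
    stop_located("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(names(default_config()), names(cfg))
  if (length(missing)) {
    stop_located("config is missing key(s): ", paste(missing, collapse = ", "))
  }
  check_range <- function(key, lo = -Inf, hi = Inf, lo_open = FALSE,
                          hi_open = FALSE, integer = FALSE, len = 1) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != len || anyNA(v)) {
      stop_located("config key '", key, "' must be numeric of length ", len)
    }
    bad <- any(if (lo_open) v <= lo else v < lo) ||
      any(if (hi_open) v >= hi else v > hi)
    if (bad) {
      stop_located("config key '", key, "' = ", paste(v, collapse = ","),
                   " is out of range")
    }
    if (integer && any(v != round(v))) {
      stop_located("config key '", key, "' must be an integer")
    }
  }
  check_range("top_k", lo = 1, integer = TRUE)
  check_range("mi_bins", lo = 0, integer = TRUE)
  check_range("dpi_tolerance", lo = 0)
  check_range("n_trees", lo = 1, integer = TRUE)
  check_range("inflation", lo = 1, lo_open = TRUE)
  check_range("coreg_quantile", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  check_range("c_grid", len = 3)
  if (cfg$c_grid[1] <= 0 || cfg$c_grid[2] < cfg$c_grid[1] || cfg$c_grid[3] <= 0) {
    stop_located("config key 'c_grid' must be (lo > 0, hi >= lo, step > 0)")
  }
  check_range("n_folds", lo = 2, integer = TRUE)
  check_range("n_runs", lo = 0, integer = TRUE)
  check_range("n_bins_decile", lo = 1, integer = TRUE)
  check_range("q_threshold", lo = 0, hi = 1, lo_open = TRUE)
  check_range("n_programs", lo = 1, integer = TRUE)
  check_range("tfs_per_program", lo = 1, integer = TRUE)
  check_range("targets_per_program", lo = 1, integer = TRUE)
  check_range("n_stress_programs", lo = 1, integer = TRUE)
  if (cfg$n_stress_programs > cfg$n_programs) {
    stop_located("config key 'n_stress_programs' exceeds n_programs")
  }
  check_range("n_families", lo = 1, integer = TRUE)
  check_range("p_bg", lo = 0, hi = 1, hi_open = TRUE)
  check_range("weight_scale", lo = 0, lo_open = TRUE)
  check_range("delta")
  check_range("noise_sd", lo = 0, lo_open = TRUE)
  check_range("n_control", lo = 0, integer = TRUE)
  check_range("n_stress", lo = 0, integer = TRUE)
  if (cfg$n_control + cfg$n_stress < 4) {
    stop_located("config keys n_control + n_stress must total at least 4")
  }
  check_range("seed", integer = TRUE)
  known_methods <- c("pcc", "scc", "clr", "aracne", "genie3")
  if (!is.character(cfg$methods) || length(cfg$methods) == 0 ||
      !all(cfg$methods %in% known_methods)) {
    stop_located("config key 'methods' must be a subset of: ",
                 paste(known_methods, collapse = ", "))
  }
  cfg
}

#' Write a configuration list as YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
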