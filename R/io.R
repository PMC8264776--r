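# Readers and writers for every on-disk format the pipeline touches.
#
# All formats are UTF-8, tab-separated text. Lines starting with '#' are
# comments and ignored, with one exception: the expression writer records
# per-sample condition labels on a '#condition' comment line so that the
# condition survives a round trip. Writers are byte-stable: identical
# objects produce identical files.

read_lines_clean <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*$", lines)
  lines[keep]
}

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. An optional `#condition` comment line (written by
#' [write_expression_matrix()]) restores per-sample condition labels.
#'
#' @param path Path to a TSV file.
#' @return A validated expression matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  cond_line <- grep("^#condition\t", lines, value = TRUE)
  lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  if (length(lines) < 2) stop_located("expression file '", path, "' has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stop_located("duplicate sample id '", sample_ids[duplicated(sample_ids)][1],
                 "' in ", path)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    stop_located("row ", which(nfield != length(header))[1], " of ", path,
                 " has ", nfield[nfield != length(header)][1],
                 " fields, expected ", length(header))
  }
  gene_ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(gene_ids)) {
    stop_located("duplicate gene id '", gene_ids[duplicated(gene_ids)][1],
                 "' in ", path)
  }
  vals <- matrix(NA_real_, length(gene_ids), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop_located("non-numeric value '", body[[i]][-1][j], "' at gene '",
                   gene_ids[i], "', sample '", sample_ids[j], "' in ", path)
    }
    vals[i, ] <- v
  }
  condition <- NULL
  if (length(cond_line)) {
    cf <- strsplit(cond_line[1], "\t", fixed = TRUE)[[1]][-1]
    if (length(cf) != length(sample_ids)) {
      stop_located("#condition line in ", path, " has ", length(cf),
                   " labels for ", length(sample_ids), " samples")
    }
    condition <- cf
  }
  expression_matrix(vals, condition = condition)
}

#' Write an expression matrix to a tab-separated file
#' @param x Expression matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  cond <- attr(x, "condition")
  if (!is.null(cond)) {
    writeLines(paste(c("#condition", cond), collapse = "\t"), con)
  }
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(rownames(x)[i], format_num(x[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a ranked edge list from a tab-separated file
#'
#' Expects header columns `regulator`, `target`, `score`, `rank`. The rank
#' column must be a permutation of 1..n and self-edges are rejected.
#'
#' @param path Path to a TSV file.
#' @return A ranked edge list; the `method` attribute is taken from an
#'   optional `#method` comment line (default `"unknown"`).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  method_line <- grep("^#method\t", lines, value = TRUE)
  method <- if (length(method_line)) {
    strsplit(method_line[1], "\t", fixed = TRUE)[[1]][2]
  } else "unknown"
  lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("regulator", "target", "score", "rank")
  if (!identical(header[seq_along(need)], need)) {
    stop_located("edge list ", path, " must start with header: ",
                 paste(need, collapse = ", "))
  }
  if (length(lines) == 1) {
    return(ranked_edge_list(character(), character(), numeric(), integer(),
                            method = method))
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  reg <- vapply(body, `[[`, character(1), 1)
  tgt <- vapply(body, `[[`, character(1), 2)
  score <- as.numeric(vapply(body, `[[`, character(1), 3))
  rank <- as.integer(vapply(body, `[[`, character(1), 4))
  ranked_edge_list(reg, tgt, score, rank, method = method)
}

#' Write a ranked edge list to a tab-separated file
#' @param x Ranked edge list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(x, path) {
  validate_edge_list(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste("#method", attr(x, "method") %||% "unknown", sep = "\t"), con)
  writeLines("regulator\ttarget\tscore\trank", con)
  if (nrow(x)) {
    ord <- order(x$rank)
    writeLines(paste(x$regulator[ord], x$target[ord],
                     format_num(x$score[ord]), x$rank[ord], sep = "\t"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene-set collection in GMT format
#'
#' Each line: set id, TAB, description, TAB, one or more gene ids. Empty
#' lines are ignored.
#'
#' @param path Path to a GMT file.
#' @return A gene-set collection (named list with `descriptions` attribute).
#' @export
read_gmt <- function(path) {
  lines <- read_lines_clean(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    stop_located("line ", which(short)[1], " of ", path,
                 " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop_located("duplicate set id '", ids[duplicated(ids)][1], "' in ", path)
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection in GMT format
#' @param collection Gene-set collection.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(collection)),
                                             names(collection))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(collection)) {
    writeLines(paste(c(id, desc[[id]], collection[[id]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a TF label file
#'
#' Tab-separated with header `tf_id`, `label` and optional `family`.
#'
#' @param path Path to a TSV file.
#' @param require_both_classes Passed to [validate_label_set()].
#' @return A label set data frame.
#' @export
read_labels <- function(path, require_both_classes = TRUE) {
  lines <- read_lines_clean(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (!all(c("tf_id", "label") %in% header)) {
    stop_located("label file ", path, " must have header columns tf_id, label")
  }
  body <- fields[-1]
  get_col <- function(col) {
    j <- match(col, header)
    vapply(body, function(f) if (length(f) >= j) f[[j]] else NA_character_,
           character(1))
  }
  fam <- if ("family" %in% header) get_col("family") else NA_character_
  label_set(get_col("tf_id"), get_col("label"), fam,
            require_both_classes = require_both_classes)
}

#' Write a TF label file
#' @param labels Label set.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("tf_id\tlabel\tfamily", con)
  writeLines(paste(labels$tf_id, labels$label, labels$family, sep = "\t"), con)
  invisible(path)
}

#' Read a regulator (TF) list, one identifier per line
#' @param path Path to a text file.
#' @return Character vector of unique TF identifiers.
#' @export
read_tf_list <- function(path) {
  tfs <- read_lines_clean(path)
  tfs <- trimws(tfs[!grepl("^\\s*#", tfs)])
  validate_regulators(tfs)
  unique(tfs)
}

#' Write a regulator (TF) list
#' @param tfs Character vector of TF identifiers.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tf_list <- function(tfs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(tfs), con)
  invisible(path)
}

#' Read a TF-by-module feature matrix from TSV
#' @param path Path written by [write_feature_matrix()].
#' @return Numeric matrix, TFs in rows, module ids in columns.
#' @export
read_feature_matrix <- function(path) {
  lines <- read_lines_clean(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  tf <- vapply(body, `[[`, character(1), 1)
  m <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(length(header) - 1)))
  if (length(header) == 2) m <- matrix(m, ncol = 1)
  dimnames(m) <- list(tf, header[-1])
  m
}

#' Write a TF-by-module feature matrix to TSV
#' @param G Numeric matrix with TF rownames and module colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(G, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("tf_id", colnames(G)), collapse = "\t"), con)
  for (i in seq_len(nrow(G))) {
    writeLines(paste(c(rownames(G)[i], format_num(G[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a data frame as a plain TSV table
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) format_num(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
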