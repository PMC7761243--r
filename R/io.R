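#' Read a sample-by-feature intensity table
#'
#' Reads a delimited text file (comma or tab, auto-detected) of per-sample
#' intensity values plus a group column, and returns a validated
#' [expression_matrix()].  Orientation is auto-detected: if `group_column`
#' is a column header, rows are samples; if it is found in the first
#' column, the table is feature-by-sample and is transposed.  The first
#' column (or header row) carries the sample identifiers.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param group_column name of the column (or row, for transposed input)
#'   holding the two-level group label.
#' @param phenotype_column optional name of a numeric per-sample phenotype
#'   column (or row).
#'
#' @return An `ExpressionMatrix`.
#' @export
read_input_table <- function(path, group_column = "group",
                             phenotype_column = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- detect_delimiter(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("format error: fewer than two columns parsed")
  header <- names(df)

  if (group_column %in% header) {
    ids <- trimws(df[[1]])
    group <- df[[group_column]]
    keep <- setdiff(header[-1], c(group_column, phenotype_column))
    phenotype <- if (!is.null(phenotype_column)) {
      if (!phenotype_column %in% header) {
        stop("format error: phenotype column '", phenotype_column,
             "' not found")
      }
      as.numeric(df[[phenotype_column]])
    }
    values <- numeric_block(df[keep], ids, keep)
    return(expression_matrix(values, sample_ids = ids, feature_ids = keep,
                             group = group, phenotype = phenotype))
  }

  first_col <- trimws(df[[1]])
  if (group_column %in% first_col) {
    # feature-by-sample layout: columns after the first are samples
    ids <- header[-1]
    group <- unlist(df[first_col == group_column, -1, drop = TRUE],
                    use.names = FALSE)
    phenotype <- NULL
    special <- group_column
    if (!is.null(phenotype_column)) {
      if (!phenotype_column %in% first_col) {
        stop("format error: phenotype row '", phenotype_column,
             "' not found")
      }
      phenotype <- as.numeric(df[first_col == phenotype_column, -1])
      special <- c(special, phenotype_column)
    }
    keep <- !(first_col %in% special)
    features <- first_col[keep]
    block <- df[keep, -1, drop = FALSE]
    values <- t(numeric_block(block, features, ids))
    return(expression_matrix(values, sample_ids = ids,
                             feature_ids = features, group = group,
                             phenotype = phenotype))
  }

  stop("format error: group column '", group_column,
       "' found neither in the header nor in the first column")
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

# convert a character data.frame block to a numeric matrix, reporting the
# first offending cell on failure
numeric_block <- function(block, row_ids, col_ids) {
  m <- matrix(NA_real_, nrow = nrow(block), ncol = ncol(block))
  for (j in seq_along(block)) {
    v <- suppressWarnings(as.numeric(block[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("non-numeric intensity value '", block[[j]][i],
           "' at row '", row_ids[i], "', column '", col_ids[j], "'")
    }
    m[, j] <- v
  }
  m
}

#' Read a knowledge-based feature grouping file
#'
#' Two-column delimited file mapping feature identifiers to chemical class
#' labels (for knowledge-driven or hybrid feature aggregation).  Features
#' absent from the file are treated as singleton classes downstream.
#'
#' @param path path to a two-column CSV/TSV file with a header row.
#' @return Named character vector: `names()` are feature ids, values are
#'   class labels.  Empty file gives an empty map.
#' @export
read_grouping_file <- function(path) {
  if (!file.exists(path)) stop("grouping file not found: ", path)
  sep <- detect_delimiter(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(setNames(character(0), character(0)))
  if (ncol(df) < 2) stop("grouping file must have two columns")
  feats <- trimws(as.character(df[[1]]))
  classes <- trimws(as.character(df[[2]]))
  dup <- duplicated(feats)
  if (any(dup)) {
    for (f in unique(feats[dup])) {
      if (length(unique(classes[feats == f])) > 1) {
        stop("feature '", f, "' listed with conflicting classes: ",
             paste(unique(classes[feats == f]), collapse = ", "))
      }
    }
    keep <- !dup
    feats <- feats[keep]
    classes <- classes[keep]
  }
  setNames(classes, feats)
}

#' Write the three result tables
#'
#' Writes `edgelist.csv`, `nodelist.csv` and `netgsa_results.csv` into
#' `outdir`.  Column schemas are fixed; see [read_outputs()] for the
#' inverse operation.
#'
#' @param edges data.frame with columns `feature_a`, `feature_b`,
#'   `pcor_group1`, `pcor_group2`, `sel_prob_group1`, `sel_prob_group2`,
#'   `edge_class`.
#' @param nodes data.frame with columns `feature_id`, `direction`,
#'   `pvalue`, `qvalue`, `subnetwork`.
#' @param enrichment data.frame with columns `subnetwork`, `n_nodes`,
#'   `n_edges_group1`, `n_edges_group2`, `statistic`, `pvalue`,
#'   `adj_pvalue`.
#' @param outdir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_outputs <- function(edges, nodes, enrichment, outdir) {
  check_columns(edges, edgelist_columns(), "edges")
  check_columns(nodes, nodelist_columns(), "nodes")
  check_columns(enrichment, enrichment_columns(), "enrichment")
  referenced <- setdiff(unique(as.character(nodes$subnetwork)), "none")
  known <- as.character(enrichment$subnetwork)
  if (!all(referenced %in% known)) {
    stop("nodes reference unknown subnetworks: ",
         paste(setdiff(referenced, known), collapse = ", "))
  }
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  paths <- file.path(outdir,
                     c("edgelist.csv", "nodelist.csv", "netgsa_results.csv"))
  write.csv(format_sig(edges), paths[1], row.names = FALSE, quote = TRUE)
  write.csv(format_sig(nodes), paths[2], row.names = FALSE, quote = TRUE)
  write.csv(format_sig(enrichment), paths[3], row.names = FALSE,
            quote = TRUE)
  invisible(paths)
}

#' Read back the three result tables
#'
#' @param outdir directory written by [write_outputs()].
#' @return list with `edges`, `nodes`, `enrichment` data.frames.
#' @export
read_outputs <- function(outdir) {
  list(
    edges = read.csv(file.path(outdir, "edgelist.csv"),
                     check.names = FALSE, stringsAsFactors = FALSE),
    nodes = read.csv(file.path(outdir, "nodelist.csv"),
                     check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = c(subnetwork = "character")),
    enrichment = read.csv(file.path(outdir, "netgsa_results.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(subnetwork = "character"))
  )
}

edgelist_columns <- function() {
  c("feature_a", "feature_b", "pcor_group1", "pcor_group2",
    "sel_prob_group1", "sel_prob_group2", "edge_class")
}
nodelist_columns <- function() {
  c("feature_id", "direction", "pvalue", "qvalue", "subnetwork")
}
enrichment_columns <- function() {
  c("subnetwork", "n_nodes", "n_edges_group1", "n_edges_group2",
    "statistic", "pvalue", "adj_pvalue")
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(what, " must be a data.frame")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing columns: ", paste(missing, collapse = ", "))
  }
}

# round numeric columns to 6 significant digits for stable round-trips
format_sig <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- signif(df[[j]], 6)
    }
  }
  df
}
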