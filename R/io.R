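#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read an expression matrix from MTX (directory) or dense TSV
#'
#' An MTX directory must hold `matrix.mtx` (genes x cells, MatrixMarket),
#' `genes.tsv` and `barcodes.tsv`; the matrix is returned cells x genes.
#' A TSV file is read as cells x genes with row names in the first column.
#'
#' @param path MTX directory or TSV file path.
#' @return dense cells x genes numeric matrix.
#' @export
read_expression <- function(path) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    m <- as.matrix(Matrix::t(m))
    dimnames(m) <- list(cells, genes)
    m
  } else {
    if (!file.exists(path))
      stop(sprintf("I/O error: file not found: %s", path), call. = FALSE)
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    as.matrix(df)
  }
}

#' Write an expression matrix as an MTX directory
#'
#' @param expr cells x genes matrix.
#' @param dir output directory (created if needed); receives `matrix.mtx`
#'   (genes x cells), `genes.tsv`, `barcodes.tsv`.
#' @export
write_expression_mtx <- function(expr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(t(expr), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(expr), file.path(dir, "genes.tsv"))
  writeLines(rownames(expr), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# deterministic TSV writer with 6-significant-digit floats
write_tsv6 <- function(df, path, row_names = FALSE) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(signif(x, 6), format = "g",
                                                 digits = 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

write_matrix_tsv6 <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% as.character(seq_len(nrow(m))),
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write_tsv6(df, path)
}

#' Load and align all pipeline inputs
#'
#' Reads the expression matrix, cell table, regulon GMT and driver table
#' (plus an optional bulk cohort), deduplicates identifiers, aligns the cell
#' table to the matrix rows, and drops regulon targets absent from the
#' matrix with a logged count.
#'
#' @param expression MTX directory or dense TSV path.
#' @param cells cell-table TSV path (columns cell, sample, tissue, state,
#'   emb1, emb2).
#' @param regulons GMT path.
#' @param drivers driver TSV path (gene, fate, fdr), optional.
#' @param cohort_expression,cohort_survival optional bulk cohort TSV paths.
#' @return list (expression, cells, regulons, drivers, cohort).
#' @export
load_inputs <- function(expression, cells, regulons, drivers = NULL,
                        cohort_expression = NULL, cohort_survival = NULL) {
  expr <- read_expression(expression)
  if (anyDuplicated(rownames(expr)))
    stop("validation error: duplicated cell ids in expression matrix",
         call. = FALSE)
  expr <- expr[, !duplicated(colnames(expr)), drop = FALSE]

  if (!file.exists(cells))
    stop(sprintf("I/O error: file not found: %s", cells), call. = FALSE)
  cell_df <- utils::read.delim(cells, stringsAsFactors = FALSE)
  if (anyDuplicated(cell_df$cell))
    stop("validation error: duplicated cell ids in cell table", call. = FALSE)
  missing <- setdiff(cell_df$cell, rownames(expr))
  if (length(missing))
    stop(sprintf("validation error: cell id '%s' not in expression matrix",
                 missing[1]), call. = FALSE)
  expr <- expr[cell_df$cell, , drop = FALSE]

  regs <- read_gmt(regulons)
  n_dropped <- 0L
  regs <- lapply(regs, function(tg) {
    keep <- tg %in% colnames(expr)
    n_dropped <<- n_dropped + sum(!keep)
    tg[keep]
  })
  if (n_dropped > 0)
    warning(sprintf("%d regulon target(s) absent from the matrix were dropped",
                    n_dropped))
  if (all(lengths(regs) == 0L))
    stop("validation error: zero overlapping genes between regulons and matrix",
         call. = FALSE)

  drv <- if (!is.null(drivers)) utils::read.delim(drivers,
                                                  stringsAsFactors = FALSE)
  cohort <- NULL
  if (!is.null(cohort_expression) && !is.null(cohort_survival)) {
    ce <- utils::read.delim(cohort_expression, row.names = 1,
                            check.names = FALSE)
    cs <- utils::read.delim(cohort_survival, stringsAsFactors = FALSE)
    cohort <- list(expression = as.matrix(ce), survival = cs)
  }
  list(expression = expr, cells = cell_df, regulons = regs,
       drivers = drv, cohort = cohort)
}

#' Export the results bundle as plain-text artifacts
#'
#' Writes the cell table with QC scores, RSS and CSI matrices, module
#' assignments, state-regulon calls, per-fate networks as GraphML plus
#' edge-list TSV, node-metric tables with CoreScore and core flags, and the
#' signature/survival summaries. All floats are written at 6 significant
#' digits; re-exporting the same bundle is byte-identical.
#'
#' @param results bundle from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
export_results <- function(results, outdir) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop(sprintf("I/O error: cannot create output directory %s", outdir),
         call. = FALSE)
  files <- character(0)
  w <- function(obj, name, matrix = FALSE) {
    p <- file.path(outdir, name)
    if (matrix) write_matrix_tsv6(obj, p) else write_tsv6(obj, p)
    files <<- c(files, p)
  }
  if (!is.null(results$cells)) w(results$cells, "cells_qc.tsv")
  if (!is.null(results$rss)) w(results$rss, "rss_matrix.tsv", matrix = TRUE)
  if (!is.null(results$csi)) w(results$csi, "csi_matrix.tsv", matrix = TRUE)
  if (!is.null(results$modules))
    w(data.frame(regulon = names(results$modules),
                 module = sprintf("Module %d", as.integer(results$modules))),
      "regulon_modules.tsv")
  if (!is.null(results$state_calls)) w(results$state_calls,
                                       "state_regulons.tsv")
  if (!is.null(results$networks)) {
    for (f in names(results$networks)) {
      nw <- results$networks[[f]]
      gp <- file.path(outdir, sprintf("network_%s.graphml", f))
      igraph::write_graph(nw$graph, gp, format = "graphml")
      files <- c(files, gp)
      el <- if (igraph::ecount(nw$graph) > 0)
        as.data.frame(igraph::as_edgelist(nw$graph),
                      col.names = c("from", "to"))
      else data.frame(from = character(), to = character())
      names(el) <- c("from", "to")
      w(el, sprintf("network_%s_edges.tsv", f))
      w(nw$nodes, sprintf("network_%s_nodes.tsv", f))
    }
  }
  if (!is.null(results$signature))
    w(data.frame(patient = names(results$signature$scores),
                 score = as.numeric(results$signature$scores),
                 quartile = as.character(results$signature$quartiles)),
      "signature_scores.tsv")
  if (!is.null(results$survival_summary))
    w(results$survival_summary, "survival_summary.tsv")
  invisible(files)
}
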