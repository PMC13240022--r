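#' Exact k-nearest-neighbour graph in an embedding
#'
#' Euclidean k nearest neighbours per cell (self excluded), computed exactly.
#' Ties at the k-th distance are broken by cell index so the graph is
#' deterministic. Distances are computed blockwise so moderately large
#' embeddings (10^5 cells) stay within memory.
#'
#' @param embedding cells x d numeric coordinate matrix.
#' @param k neighbours per cell; must be < number of cells.
#' @param block rows per distance block.
#' @return a `neighbour_graph`: list with `index` (cells x k integer matrix of
#'   neighbour indices) and `dist` (matching distances).
#' @export
knn_neighbors <- function(embedding, k = 30L, block = 2000L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  k <- check_count(k, "k")
  if (n <= k)
    stop("validation error: need more cells than k neighbours", call. = FALSE)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(embedding^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared distances from this block to all cells
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(embedding[rows, , drop = FALSE],
                                                    embedding)
    d2[cbind(seq_along(rows), rows)] <- Inf      # exclude self
    d2[d2 < 0] <- 0
    for (j in seq_along(rows)) {
      o <- order(d2[j, ], seq_len(n))[seq_len(k)] # index tie-break
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(d2[j, o])
    }
  }
  structure(list(index = idx, dist = dst, k = k), class = "neighbour_graph")
}

.neighbour_label_mismatch <- function(graph, labels, what) {
  stopifnot(inherits(graph, "neighbour_graph"))
  labels <- as.character(labels)
  if (length(labels) != nrow(graph$index) || anyNA(labels))
    stop(sprintf("validation error: %s labels must cover every cell", what),
         call. = FALSE)
  neigh <- matrix(labels[graph$index], nrow = nrow(graph$index))
  rowMeans(neigh != labels)
}

#' Per-cell batch mixing score
#'
#' Fraction of a cell's k nearest neighbours originating from a different
#' sample. Higher values indicate better inter-sample mixing; for random
#' labels over S equally sized samples the expectation is (S-1)/S.
#'
#' @param graph a [knn_neighbors()] result.
#' @param sample_labels per-cell sample (batch) labels.
#' @return numeric vector in \[0, 1\], one score per cell.
#' @export
batch_mixing_score <- function(graph, sample_labels) {
  .neighbour_label_mismatch(graph, sample_labels, "sample")
}

#' Per-cell tissue-type separation score
#'
#' Fraction of a cell's k nearest neighbours belonging to a different tissue
#' type. Lower values indicate tighter within-tissue clustering; a cell deep
#' inside a pure-tissue blob scores 0.
#'
#' @param graph a [knn_neighbors()] result.
#' @param tissue_labels per-cell tissue labels.
#' @return numeric vector in \[0, 1\], one score per cell.
#' @export
tissue_separation_score <- function(graph, tissue_labels) {
  .neighbour_label_mismatch(graph, tissue_labels, "tissue")
}
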