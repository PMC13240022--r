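#' Rank genes within each cell by decreasing expression
#'
#' Builds the per-cell gene ranking used by the recovery-curve activity score.
#' Ties are broken by a single seeded random permutation of the genes, shared
#' across cells, so that cells with identical expression vectors receive
#' identical rankings and the whole ranking is reproducible from the seed.
#'
#' @param expr cells x genes numeric matrix, non-negative.
#' @param seed integer seed for the tie-breaking permutation.
#' @return a `gene_ranking` object: list with `positions` (cells x genes
#'   integer matrix; `positions[c, g]` is the rank of gene `g` in cell `c`,
#'   1 = highest expression), `tiebreak` (the permutation used), `genes`,
#'   and `seed`.
#' @export
rank_genes_per_cell <- function(expr, seed = 1L) {
  if (is.null(dim(expr)) || ncol(expr) == 0L)
    stop("validation error: expression matrix has zero genes", call. = FALSE)
  if (any(expr < 0))
    stop("validation error: expression must be non-negative", call. = FALSE)
  n_genes <- ncol(expr)
  tiebreak <- with_seed(seed, sample.int(n_genes))
  pos <- matrix(0L, nrow = nrow(expr), ncol = n_genes,
                dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    o <- order(-expr[i, ], tiebreak)
    pos[i, o] <- seq_len(n_genes)
  }
  structure(list(positions = pos, tiebreak = tiebreak,
                 genes = colnames(expr), seed = as.integer(seed)),
            class = "gene_ranking")
}

# maximum achievable area for a k-gene set within the top T ranks
.auc_max_area <- function(k, T) {
  m <- min(k, T)
  sum(T - seq_len(m) + 1)
}

#' Recovery-curve AUC score of one gene set across cells
#'
#' With `T = floor(top_fraction * n_genes)`, the recovery curve of a gene set
#' in a cell counts, at each rank 1..T, how many set genes rank at or above
#' it. The score is the area under this step curve divided by the maximum
#' achievable area (all set genes packed at the very top), giving a value in
#' \[0, 1\] that depends only on expression ranks.
#'
#' @param ranking a [rank_genes_per_cell()] result.
#' @param gene_set character vector of gene names.
#' @param top_fraction fraction of top-ranked genes forming the evaluation
#'   window, in (0, 1].
#' @return numeric vector of per-cell scores, or all-`NA` with a warning when
#'   no set gene is present in the ranking.
#' @export
aucell_score <- function(ranking, gene_set, top_fraction = 0.05) {
  stopifnot(inherits(ranking, "gene_ranking"))
  check_fraction(top_fraction, "top_fraction")
  if (top_fraction <= 0) stop_param("top_fraction", "must be positive")
  genes <- ranking$genes
  set <- intersect(unique(gene_set), genes)
  n_cells <- nrow(ranking$positions)
  out <- rep(NA_real_, n_cells)
  names(out) <- rownames(ranking$positions)
  if (length(set) == 0L) {
    warning("gene set has no genes in the ranking; scored as missing")
    return(out)
  }
  T <- floor(top_fraction * length(genes))
  if (T < 1L) stop_param("top_fraction", "window is empty for this gene count")
  p <- ranking$positions[, set, drop = FALSE]
  # area under the cumulative-hit step curve: each hit at rank r <= T
  # contributes (T - r + 1) unit columns
  area <- rowSums(pmax(T - p + 1L, 0L))
  out[] <- area / .auc_max_area(length(set), T)
  out
}

#' Score a collection of gene sets (regulons or differentiation programs)
#'
#' Column-wise application of [aucell_score()] over a named list of gene
#' sets, yielding the cells x sets activity matrix. Sets with no gene in the
#' matrix produce an all-missing column with a warning.
#'
#' @param ranking a [rank_genes_per_cell()] result.
#' @param sets named list of gene-name vectors.
#' @param top_fraction see [aucell_score()].
#' @return cells x sets numeric matrix of activity scores.
#' @export
score_gene_sets <- function(ranking, sets, top_fraction = 0.05) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("validation error: gene sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("validation error: duplicate gene-set names", call. = FALSE)
  out <- vapply(sets, function(s) aucell_score(ranking, s, top_fraction),
                numeric(nrow(ranking$positions)))
  rownames(out) <- rownames(ranking$positions)
  out
}

#' Score differentiation programs, restricted to fate-assigned cells
#'
#' Scores each program with the recovery-curve AUC and, when the cell table
#' marks unassigned cells (missing/`NA`/"unassigned" state), restricts the
#' returned matrix to cells confidently assigned to a terminal state.
#'
#' @param expr cells x genes matrix.
#' @param programs named list of program gene sets (e.g. HB1, HB2, FH1,
#'   FH2, AH along the hepatocyte maturation axis).
#' @param cells optional cell table with `cell` and `state` columns.
#' @param top_fraction see [aucell_score()].
#' @param seed tie-break seed for the ranking.
#' @return cells x programs activity matrix (assigned cells only when a cell
#'   table is given).
#' @export
score_programs <- function(expr, programs, cells = NULL,
                           top_fraction = 0.05, seed = 1L) {
  ranking <- rank_genes_per_cell(expr, seed = seed)
  act <- score_gene_sets(ranking, programs, top_fraction)
  if (!is.null(cells)) {
    keep <- !is.na(cells$state) & cells$state != "" &
      tolower(cells$state) != "unassigned"
    act <- act[cells$cell[keep], , drop = FALSE]
  }
  act
}
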