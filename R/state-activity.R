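#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the combined sample has at most 12 observations
#' and no ties; otherwise the normal approximation with midrank tie
#' correction and continuity correction. Returns the Mann-Whitney U for the
#' first group.
#'
#' @param x,y numeric samples (both non-empty).
#' @param alternative "two.sided", "greater" (x tends larger), or "less".
#' @return list with `statistic` (U) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("validation error: both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  p <- wt$p.value
  # fully tied samples (zero rank variance) carry no evidence either way
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = min(p, 1))
}

#' Per-state mean activity and z-scores
#'
#' Computes the regulons x states mean-activity matrix and a matching
#' z-matrix under one of two standardization conventions. Mode `"states"`
#' z-scores each regulon's k state means against each other (population SD),
#' as in row-wise normalization of a state-mean heatmap; with k states the
#' largest attainable |z| is sqrt(k-1), e.g. sqrt(2) ~ 1.414 for 3 states.
#' Mode `"cellwise"` z-scores the regulon across all cells first and then
#' averages the z within each state, which can exceed that bound. Degenerate
#' (zero-spread) rows yield all-zero z.
#'
#' @param activity cells x regulons activity matrix.
#' @param state_labels per-cell state labels (>= 2 states).
#' @param z_mode "cellwise" (default) or "states".
#' @return list with `mean` and `z` (regulons x states matrices), `states`,
#'   and `z_mode`.
#' @export
state_mean_zscore <- function(activity, state_labels,
                              z_mode = c("cellwise", "states")) {
  z_mode <- match.arg(z_mode)
  state_labels <- as.character(state_labels)
  states <- sort(unique(state_labels))
  if (length(states) < 2L)
    stop("validation error: need at least two states", call. = FALSE)
  grp <- lapply(states, function(s) which(state_labels == s))
  group_means <- function(m) {
    out <- vapply(grp, function(ix) colMeans(m[ix, , drop = FALSE]),
                  numeric(ncol(m)))
    matrix(out, nrow = ncol(m), ncol = length(states),
           dimnames = list(colnames(m), states))
  }
  mu <- group_means(activity)
  z <- if (z_mode == "states") {
    t(apply(mu, 1, zscore_pop))
  } else {
    zc <- apply(activity, 2, zscore_pop)         # cells x regulons
    group_means(matrix(zc, nrow = nrow(activity),
                       dimnames = dimnames(activity)))
  }
  dimnames(z) <- dimnames(mu)
  list(mean = mu, z = z, states = states, z_mode = z_mode)
}

#' Select state-specific high-activity regulons
#'
#' A (regulon, state) pair is selected when the regulon's z under the chosen
#' mode exceeds `z_threshold` in that state and a one-sided (greater)
#' rank-sum test of the regulon's per-cell activity in the state versus all
#' other cells gives p < `alpha`. A regulon can be selected in at most one
#' state; the state with the largest z wins. With mode `"states"` and k
#' states the z-values cannot exceed sqrt(k-1), so a threshold at or above
#' that bound provably selects nothing and a warning is emitted.
#'
#' @param activity cells x regulons activity matrix.
#' @param state_labels per-cell state labels.
#' @param z_threshold minimum z for selection.
#' @param alpha rank-sum significance level.
#' @param z_mode see [state_mean_zscore()].
#' @param adjust_p apply Benjamini-Hochberg across all (regulon, state) tests.
#' @return data.frame (regulon, state, z, p, selected), one row per pair.
#' @export
identify_state_regulons <- function(activity, state_labels,
                                    z_threshold = 1.5, alpha = 0.05,
                                    z_mode = c("cellwise", "states"),
                                    adjust_p = FALSE) {
  z_mode <- match.arg(z_mode)
  smz <- state_mean_zscore(activity, state_labels, z_mode)
  states <- smz$states
  k <- length(states)
  if (z_mode == "states" && z_threshold >= sqrt(k - 1) - 1e-12)
    warning(sprintf(paste0(
      "z_threshold %.3g is unattainable in 'states' mode with %d states ",
      "(max |z| = sqrt(%d) = %.4g); no regulon can be selected"),
      z_threshold, k, k - 1, sqrt(k - 1)))
  state_labels <- as.character(state_labels)
  pmat <- matrix(NA_real_, ncol(activity), k,
                 dimnames = list(colnames(activity), states))
  for (s in seq_len(k)) {
    inS <- state_labels == states[s]
    for (j in seq_len(ncol(activity)))
      pmat[j, s] <- wilcoxon_rank_sum(activity[inS, j], activity[!inS, j],
                                      alternative = "greater")$p.value
  }
  if (adjust_p) pmat[] <- stats::p.adjust(pmat, method = "BH")
  df <- data.frame(
    regulon = rep(rownames(pmat), times = k),
    state = rep(states, each = nrow(pmat)),
    z = as.vector(smz$z),
    p = as.vector(pmat),
    stringsAsFactors = FALSE
  )
  df$selected <- df$z > z_threshold & df$p < alpha
  # one state per regulon: among selected rows keep the argmax-z state
  if (any(df$selected)) {
    sel <- df[df$selected, ]
    best <- tapply(seq_len(nrow(sel)), sel$regulon, function(ix)
      ix[which.max(sel$z[ix])])
    keep_key <- paste(sel$regulon[unlist(best)], sel$state[unlist(best)])
    df$selected <- df$selected & paste(df$regulon, df$state) %in% keep_key
  }
  df
}

#' Pairwise state comparisons of program activity
#'
#' Two-sided rank-sum tests for every state pair, per program column.
#'
#' @param programs cells x programs activity matrix.
#' @param state_labels per-cell state labels.
#' @return data.frame (program, state1, state2, p); comparisons involving a
#'   state with fewer than 2 cells are skipped with a warning.
#' @export
compare_program_activity <- function(programs, state_labels) {
  state_labels <- as.character(state_labels)
  states <- sort(unique(state_labels))
  pairs <- utils::combn(states, 2)
  rows <- list()
  for (pc in seq_len(ncol(pairs))) {
    s1 <- pairs[1, pc]; s2 <- pairs[2, pc]
    i1 <- state_labels == s1; i2 <- state_labels == s2
    if (sum(i1) < 2L || sum(i2) < 2L) {
      warning(sprintf("comparison %s vs %s skipped: state with < 2 cells",
                      s1, s2))
      next
    }
    for (j in seq_len(ncol(programs))) {
      p <- wilcoxon_rank_sum(programs[i1, j], programs[i2, j],
                             alternative = "two.sided")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        program = colnames(programs)[j] %||% as.character(j),
        state1 = s1, state2 = s2, p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(program = character(), state1 = character(),
                      state2 = character(), p = numeric()))
  do.call(rbind, rows)
}

#' Per-state mean expression and expression prevalence
#'
#' For each requested gene and state, the mean expression and the fraction
#' of that state's cells with expression above zero — the two quantities a
#' dot-plot encodes as colour and dot size.
#'
#' @param expr cells x genes expression matrix.
#' @param genes genes to summarize; unknown genes are dropped with a warning.
#' @param state_labels per-cell state labels.
#' @return data.frame (gene, state, mean_expression, prevalence).
#' @export
state_expression_summary <- function(expr, genes, state_labels) {
  state_labels <- as.character(state_labels)
  known <- genes %in% colnames(expr)
  if (any(!known))
    warning(sprintf("%d unknown gene(s) dropped: %s", sum(!known),
                    paste(utils::head(genes[!known], 5), collapse = ", ")))
  genes <- genes[known]
  states <- sort(unique(state_labels))
  out <- expand.grid(gene = genes, state = states,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_expression <- NA_real_
  out$prevalence <- NA_real_
  for (s in states) {
    ix <- state_labels == s
    sub <- expr[ix, genes, drop = FALSE]
    rr <- out$state == s
    out$mean_expression[rr] <- colMeans(sub)[out$gene[rr]]
    out$prevalence[rr] <- colMeans(sub > 0)[out$gene[rr]]
  }
  out
}
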