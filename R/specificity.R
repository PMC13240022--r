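.shannon_h <- function(p) {
  # base-2 Shannon entropy with the 0*log(0) := 0 convention
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Regulon specificity score for one regulon and one cell state
#'
#' The regulon's activity vector is normalized to a probability distribution
#' over cells, the state is encoded as the uniform indicator distribution
#' over its member cells, and their Jensen-Shannon divergence (base-2 logs,
#' so JSD is in \[0, 1\]) is computed as
#' `JSD = H((P_R + P_C)/2) - (H(P_R) + H(P_C))/2`. The score is `1 - JSD`
#' by default (`sqrt_jsd = TRUE` gives the `1 - sqrt(JSD)` variant common in
#' the specificity-score literature). A score of 1 means the activity mass
#' sits exactly on the state's cells; 0 means disjoint support.
#'
#' @param activity per-cell activity values of one regulon (non-negative).
#' @param state_membership logical vector marking the state's cells.
#' @param sqrt_jsd use `1 - sqrt(JSD)` instead of `1 - JSD`.
#' @return a single score in \[0, 1\].
#' @export
compute_rss <- function(activity, state_membership, sqrt_jsd = FALSE) {
  if (length(activity) != length(state_membership))
    stop("validation error: activity and membership lengths differ",
         call. = FALSE)
  if (any(activity < 0, na.rm = TRUE) || anyNA(activity))
    stop("validation error: activity must be non-negative and complete",
         call. = FALSE)
  if (sum(activity) == 0)
    stop("undefined distribution: all-zero activity", call. = FALSE)
  if (!any(state_membership))
    stop("validation error: empty state", call. = FALSE)
  p_r <- activity / sum(activity)
  p_c <- as.numeric(state_membership) / sum(state_membership)
  m <- (p_r + p_c) / 2
  jsd <- .shannon_h(m) - (.shannon_h(p_r) + .shannon_h(p_c)) / 2
  jsd <- min(max(jsd, 0), 1)                   # guard rounding at the ends
  if (sqrt_jsd) 1 - sqrt(jsd) else 1 - jsd
}

#' Regulon specificity scores for every regulon and state
#'
#' @param activity cells x regulons activity matrix.
#' @param state_labels per-cell state labels.
#' @param sqrt_jsd see [compute_rss()].
#' @return regulons x states matrix of scores; a regulon whose column cannot
#'   be scored (all-zero activity) yields `NA`s with a warning.
#' @export
compute_rss_matrix <- function(activity, state_labels, sqrt_jsd = FALSE) {
  state_labels <- as.character(state_labels)
  if (length(state_labels) != nrow(activity))
    stop("validation error: one state label per cell required", call. = FALSE)
  states <- sort(unique(state_labels))
  out <- matrix(NA_real_, ncol(activity), length(states),
                dimnames = list(colnames(activity), states))
  for (j in seq_len(ncol(activity))) {
    a <- activity[, j]
    if (anyNA(a) || sum(a) == 0) {
      warning(sprintf("regulon '%s' could not be scored; set to NA",
                      colnames(activity)[j] %||% j))
      next
    }
    for (s in seq_along(states))
      out[j, s] <- compute_rss(a, state_labels == states[s], sqrt_jsd)
  }
  out
}

#' Connection specificity index matrix
#'
#' For each regulon pair (A, B), the Pearson correlation of their per-cell
#' activity profiles is compared with the correlations of A and of B with
#' every other regulon i: the index is the fraction of the N-2 other regulons
#' for which `PCC(A,i) < PCC(A,B)` or `PCC(B,i) < PCC(A,B)` (strict
#' inequalities). High values mean the pair's co-activity is specific to the
#' pair rather than shared network-wide. The diagonal is set to 1.
#'
#' @param activity cells x regulons activity matrix (>= 3 regulons; every
#'   column must vary).
#' @return symmetric regulons x regulons matrix with values in \[0, 1\].
#' @export
compute_csi <- function(activity) {
  n <- ncol(activity)
  if (n < 3L)
    stop("validation error: CSI needs at least 3 regulons", call. = FALSE)
  v <- apply(activity, 2, stats::var)
  if (any(v == 0 | is.na(v))) {
    bad <- colnames(activity)[which(v == 0 | is.na(v))[1]]
    stop(sprintf("validation error: zero-variance activity for regulon '%s'",
                 bad %||% "<unnamed>"), call. = FALSE)
  }
  pcc <- stats::cor(activity)
  csi <- matrix(1, n, n, dimnames = dimnames(pcc))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      others <- setdiff(seq_len(n), c(a, b))
      hit <- pcc[a, others] < pcc[a, b] | pcc[b, others] < pcc[a, b]
      csi[a, b] <- csi[b, a] <- sum(hit) / (n - 2L)
    }
  }
  csi
}

#' Cluster regulons into modules from the CSI matrix
#'
#' Average-linkage agglomerative clustering on the distance `1 - CSI`, cut
#' into `n_modules` groups. Modules are relabelled `Module 1..k` by
#' decreasing size (ties by first appearance), so labels are deterministic.
#'
#' @param csi symmetric CSI matrix.
#' @param n_modules number of modules to cut.
#' @return named integer vector of module numbers (1 = largest), one per
#'   regulon, with a `labels` attribute of the "Module k" strings.
#' @export
cluster_modules <- function(csi, n_modules = 7L) {
  n <- nrow(csi)
  n_modules <- check_count(n_modules, "n_modules")
  if (n_modules > n)
    stop("validation error: n_modules exceeds the number of regulons",
         call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - csi), method = "average")
  raw <- stats::cutree(hc, k = n_modules)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- integer(n_modules)
  remap[as.integer(names(sizes))[ord]] <- seq_len(n_modules)
  out <- remap[raw]
  names(out) <- rownames(csi)
  attr(out, "labels") <- sprintf("Module %d", out)
  out
}
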