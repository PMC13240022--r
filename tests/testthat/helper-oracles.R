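# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths: everything is recomputed from first principles.

# step-curve AUC by explicit enumeration of the cumulative-hit curve
oracle_aucell <- function(ranks_of_set, n_genes, top_fraction) {
  T <- floor(top_fraction * n_genes)
  hits <- vapply(seq_len(T), function(x) sum(ranks_of_set <= x), numeric(1))
  area <- sum(hits)
  k <- length(ranks_of_set)
  max_area <- sum(vapply(seq_len(T), function(x) min(x, k), numeric(1)))
  area / max_area
}

# CSI by a literal triple loop over the printed definition
oracle_csi <- function(activity) {
  n <- ncol(activity)
  pcc <- stats::cor(activity)
  out <- matrix(1, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    cnt <- 0L
    for (i in seq_len(n)) {
      if (i == a || i == b) next
      if (pcc[a, i] < pcc[a, b] || pcc[b, i] < pcc[a, b]) cnt <- cnt + 1L
    }
    out[a, b] <- cnt / (n - 2)
  }
  dimnames(out) <- dimnames(pcc)
  out
}

# all-pairs exact kNN with index tie-break
oracle_knn <- function(emb, k) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  t(vapply(seq_len(n), function(i) order(d[i, ], seq_len(n))[seq_len(k)],
           integer(k)))
}

# exhaustive betweenness / closeness on a small directed edge list:
# every simple path between every ordered node pair is enumerated by DFS,
# the shortest ones kept, and pass-through fractions accumulated
oracle_paths <- function(edges, nodes) {
  adj <- lapply(nodes, function(v) unique(edges$to[edges$from == v]))
  names(adj) <- nodes
  n <- length(nodes)
  all_simple_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
      for (v in setdiff(adj[[u]], path)) walk(c(path, v))
    }
    walk(s)
    out
  }
  btw <- stats::setNames(rep(0, n), nodes)
  dmat <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(dmat) <- 0
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_simple_paths(s, t)
    if (length(paths) == 0) next
    lens <- lengths(paths) - 1L
    dmat[s, t] <- min(lens)
    shortest <- paths[lens == min(lens)]
    for (v in setdiff(nodes, c(s, t))) {
      through <- vapply(shortest, function(p) v %in% p, logical(1))
      btw[v] <- btw[v] + mean(through)
    }
  }
  closeness <- vapply(nodes, function(v) {
    d <- dmat[setdiff(nodes, v), v]      # incoming geodesics
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d[reach]))
  }, numeric(1))
  list(betweenness = if (n > 2) btw / ((n - 1) * (n - 2)) else btw * 0,
       closeness = closeness, dist = dmat)
}

# exact rank-sum p by enumerating every assignment of ranks to group x
oracle_ranksum <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  switch(alternative,
    greater = mean(u_all >= u_obs),
    less = mean(u_all <= u_obs),
    two.sided = min(1, 2 * min(mean(u_all >= u_obs), mean(u_all <= u_obs))))
}

# small default design used across pipeline-level tests
small_design <- function(seed = 42L, ...) {
  synthetic_design(n_cells = 300L, n_genes = 400L, n_regulons = 20L,
                   n_state_specific_per_state = 3L, seed = seed, ...)
}
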