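#' Intersect state-regulon targets with fate-driving genes
#'
#' For each fate, the union of the targets of that fate's selected regulons
#' is intersected with the genes whose fate-driver FDR falls below the
#' threshold; a selected TF itself joins the set when it appears as a
#' sub-threshold driver of the fate.
#'
#' @param state_calls output of [identify_state_regulons()].
#' @param regulons named list of regulon target sets (names are TFs).
#' @param drivers data.frame (gene, fate, fdr).
#' @param fdr_threshold driver FDR cut-off.
#' @return named list: fate -> character vector of core genes. Fates with no
#'   selected regulons give an empty set with a warning.
#' @export
intersect_core_genes <- function(state_calls, regulons, drivers,
                                 fdr_threshold = 0.05) {
  stopifnot(all(c("gene", "fate", "fdr") %in% names(drivers)))
  fates <- sort(unique(drivers$fate))
  out <- stats::setNames(vector("list", length(fates)), fates)
  sel <- state_calls[state_calls$selected, , drop = FALSE]
  for (f in fates) {
    tfs <- sel$regulon[sel$state == f]
    if (length(tfs) == 0L) {
      warning(sprintf("fate '%s' has no selected regulons; empty core set", f))
      out[[f]] <- character(0)
      next
    }
    targets <- unique(c(unlist(regulons[tfs], use.names = FALSE), tfs))
    hits <- drivers$gene[drivers$fate == f & drivers$fdr < fdr_threshold]
    out[[f]] <- sort(intersect(targets, hits))
  }
  out
}

#' Build a fate-specific TF-to-target regulatory network
#'
#' Edges run from each of the fate's selected regulon TFs to the regulon
#' targets surviving the core-gene intersection (TF-TF edges arise when a TF
#' is another TF's target and in the core set). Duplicate edges from
#' overlapping regulons are collapsed; TFs with no surviving target are
#' dropped. Nodes carry a `kind` attribute ("TF" for edge sources, "target"
#' otherwise) and TFs carry their regulon `module` when given.
#'
#' @param core_genes core gene set for the fate.
#' @param tfs the fate's selected regulon TFs.
#' @param regulons named list of regulon target sets.
#' @param modules optional named integer vector of regulon module numbers.
#' @return a directed [igraph::igraph] (possibly empty).
#' @export
build_network <- function(core_genes, tfs, regulons, modules = NULL) {
  edges <- list()
  for (tf in tfs) {
    tgt <- intersect(regulons[[tf]], core_genes)
    tgt <- setdiff(tgt, tf)                       # no self-loops
    if (length(tgt))
      edges[[tf]] <- data.frame(from = tf, to = tgt, stringsAsFactors = FALSE)
  }
  if (length(edges) == 0L)
    return(igraph::make_empty_graph(directed = TRUE))
  el <- unique(do.call(rbind, edges))
  g <- igraph::graph_from_data_frame(el, directed = TRUE)
  kind <- ifelse(igraph::V(g)$name %in% el$from, "TF", "target")
  g <- igraph::set_vertex_attr(g, "kind", value = kind)
  mod <- rep(NA_integer_, igraph::vcount(g))
  if (!is.null(modules)) {
    hit <- match(igraph::V(g)$name, names(modules))
    mod[!is.na(hit)] <- unname(modules[hit[!is.na(hit)]])
  }
  igraph::set_vertex_attr(g, "module", value = mod)
}

#' Node topology metrics of a regulatory network
#'
#' In- and out-degree on the directed graph; betweenness by exact
#' shortest-path counting on the directed graph, normalized by
#' (n-1)(n-2); closeness over incoming shortest paths with the
#' Wasserman-Faust scaling for disconnected graphs
#' (`(r-1)/(n-1) * (r-1)/sum(d)` over the r-1 nodes that reach the node;
#' 0 when nothing does); local clustering coefficient on the undirected
#' projection (0 for degree < 2).
#'
#' @param g a directed [igraph::igraph].
#' @return data.frame (node, kind, in_degree, out_degree, betweenness,
#'   closeness, clustering); all metrics 0 for a single-node graph.
#' @export
topology_metrics <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L)
    return(data.frame(node = character(), kind = character(),
                      in_degree = numeric(), out_degree = numeric(),
                      betweenness = numeric(), closeness = numeric(),
                      clustering = numeric()))
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))
  kind <- igraph::vertex_attr(g, "kind") %||% rep(NA_character_, n)
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  btw <- if (n > 2)
    igraph::betweenness(g, directed = TRUE, normalized = FALSE) /
      ((n - 1) * (n - 2))
  else rep(0, n)
  # closeness: incoming geodesics, Wasserman-Faust disconnected scaling
  dm <- igraph::distances(g, mode = "in")         # dm[v, u] = d(u -> v)
  clo <- vapply(seq_len(n), function(v) {
    d <- dm[v, -v]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0L || n == 1L) return(0)
    (r / (n - 1)) * (r / sum(d[reach]))
  }, numeric(1))
  und <- igraph::as_undirected(g, mode = "collapse")
  cc <- igraph::transitivity(und, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  data.frame(node = nm, kind = kind,
             in_degree = as.numeric(indeg), out_degree = as.numeric(outdeg),
             betweenness = as.numeric(btw), closeness = clo,
             clustering = as.numeric(cc),
             stringsAsFactors = FALSE)
}

#' Composite CoreScore and core-node flags
#'
#' Each topology metric is z-scored across nodes (population SD; a metric
#' with zero spread contributes zeros) and the CoreScore is their unweighted
#' mean, so no single topological aspect dominates. The top
#' `ceil(core_fraction * n)` nodes by CoreScore are flagged as core
#' regulatory nodes, ties broken lexicographically by node name.
#'
#' @param metrics a [topology_metrics()] table.
#' @param core_fraction fraction of nodes flagged as core.
#' @param degree_mode "in_out" uses in- and out-degree as separate metrics
#'   (five in total); "total" collapses them into one total degree (four).
#' @return the input with `core_score` and `core` columns appended,
#'   ordered by decreasing CoreScore.
#' @export
core_score <- function(metrics, core_fraction = 0.30,
                       degree_mode = c("in_out", "total")) {
  degree_mode <- match.arg(degree_mode)
  n <- nrow(metrics)
  if (n == 0L) {
    metrics$core_score <- numeric(0); metrics$core <- logical(0)
    return(metrics)
  }
  check_fraction(core_fraction, "core_fraction")
  cols <- if (degree_mode == "in_out") {
    list(metrics$in_degree, metrics$out_degree, metrics$betweenness,
         metrics$closeness, metrics$clustering)
  } else {
    list(metrics$in_degree + metrics$out_degree, metrics$betweenness,
         metrics$closeness, metrics$clustering)
  }
  zs <- vapply(cols, zscore_pop, numeric(n))
  score <- if (n == 1L) 0 else rowMeans(zs)
  if (all(score == 0) && n > 1L)
    warning("degenerate CoreScore: all nodes have identical metrics")
  ord <- order(-score, metrics$node)
  n_core <- ceiling(core_fraction * n)
  core <- rep(FALSE, n)
  core[ord[seq_len(n_core)]] <- TRUE
  out <- metrics
  out$core_score <- score
  out$core <- core
  out[ord, , drop = FALSE]
}

#' Assemble the fate network with metrics, CoreScore and module inheritance
#'
#' Convenience wrapper: builds the network, computes topology metrics and
#' CoreScores, flags core nodes, and lets each target gene inherit the
#' module of its highest-CoreScore regulating TF.
#'
#' @inheritParams build_network
#' @inheritParams core_score
#' @return list with `graph` (annotated igraph) and `nodes` (metric table
#'   with core_score, core, module).
#' @export
fate_network <- function(core_genes, tfs, regulons, modules = NULL,
                         core_fraction = 0.30,
                         degree_mode = c("in_out", "total")) {
  g <- build_network(core_genes, tfs, regulons, modules)
  met <- topology_metrics(g)
  met <- core_score(met, core_fraction, degree_mode)
  mod <- igraph::vertex_attr(g, "module") %||% rep(NA_integer_, nrow(met))
  names(mod) <- igraph::V(g)$name
  score <- stats::setNames(met$core_score, met$node)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    for (v in unique(el[, 2])) {
      if (!is.na(mod[v])) next                   # TFs keep their own module
      regs <- el[el[, 2] == v, 1]
      best <- regs[which.max(score[regs])]
      mod[v] <- mod[best]
    }
  }
  met$module <- unname(mod[met$node])
  g <- igraph::set_vertex_attr(g, "module", value = unname(mod[igraph::V(g)$name]))
  g <- igraph::set_vertex_attr(g, "core_score",
                               value = unname(score[igraph::V(g)$name]))
  g <- igraph::set_vertex_attr(g, "core",
    value = unname(stats::setNames(met$core, met$node)[igraph::V(g)$name]))
  list(graph = g, nodes = met)
}
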