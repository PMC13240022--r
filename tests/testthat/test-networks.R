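make_calls <- function(tfs, states) {
  data.frame(regulon = tfs, state = states, z = 2, p = 1e-4, selected = TRUE,
             stringsAsFactors = FALSE)
}

test_that("core-gene intersection matches a hand-enumerable fixture", {
  regs <- list(TF1 = c("a", "b", "c", "d", "e"),
               TF2 = c("d", "e", "f", "g", "h"))
  drivers <- data.frame(
    gene = c("a", "d", "f", "TF1", "b", "z"),
    fate = "fate0",
    fdr = c(0.01, 0.02, 0.03, 0.04, 0.5, 0.01))
  calls <- make_calls(c("TF1", "TF2"), c("fate0", "fate0"))
  core <- intersect_core_genes(calls, regs, drivers, 0.05)
  # by hand: targets {a..h} + TFs; drivers < 0.05 are {a, d, f, TF1, z};
  # z is not a target, b fails the FDR cut
  expect_equal(core$fate0, c("TF1", "a", "d", "f"))
  # fdr_threshold = 0 -> empty
  expect_equal(intersect_core_genes(calls, regs, drivers, 0)$fate0,
               character(0))
  # fate with no selected regulons warns and yields empty
  drivers2 <- rbind(drivers, data.frame(gene = "a", fate = "fate1", fdr = 0.01))
  expect_warning(core2 <- intersect_core_genes(calls, regs, drivers2, 0.05),
                 "fate1")
  expect_equal(core2$fate1, character(0))
})

test_that("network construction gives stars, deduplication and empty graphs", {
  regs <- list(TF1 = c("a", "b", "c"), TF2 = c("b", "c", "d"))
  g <- build_network(c("a", "b", "c"), "TF1", regs)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(table(igraph::V(g)$kind)[["TF"]], 1L)
  expect_equal(table(igraph::V(g)$kind)[["target"]], 3L)
  # overlapping regulons deduplicate to distinct (TF, target) pairs
  g2 <- build_network(c("a", "b", "c", "d"), c("TF1", "TF2"), regs)
  expect_equal(igraph::ecount(g2), 6L)
  # empty core set -> valid empty graph
  g0 <- build_network(character(0), "TF1", regs)
  expect_equal(igraph::vcount(g0), 0L)
  # a TF appearing in another regulon's targets gives a TF-TF edge
  regs3 <- list(TF1 = c("TF2", "a"), TF2 = c("b"))
  g3 <- build_network(c("TF2", "a", "b"), c("TF1", "TF2"), regs3)
  el <- igraph::as_edgelist(g3)
  expect_true(any(el[, 1] == "TF1" & el[, 2] == "TF2"))
})

test_that("topology metrics match closed forms on canonical graphs", {
  # directed star: hub out-degree 9, betweenness 0, leaves in-degree 1
  regs <- list(H = paste0("t", 1:9))
  g <- build_network(paste0("t", 1:9), "H", regs)
  m <- topology_metrics(g)
  hub <- m[m$node == "H", ]
  expect_equal(hub$out_degree, 9)
  expect_equal(hub$betweenness, 0)
  expect_true(all(m$in_degree[m$node != "H"] == 1))
  # path A -> B -> C: B carries the single through-path, normalized by 2
  gp <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C")))
  mp <- topology_metrics(gp)
  expect_equal(mp$betweenness[mp$node == "B"], 0.5)
  # triangle: undirected clustering coefficient 1 everywhere
  gt <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")))
  expect_equal(topology_metrics(gt)$clustering, rep(1, 3))
  # single node: all metrics zero
  g1 <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices("X")
  m1 <- topology_metrics(g1)
  expect_true(all(m1[, c("in_degree", "out_degree", "betweenness",
                         "closeness", "clustering")] == 0))
})

test_that("betweenness and closeness match exhaustive path enumeration", {
  set.seed(83)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    nodes <- paste0("v", seq_len(n))
    ne <- sample(2:(n * (n - 1) / 2), 1)
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    edges <- pairs[sample(nrow(pairs), min(ne, nrow(pairs))), ]
    g <- igraph::graph_from_data_frame(edges, vertices = nodes)
    m <- topology_metrics(g)
    o <- oracle_paths(edges, nodes)
    expect_equal(stats::setNames(m$betweenness, m$node), o$betweenness[m$node],
                 tolerance = 1e-12)
    expect_equal(stats::setNames(m$closeness, m$node), o$closeness[m$node],
                 tolerance = 1e-12)
  }
})

test_that("CoreScore ranks dominating nodes first and flags exact core sizes", {
  met <- data.frame(node = paste0("n", 1:10), kind = "target",
                    in_degree = c(9, 1:9 * 0 + 1),
                    out_degree = c(9, rep(1, 9)),
                    betweenness = c(0.9, rep(0.1, 9)),
                    closeness = c(0.9, rep(0.2, 9)),
                    clustering = c(1, rep(0.3, 9)))
  out <- core_score(met, 0.30)
  expect_equal(out$node[1], "n1")       # maximal in every metric
  expect_equal(sum(out$core), ceiling(0.3 * 10))
  # CoreScore is a mean of z-scores: sums to zero across nodes
  expect_equal(sum(out$core_score), 0, tolerance = 1e-12)
  # identical metrics: all-zero scores, lexicographic core set, warning
  met2 <- met; met2[, 3:7] <- 1
  expect_warning(out2 <- core_score(met2, 0.30), "degenerate")
  expect_true(all(out2$core_score == 0))
  expect_equal(sort(out2$node[out2$core]), c("n1", "n10", "n2"))
  # collapsing in/out-degree to total degree is the 4-metric variant
  out4 <- core_score(met, 0.30, degree_mode = "total")
  expect_equal(out4$node[1], "n1")
})

test_that("core-set size is exactly ceil(fraction * n) across sizes", {
  set.seed(97)
  for (n in c(1, 3, 7, 10, 33)) {
    met <- data.frame(node = sprintf("n%02d", 1:n), kind = "target",
                      in_degree = stats::runif(n), out_degree = stats::runif(n),
                      betweenness = stats::runif(n), closeness = stats::runif(n),
                      clustering = stats::runif(n))
    expect_equal(sum(core_score(met, 0.3)$core), ceiling(0.3 * n))
  }
})

test_that("planted hubs land in the top-30% core set and match brute force", {
  recall <- vapply(1:50, function(s) {
    net <- simulate_hub_network(n_nodes = sample(20:60, 1), n_tfs = 8,
                                n_hubs = 2, seed = s)
    g <- igraph::graph_from_data_frame(net$edges)
    out <- core_score(topology_metrics(g), 0.30)
    mean(net$hubs %in% out$node[out$core])
  }, numeric(1))
  expect_gte(mean(recall), 0.9)
  # one seeded network fully cross-checked against the exhaustive oracle
  net <- simulate_hub_network(n_nodes = 8, n_tfs = 3, n_hubs = 2, seed = 1)
  nodes <- unique(c(net$edges$from, net$edges$to))
  g <- igraph::graph_from_data_frame(net$edges, vertices = nodes)
  m <- topology_metrics(g)
  o <- oracle_paths(net$edges, nodes)
  expect_equal(stats::setNames(m$betweenness, m$node), o$betweenness[m$node])
  expect_equal(stats::setNames(m$closeness, m$node), o$closeness[m$node])
})

test_that("assembled fate networks inherit modules and are deterministic", {
  d <- small_design(seed = 37L)
  sc <- generate_single_cell_dataset(d)
  drv <- generate_fate_drivers(sc$truth, sc$regulons, overlap_fraction = 1,
                               seed = 3)
  tfs <- sc$truth$state_specific_regulons$fate2
  calls <- make_calls(tfs, rep("fate2", length(tfs)))
  # only fate2 has selected regulons here; the other fates warn empty
  core <- suppressWarnings(intersect_core_genes(calls, sc$regulons, drv, 0.05))
  mods <- stats::setNames(rep(1:2, length.out = length(tfs)), tfs)
  nw1 <- fate_network(core$fate2, tfs, sc$regulons, modules = mods)
  nw2 <- fate_network(core$fate2, tfs, sc$regulons, modules = mods)
  expect_identical(nw1$nodes, nw2$nodes)
  expect_true(all(!is.na(nw1$nodes$module)))
  # targets carry the module of their best-scoring regulating TF
  el <- igraph::as_edgelist(nw1$graph)
  sco <- stats::setNames(nw1$nodes$core_score, nw1$nodes$node)
  mod <- stats::setNames(nw1$nodes$module, nw1$nodes$node)
  tgt <- setdiff(unique(el[, 2]), tfs)[1]
  regs_of <- el[el[, 2] == tgt, 1]
  expect_equal(mod[[tgt]], mod[[regs_of[which.max(sco[regs_of])]]])
})
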