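make_table <- function(rows) {
  clean_relationships(read_relationships(
    write_rel_csv(c("gene,compound,plant", rows))))
}

test_that("network construction places nodes, edges and orphans", {
  tbl <- make_table(c("G1,C1,P1", "G2,C1,P1"))
  net <- build_network(tbl)
  expect_equal(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 3)
  expect_setequal(igraph::E(net)$layer,
                  c("gene-compound", "gene-compound", "compound-plant"))

  tbl2 <- make_table(c("G1,C1,P1", "G3,,"))
  net2 <- build_network(tbl2)
  expect_true("G3" %in% igraph::V(net2)$name)
  expect_equal(igraph::degree(net2, "G3")[[1]], 0)

  expect_error(build_network(make_table("G1,C1,P1")[0, ]), "empty")
})

test_that("repeated rows collapse to one edge; frequency mode records them", {
  rows <- rep("G1,C1,P1", 5)
  net <- build_network(make_table(rows))  # duplicates removed by cleaning
  expect_equal(igraph::ecount(net), 2)
  # distinct plants keep the gene-compound pair appearing in several rows
  tbl <- make_table(c("G1,C1,P1", "G1,C1,P2", "G1,C1,P3"))
  netf <- build_network(tbl, weight = "frequency")
  e <- igraph::E(netf)[igraph::E(netf)$layer == "gene-compound"]
  expect_equal(e$weight, 3)
  netu <- build_network(tbl)
  expect_true(all(igraph::E(netu)$weight == 1))
})

test_that("every edge's layer tag matches its endpoint types", {
  for (s in 1:10) {
    g <- random_tripartite(seed = s)
    expect_silent(assert_tripartite(g))
  }
  bad <- igraph::make_graph(~ a - b)
  igraph::V(bad)$entity_type <- c("gene", "plant")
  igraph::E(bad)$layer <- "gene-compound"
  expect_error(assert_tripartite(bad), "forbidden edge")
})

test_that("density matches the pair-enumeration oracle on small graphs", {
  expect_equal(net_density(igraph::make_full_graph(4)), 1.0)
  expect_equal(net_density(igraph::make_empty_graph(10, directed = FALSE)), 0)
  expect_error(net_density(igraph::make_empty_graph(1)), "2 nodes")
  for (s in 1:20) {
    g <- random_tripartite(n_gene = sample(3:15, 1), n_comp = sample(2:10, 1),
                           seed = 100 + s)
    n <- igraph::vcount(g)
    pairs <- utils::combn(n, 2)
    connected <- sum(apply(pairs, 2, function(pr)
      igraph::are_adjacent(g, pr[1], pr[2])))
    expect_equal(net_density(g), connected / ncol(pairs))
  }
})

test_that("centrality conventions: star, path, isolate", {
  star <- igraph::make_star(5, mode = "undirected")  # center is vertex 1
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  igraph::V(star)$entity_type <- "gene"
  cent <- node_centralities(star)
  expect_equal(cent$betweenness[cent$node == "c"], 6)  # C(4,2) pairs
  expect_true(all(cent$betweenness[cent$node != "c"] == 0))

  path <- igraph::make_graph(~ A - B, B - C)
  cent2 <- node_centralities(path)
  expect_equal(cent2$closeness[cent2$node == "B"], 1.0)
  expect_equal(cent2$closeness[cent2$node == "A"], 2 / 3)

  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "x"
  cent3 <- node_centralities(iso)
  expect_equal(cent3$degree, 0L)
  expect_equal(cent3$closeness, 0)
})

test_that("betweenness and closeness agree with an all-pairs oracle", {
  for (s in 1:5) {
    g <- random_tripartite(n_gene = 10, n_comp = 6, n_plant = 3,
                           p_gc = 0.3, p_cp = 0.5, seed = 200 + s)
    n <- igraph::vcount(g)
    cent <- node_centralities(g)
    d <- igraph::distances(g)
    # closeness: reachable-fraction convention recomputed longhand
    for (v in seq_len(n)) {
      row <- d[v, -v]
      r <- sum(is.finite(row))
      expected <- if (r == 0) 0 else (r / sum(row[is.finite(row)])) * (r / (n - 1))
      expect_equal(cent$closeness[v], expected)
    }
    # betweenness: shortest-path enumeration oracle
    btw <- numeric(n)
    for (src in seq_len(n - 1)) for (dst in (src + 1):n) {
      if (!is.finite(d[src, dst])) next
      paths <- igraph::all_shortest_paths(g, src, dst)$vpaths
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        btw[as.integer(names(tab))] <-
          btw[as.integer(names(tab))] + as.numeric(tab) / length(paths)
      }
    }
    expect_equal(cent$betweenness, btw, tolerance = 1e-10)
  }
})

test_that("eigenvector centrality lives on the largest component", {
  g <- random_tripartite(seed = 3)
  comp <- igraph::components(g)
  cent <- node_centralities(g)
  big <- which.max(comp$csize)
  outside <- comp$membership != big
  if (any(outside)) expect_true(all(cent$eigenvector[outside] == 0))
  expect_equal(max(cent$eigenvector), 1)
  # agrees with a dense eigendecomposition of the component's adjacency
  idx <- which(comp$membership == big)
  sub <- igraph::induced_subgraph(g, idx)
  A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
  ref <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
  ref <- ref / max(ref)
  ours <- cent$eigenvector[idx][match(igraph::V(sub)$name,
                                      igraph::V(g)$name[idx])]
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("composition percentages recompute from counts and sum to 100", {
  tbl <- generate_relationships(fixture_spec(n_genes = 30, n_compounds = 10,
                                             seed = 2), tempfile())$table
  net <- build_network(tbl)
  topo <- topology_summary(net)
  types <- igraph::V(net)$entity_type
  for (ty in c("gene", "compound", "plant"))
    expect_equal(topo$composition[[ty]],
                 round(100 * sum(types == ty) / length(types), 1))
  expect_lt(abs(sum(topo$composition) - 100), 0.1 + 1e-9)
})

test_that("tripartite layering admits no triangles, so clustering is 0", {
  for (s in 1:5) {
    g <- random_tripartite(seed = 300 + s)
    expect_equal(topology_summary(g)$avg_clustering, 0)
  }
})

test_that("hub compounds count distinct gene targets at the threshold", {
  # 3 of 20 compounds with >= 5 gene targets -> hub fraction 15%
  rows <- character(0)
  for (i in 1:3) rows <- c(rows, sprintf("G%d_%d,HUB%d,P1", i, 1:6, i))
  for (i in 4:20) rows <- c(rows, sprintf("G%d_1,C%d,P1", i, i))
  topo <- topology_summary(build_network(make_table(rows)))
  expect_equal(nrow(topo$hub_compounds), 3)
  expect_equal(topo$hub_fraction, 0.15)
  expect_true(all(topo$hub_compounds$degree >= 5))
})

test_that("community-size power-law fit reports an R-squared", {
  tbl <- generate_relationships(fixture_spec(seed = 11), tempfile())$table
  net <- build_network(tbl)
  part <- louvain_partition(net, seed = 1)
  topo <- topology_summary(net, partition = part)
  expect_true(topo$powerlaw_r2 >= 0 && topo$powerlaw_r2 <= 1)
  expect_true(is.na(topology_summary(net)$powerlaw_r2))
})
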