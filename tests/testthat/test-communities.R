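two_triangles <- function() {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  igraph::V(g)$entity_type <- "gene"
  g
}

test_that("modularity matches hand computations", {
  g <- two_triangles()
  mem <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity_q(g, mem), 0.5)  # 2 * (3/6 - (6/12)^2)
  expect_equal(modularity_q(g, rep(1, 6)), 0)  # single community
  expect_error(modularity_q(igraph::make_empty_graph(3), rep(1, 3)),
               "no edges")
})

test_that("modularity equals the double-sum oracle and igraph on small graphs", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    g <- igraph::sample_gnp(n, 0.5)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- letters[seq_len(n)]
    mem <- sample(1:3, n, replace = TRUE)
    q <- modularity_q(g, mem)
    expect_equal(q, modularity_double_sum(g, mem), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, mem), tolerance = 1e-12)
  }
})

test_that("Louvain finds the optimal split of two triangles, deterministically", {
  g <- two_triangles()
  p1 <- louvain_partition(g, seed = 42)
  expect_equal(p1$n_communities, 2)
  expect_equal(p1$modularity_q, 0.5)
  expect_equal(unname(p1$assignment[c("a", "b", "c")]), rep(1L, 3))
  expect_equal(unname(p1$assignment[c("d", "e", "f")]), rep(2L, 3))
  p2 <- louvain_partition(g, seed = 42)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("degenerate Louvain inputs: single edge, no edges", {
  g <- igraph::make_graph(~ a - b)
  igraph::V(g)$entity_type <- "gene"
  p <- louvain_partition(g, seed = 1)
  expect_equal(p$modularity_q, 0)
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- letters[1:3]
  p0 <- louvain_partition(g0, seed = 1)
  expect_equal(p0$n_communities, 3)
  expect_equal(p0$modularity_q, 0)
})

test_that("Louvain modularity is at least the singleton-partition modularity", {
  for (s in 1:5) {
    g <- random_tripartite(n_gene = 12, n_comp = 6, seed = 400 + s)
    g <- igraph::induced_subgraph(g, igraph::degree(g) > 0)
    if (igraph::ecount(g) == 0) next
    p <- louvain_partition(g, seed = s)
    singleton <- modularity_q(g, seq_len(igraph::vcount(g)))
    expect_gte(p$modularity_q, singleton)
  }
})

test_that("rewiring preserves degrees, types, layers and simplicity", {
  set.seed(99)
  for (s in 1:20) {
    g <- random_tripartite(n_gene = sample(6:12, 1), n_comp = sample(4:8, 1),
                           seed = 500 + s)
    base_deg <- igraph::degree(g)
    for (rep in 1:5) {
      # a sparse draw can leave a layer with < 2 edges: unchanged, warns
      r <- suppressWarnings(rewire_tripartite(g))
      expect_identical(igraph::degree(r)[names(base_deg)], base_deg)
      expect_identical(igraph::V(r)$entity_type, igraph::V(g)$entity_type)
      expect_true(igraph::is_simple(r))
      expect_equal(sort(table(igraph::E(r)$layer)),
                   sort(table(igraph::E(g)$layer)))
      expect_silent(assert_tripartite(r))
    }
  }
})

test_that("a 4-cycle layer swaps to the only alternative labeled graph or itself", {
  # gene-compound 4-cycle: g1-c1, g1-c2, g2-c1, g2-c2 is complete bipartite
  # K22, which has no alternative: swaps must leave it unchanged
  edf <- data.frame(from = c("g1", "g1", "g2", "g2"),
                    to = c("c1", "c2", "c1", "c2"),
                    layer = "gene-compound", weight = 1)
  g <- igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = data.frame(name = c("g1", "g2", "c1", "c2"),
                          entity_type = c("gene", "gene", "compound", "compound")))
  key <- function(x) paste(sort(apply(igraph::ends(x, igraph::E(x)), 1,
                                      function(e) paste(sort(e), collapse = "-"))),
                           collapse = ";")
  set.seed(1)
  for (i in 1:10) expect_identical(key(rewire_tripartite(g)), key(g))

  # path g1-c1, g2-c2 (2 edges, disjoint): the swap g1-c2, g2-c1 is the only
  # other labeled simple graph with the same degrees
  edf2 <- edf[c(1, 4), ]
  g2 <- igraph::graph_from_data_frame(
    edf2, directed = FALSE,
    vertices = data.frame(name = c("g1", "g2", "c1", "c2"),
                          entity_type = c("gene", "gene", "compound", "compound")))
  seen <- character(0)
  set.seed(2)
  for (i in 1:50) seen <- union(seen, key(rewire_tripartite(g2)))
  expect_setequal(seen, c("c1-g1;c2-g2", "c1-g2;c2-g1"))
})

test_that("rewiring with a fixed seed is byte-identical across runs", {
  g <- random_tripartite(seed = 8)
  r1 <- randomize_network(g, 3, seed = 31)
  r2 <- randomize_network(g, 3, seed = 31)
  for (i in 1:3)
    expect_identical(igraph::as_edgelist(r1[[i]]), igraph::as_edgelist(r2[[i]]))
})

test_that("a layer with fewer than 2 edges is left unchanged with a warning", {
  tbl <- clean_relationships(read_relationships(write_rel_csv(
    c("gene,compound,plant", "G1,C1,P1", "G2,C1,P1", "G3,C1,P1"))))
  net <- build_network(tbl)  # compound-plant layer has 1 edge
  set.seed(1)
  expect_warning(r <- rewire_tripartite(net), "compound-plant")
  expect_true(igraph::are_adjacent(r, "C1", "P1"))
})

test_that("empirical p-values use the +1 correction at both extremes", {
  ep <- phytonet:::.empirical_p
  expect_equal(ep(rep(0.1, 1000), 0.9, "upper"), 1 / 1001)
  expect_equal(ep(rep(0.9, 1000), 0.1, "upper"), 1.0)
  expect_equal(ep(rep(0.9, 1000), 0.1, "lower"), 1 / 1001)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(50)
    p <- ep(x, rnorm(1), "upper")
    expect_gte(p, 1 / 51)
    expect_lte(p, 1)
  }
})

test_that("convergence CV follows the trailing-half-window definition", {
  cc <- phytonet:::.convergence_cv
  set.seed(3)
  x <- rnorm(400, mean = 5)
  tab <- cc(x, seq(100, 400, 100))
  expect_equal(tab$cum_mean, cumsum(x)[c(100, 200, 300, 400)] / c(100, 200, 300, 400))
  # checkpoint 400: window (200, 400] = {300, 400}
  expect_equal(tab$cv[4], sd(tab$cum_mean[3:4]) / abs(tab$cum_mean[4]))
  # checkpoint 100: single checkpoint in window -> 0
  expect_equal(tab$cv[1], 0)
})

test_that("null_test rejects tiny ensembles and reports a full trajectory", {
  g <- random_tripartite(seed = 12)
  expect_error(null_test(g, "modularity", n_iter = 5), "meaningless")
  nt <- null_test(g, "avg_clustering", n_iter = 50, seed = 9)
  expect_equal(length(nt$samples), 50)
  expect_equal(nt$convergence$iteration, 50)
  expect_gte(nt$empirical_p, 1 / 51)
  # clustering is structurally 0 in a tripartite graph: null equals observed
  expect_true(all(nt$samples == 0))
})

test_that("null_test is reproducible and its p consistent with its samples", {
  g <- random_tripartite(n_gene = 10, n_comp = 6, seed = 77)
  n1 <- null_test(g, "modularity", n_iter = 30, seed = 4)
  n2 <- null_test(g, "modularity", n_iter = 30, seed = 4)
  expect_identical(n1$samples, n2$samples)
  expect_equal(n1$empirical_p,
               (1 + sum(n1$samples >= n1$observed)) / (1 + 30))
})

test_that("null ensembles serialize to JSON and CSV", {
  g <- random_tripartite(n_gene = 10, n_comp = 6, seed = 77)
  nt <- null_test(g, "modularity", n_iter = 20, seed = 4)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_null_ensemble(nt, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$observed, nt$observed)
  expect_equal(back$samples, nt$samples)
  expect_equal(nrow(read.csv(cp)), nrow(nt$convergence))
})
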