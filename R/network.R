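#' Build a typed tripartite network from a relationship table
#'
#' One node per distinct gene, compound and plant; an undirected gene-compound
#' edge per distinct co-occurring pair and a compound-plant edge likewise.
#' Gene-plant edges never exist: plants reach genes only through compounds.
#' Orphan genes are kept as isolated nodes. The resulting [igraph::graph]
#' carries the vertex attribute `entity_type` ("gene"/"compound"/"plant"),
#' and edge attributes `layer` ("gene-compound"/"compound-plant") and
#' `weight` (1, or the number of supporting rows with `weight = "frequency"`).
#'
#' @param table a `phyto_relationships` table ([clean_relationships()]).
#' @param weight `"unit"` (default) or `"frequency"` (rows per pair).
#' @return An igraph object; also of class checked by [assert_tripartite()].
#' @export
build_network <- function(table, weight = c("unit", "frequency")) {
  weight <- match.arg(weight)
  stopifnot(is.data.frame(table), "gene" %in% names(table))
  if (nrow(table) == 0L) stop("cannot build a network from an empty table")

  genes <- unique(table$gene)
  comps <- if ("compound" %in% names(table))
    unique(table$compound[!is.na(table$compound)]) else character(0)
  plants <- if ("plant" %in% names(table))
    unique(table$plant[!is.na(table$plant)]) else character(0)

  all_names <- c(genes, comps, plants)
  if (anyDuplicated(all_names))
    stop("entity name used for more than one type: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  vertices <- data.frame(
    name = all_names,
    entity_type = rep(c("gene", "compound", "plant"),
                      c(length(genes), length(comps), length(plants))),
    stringsAsFactors = FALSE)

  edges <- list()
  if (length(comps)) {
    gc <- table[!is.na(table$compound), c("gene", "compound")]
    if (nrow(gc)) {
      key <- paste(gc$gene, gc$compound, sep = "\r")
      tab <- table(key)
      parts <- strsplit(names(tab), "\r", fixed = TRUE)
      edges$gc <- data.frame(
        from = vapply(parts, `[`, "", 1L), to = vapply(parts, `[`, "", 2L),
        layer = "gene-compound",
        weight = if (weight == "frequency") as.numeric(tab) else 1,
        stringsAsFactors = FALSE)
    }
  }
  if (length(comps) && length(plants)) {
    cp <- table[!is.na(table$compound) & !is.na(table$plant),
                c("compound", "plant")]
    if (nrow(cp)) {
      key <- paste(cp$compound, cp$plant, sep = "\r")
      tab <- table(key)
      parts <- strsplit(names(tab), "\r", fixed = TRUE)
      edges$cp <- data.frame(
        from = vapply(parts, `[`, "", 1L), to = vapply(parts, `[`, "", 2L),
        layer = "compound-plant",
        weight = if (weight == "frequency") as.numeric(tab) else 1,
        stringsAsFactors = FALSE)
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               layer = character(0), weight = numeric(0))
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vertices)
  assert_tripartite(g)
  g
}

#' Assert the structural invariants of a tripartite network
#'
#' Checks that every vertex has a valid `entity_type`, that the graph is
#' simple (no loops, no parallel edges), and that every edge joins a
#' gene-compound or compound-plant pair with a matching `layer` tag.
#'
#' @param g an igraph object.
#' @return `g`, invisibly; errors on violation.
#' @export
assert_tripartite <- function(g) {
  stopifnot(igraph::is_igraph(g))
  types <- igraph::V(g)$entity_type
  if (is.null(types) || !all(types %in% c("gene", "compound", "plant")))
    stop("every vertex needs entity_type in {gene, compound, plant}")
  if (!igraph::is_simple(g)) stop("graph must be simple (no loops/multi-edges)")
  if (igraph::ecount(g)) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    t1 <- types[ends[, 1]]; t2 <- types[ends[, 2]]
    pair <- paste(pmin(t1, t2), pmax(t1, t2), sep = "-")
    expect <- ifelse(pair == "compound-gene", "gene-compound",
                     ifelse(pair == "compound-plant", "compound-plant", NA))
    if (anyNA(expect)) stop("forbidden edge between types: ",
                            paste(unique(pair[is.na(expect)]), collapse = ", "))
    layer <- igraph::E(g)$layer
    if (is.null(layer) || !all(layer == expect))
      stop("edge layer tags do not match endpoint types")
  }
  invisible(g)
}

#' Network density
#'
#' `2 m / (n (n - 1))` for a simple undirected graph with `n` nodes and `m`
#' edges. The reference dataset's 143-node, 1033-edge network gives 0.1017.
#'
#' @param net an igraph object with at least 2 nodes.
#' @return A single numeric density in `[0, 1]`.
#' @export
net_density <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("density needs at least 2 nodes")
  2 * igraph::ecount(net) / (n * (n - 1))
}

#' Per-node centrality profile
#'
#' Degree, degree centrality (`degree / (n - 1)`), unnormalized betweenness,
#' closeness and eigenvector centrality for every node.
#'
#' Closeness uses the reachable-fraction convention for disconnected graphs:
#' for a node reaching `r` other nodes with total distance `D`,
#' `closeness = (r / D) * (r / (n - 1))`, so values stay in `[0, 1]` and
#' isolated nodes score 0. Eigenvector centrality is computed on the largest
#' connected component (power iteration, tolerance 1e-6, scaled to max 1);
#' nodes outside it score 0.
#'
#' @param net a nonempty igraph object.
#' @return A data frame: node, entity_type, degree, degree_centrality,
#'   betweenness, closeness, eigenvector.
#' @export
node_centralities <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network")
  deg <- igraph::degree(net)
  dc <- if (n > 1) deg / (n - 1) else rep(0, n)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)

  d <- igraph::distances(net)
  diag(d) <- Inf
  clo <- apply(d, 1, function(row) {
    reach <- is.finite(row)
    r <- sum(reach)
    if (r == 0 || n < 2) return(0)
    (r / sum(row[reach])) * (r / (n - 1))
  })

  eig <- rep(0, n)
  comp <- igraph::components(net)
  if (igraph::ecount(net) > 0) {
    big <- which.max(comp$csize)
    idx <- which(comp$membership == big)
    if (length(idx) > 1) {
      sub <- igraph::induced_subgraph(net, idx)
      A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
      # deterministic shifted power iteration: iterating (A + I) has the same
      # leading eigenvector but cannot oscillate on bipartite structures
      # (any layered tripartite graph is bipartite: compounds vs the rest)
      x <- rep(1 / sqrt(nrow(A)), nrow(A))
      converged <- FALSE
      for (it in seq_len(1000L)) {
        xn <- as.vector(A %*% x) + x
        xn <- xn / sqrt(sum(xn^2))
        if (max(abs(xn - x)) < 1e-6) { x <- xn; converged <- TRUE; break }
        x <- xn
      }
      if (!converged)
        stop("eigenvector centrality did not converge on the component ",
             "containing ", igraph::V(sub)$name[1],
             " (", nrow(A), " nodes)")
      eig[idx] <- x / max(x)
    }
  }
  types <- igraph::V(net)$entity_type
  if (is.null(types)) types <- NA_character_
  data.frame(node = igraph::V(net)$name,
             entity_type = types,
             degree = as.integer(deg), degree_centrality = dc,
             betweenness = btw, closeness = clo, eigenvector = eig,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Topology summary of a tripartite network
#'
#' Node/edge counts, density, average clustering coefficient (mean local
#' clustering, nodes of degree < 2 counted as 0 — note a valid tripartite
#' layering admits no triangles, so this is 0 by construction for in-type
#' networks), composition percentages per entity type (1 d.p.), hub compounds
#' (at least `hub_degree` distinct gene targets), and, when a partition is
#' supplied, the R-squared of a least-squares fit of log community size
#' against log rank.
#'
#' @param net a nonempty igraph object with `entity_type`.
#' @param partition optional [louvain_partition()] result.
#' @param hub_degree minimum distinct gene targets for a hub compound.
#' @return A `phyto_topology` list.
#' @export
topology_summary <- function(net, partition = NULL, hub_degree = 5L) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network")
  types <- igraph::V(net)$entity_type
  comp_pct <- round(100 * table(factor(types, c("gene", "compound", "plant"))) / n, 1)

  clustering <- igraph::transitivity(net, type = "localaverage", isolates = "zero")
  if (is.nan(clustering)) clustering <- 0

  comp_idx <- which(types == "compound")
  hubs <- data.frame(compound = character(0), degree = integer(0))
  if (length(comp_idx)) {
    gene_deg <- vapply(comp_idx, function(v) {
      nb <- igraph::neighbors(net, v)
      sum(nb$entity_type == "gene")
    }, integer(1))
    ord <- order(-gene_deg, igraph::V(net)$name[comp_idx])
    hubs <- data.frame(compound = igraph::V(net)$name[comp_idx][ord],
                       degree = gene_deg[ord], stringsAsFactors = FALSE)
    hubs <- hubs[hubs$degree >= hub_degree, , drop = FALSE]
    rownames(hubs) <- NULL
  }
  hub_fraction <- if (length(comp_idx)) nrow(hubs) / length(comp_idx) else NA_real_

  powerlaw_r2 <- NA_real_
  if (!is.null(partition)) {
    sizes <- sort(as.numeric(table(partition$assignment)), decreasing = TRUE)
    if (length(sizes) >= 3 && stats::sd(log(sizes)) > 0) {
      fit <- stats::lm(log(sizes) ~ log(seq_along(sizes)))
      powerlaw_r2 <- summary(fit)$r.squared
    }
  }

  structure(list(n_nodes = n, n_edges = igraph::ecount(net),
                 density = if (n >= 2) net_density(net) else NA_real_,
                 avg_clustering = clustering,
                 composition = comp_pct,
                 hub_compounds = hubs, hub_degree = hub_degree,
                 hub_fraction = hub_fraction,
                 powerlaw_r2 = powerlaw_r2),
            class = "phyto_topology")
}

#' @export
print.phyto_topology <- function(x, ...) {
  cat(sprintf("Tripartite network: %d nodes, %d edges, density %.4f\n",
              x$n_nodes, x$n_edges, x$density))
  cat(sprintf("  composition: genes %.1f%% | compounds %.1f%% | plants %.1f%%\n",
              x$composition[["gene"]], x$composition[["compound"]],
              x$composition[["plant"]]))
  cat(sprintf("  avg clustering: %.3f | hub compounds (>=%d gene targets): %d (%.1f%%)\n",
              x$avg_clustering, x$hub_degree, nrow(x$hub_compounds),
              100 * x$hub_fraction))
  if (!is.na(x$powerlaw_r2))
    cat(sprintf("  community size power-law R^2: %.3f\n", x$powerlaw_r2))
  invisible(x)
}
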