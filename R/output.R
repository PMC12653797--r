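.phyto_dirs <- c("1_network", "2_figures/visualization", "3_gene_selection",
                 "4_enrichment")

#' Initialize the hierarchical output tree
#'
#' Creates `1_network/`, `2_figures/visualization/`, `3_gene_selection/` and
#' `4_enrichment/` under `output_root`. Refuses to touch an existing
#' non-empty root unless `overwrite = TRUE`, so completed runs cannot be
#' clobbered accidentally.
#'
#' @param output_root run directory (created if missing).
#' @param overwrite allow writing into an existing non-empty root.
#' @return The absolute root path, invisibly.
#' @export
init_run <- function(output_root, overwrite = FALSE) {
  if (dir.exists(output_root) &&
      length(list.files(output_root, all.files = TRUE, no.. = TRUE)) > 0 &&
      !overwrite)
    stop("output root exists and is not empty (use overwrite = TRUE): ",
         output_root)
  dir.create(output_root, showWarnings = FALSE, recursive = TRUE)
  root <- normalizePath(output_root, mustWork = TRUE)
  ok <- file.access(root, 2) == 0
  if (!ok) stop("output root is not writable: ", root)
  for (d in .phyto_dirs)
    dir.create(file.path(root, d), showWarnings = FALSE, recursive = TRUE)
  invisible(root)
}

#' Write a tripartite network as GEXF 1.2
#'
#' Nodes carry the string attribute `entity_type`, edges the string attribute
#' `layer` and a numeric weight. The network is re-validated before writing:
#' a graph violating the tripartite type invariants is never serialized.
#'
#' @param net a tripartite igraph object.
#' @param path output `.gexf` path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(net, path) {
  assert_tripartite(net)
  doc <- xml2::xml_new_root("gexf", xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  nattr <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(nattr, "attribute", id = "0", title = "entity_type",
                      type = "string")
  eattr <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattr, "attribute", id = "0", title = "layer",
                      type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(igraph::vcount(net))) {
    nm <- igraph::V(net)$name[i]
    node <- xml2::xml_add_child(nodes, "node", id = nm, label = nm)
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = igraph::V(net)$entity_type[i])
  }
  edges <- xml2::xml_add_child(graph, "edges")
  if (igraph::ecount(net)) {
    ends <- igraph::ends(net, igraph::E(net))
    w <- igraph::E(net)$weight
    if (is.null(w)) w <- rep(1, nrow(ends))
    lay <- igraph::E(net)$layer
    for (i in seq_len(nrow(ends))) {
      e <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                               source = ends[i, 1], target = ends[i, 2],
                               weight = sprintf("%.10g", w[i]))
      av <- xml2::xml_add_child(e, "attvalues")
      xml2::xml_add_child(av, "attvalue", "for" = "0", value = lay[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GEXF 1.2 tripartite network back
#'
#' @param path a `.gexf` file written by [write_gexf()].
#' @return A tripartite igraph object.
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//nodes/node")
  vertices <- data.frame(
    name = xml2::xml_attr(nodes, "id"),
    entity_type = xml2::xml_attr(
      xml2::xml_find_first(nodes, ".//attvalue[@for='0']"), "value"),
    stringsAsFactors = FALSE)
  edges <- xml2::xml_find_all(doc, ".//edges/edge")
  edf <- data.frame(
    from = xml2::xml_attr(edges, "source"),
    to = xml2::xml_attr(edges, "target"),
    layer = xml2::xml_attr(
      xml2::xml_find_first(edges, ".//attvalue[@for='0']"), "value"),
    weight = as.numeric(xml2::xml_attr(edges, "weight")),
    stringsAsFactors = FALSE)
  if (nrow(edf) == 0)
    edf <- data.frame(from = character(0), to = character(0),
                      layer = character(0), weight = numeric(0))
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vertices)
  assert_tripartite(g)
  g
}

#' Write / read a network in node-link JSON
#'
#' The JSON object has `directed`, `nodes` (id, entity_type) and `links`
#' (source, target, layer, weight); a write-read round trip reproduces the
#' node set, edge set and attributes exactly.
#'
#' @param net a tripartite igraph object.
#' @param path output `.json` path.
#' @return `path` invisibly ([write_graph_json()]); an igraph object
#'   ([read_graph_json()]).
#' @export
write_graph_json <- function(net, path) {
  assert_tripartite(net)
  nodes <- data.frame(id = igraph::V(net)$name,
                      entity_type = igraph::V(net)$entity_type,
                      stringsAsFactors = FALSE)
  if (igraph::ecount(net)) {
    ends <- igraph::ends(net, igraph::E(net))
    w <- igraph::E(net)$weight
    if (is.null(w)) w <- rep(1, nrow(ends))
    links <- data.frame(source = ends[, 1], target = ends[, 2],
                        layer = igraph::E(net)$layer, weight = w,
                        stringsAsFactors = FALSE)
  } else {
    links <- data.frame(source = character(0), target = character(0),
                        layer = character(0), weight = numeric(0))
  }
  jsonlite::write_json(list(directed = FALSE, nodes = nodes, links = links),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  links <- as.data.frame(obj$links, stringsAsFactors = FALSE)
  if (!nrow(links))
    links <- data.frame(source = character(0), target = character(0),
                        layer = character(0), weight = numeric(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = links$source, to = links$target, layer = links$layer,
               weight = links$weight, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes$id, entity_type = nodes$entity_type,
                          stringsAsFactors = FALSE))
  assert_tripartite(g)
  g
}

#' Write the Markdown analysis report
#'
#' One report per run with sections for validation, network topology,
#' communities and the configuration-model null, and each enrichment method
#' that ran.
#'
#' @param results named list with any of `validation` (`phyto_validation`),
#'   `stats` (`phyto_stats`), `topology` (`phyto_topology`), `partition`
#'   (`phyto_partition`), `null` (`phyto_null`), `enrichment` (named list of
#'   data frames keyed by method), `skipped` (character).
#' @param path output `.md` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  ln <- c("# Tripartite network & enrichment analysis report", "",
          sprintf("Generated by phytonet %s on %s", .phyto_version(),
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S")), "")
  if (!is.null(results$validation)) {
    v <- results$validation
    ln <- c(ln, "## Validation", "",
            sprintf("- status: **%s**", v$status),
            sprintf("- rows: %d, invalid fraction: %.3f, duplicates removed: %d",
                    v$n_rows, v$invalid_fraction, v$duplicate_count),
            sprintf("- warnings: %s",
                    if (length(v$warnings)) paste(v$warnings, collapse = "; ")
                    else "none"), "")
  }
  if (!is.null(results$stats)) {
    s <- results$stats
    ln <- c(ln, "## Relationship statistics", "",
            sprintf("- %d genes, %d compounds, %d plants",
                    s$n_genes, s$n_compounds, s$n_plants),
            sprintf("- cross-plant compounds: %.1f%%, multi-compound genes: %.1f%%, orphan genes: %.1f%%",
                    100 * s$cross_plant_compound_fraction,
                    100 * s$multi_compound_gene_fraction,
                    100 * s$orphan_gene_fraction), "")
  }
  if (!is.null(results$topology)) {
    t <- results$topology
    ln <- c(ln, "## Network topology", "",
            sprintf("- %d nodes, %d edges, density %.4f",
                    t$n_nodes, t$n_edges, t$density),
            sprintf("- composition: genes %.1f%% / compounds %.1f%% / plants %.1f%%",
                    t$composition[["gene"]], t$composition[["compound"]],
                    t$composition[["plant"]]),
            sprintf("- average clustering: %.3f; hub compounds (>= %d gene targets): %d",
                    t$avg_clustering, t$hub_degree, nrow(t$hub_compounds)), "")
  }
  if (!is.null(results$partition)) {
    p <- results$partition
    ln <- c(ln, "## Communities", "",
            sprintf("- Louvain: %d communities, modularity Q = %.4f (resolution %.2f)",
                    p$n_communities, p$modularity_q, p$resolution), "")
  }
  if (!is.null(results$null)) {
    nl <- results$null
    ln <- c(ln, "## Configuration-model null", "",
            sprintf("- metric: %s; observed %.4f vs null %.4f +/- %.4f",
                    nl$metric_name, nl$observed, mean(nl$samples),
                    stats::sd(nl$samples)),
            sprintf("- empirical p = %.4g (%d degree-preserving replicates, %s tail)",
                    nl$empirical_p, nl$n_iter, nl$tail), "")
  }
  for (m in names(results$enrichment)) {
    rec <- results$enrichment[[m]]
    ln <- c(ln, sprintf("## Enrichment: %s", m), "")
    if (is.null(rec) || !nrow(rec)) {
      ln <- c(ln, "- no gene set retained", "")
    } else {
      top <- utils::head(rec[order(rec$p_adj), ], 10)
      ln <- c(ln, sprintf("- %d sets tested; top hits by adjusted p:", nrow(rec)),
              sprintf("  - %s (p_adj = %.3g)", top$set_name, top$p_adj), "")
    }
  }
  if (length(results$skipped))
    ln <- c(ln, "## Skipped stages", "",
            sprintf("- %s", results$skipped), "")
  writeLines(ln, path)
  invisible(path)
}

#' Write the run manifest
#'
#' Records timestamp, tool version, input digests, the full parameter set,
#' seeds, skipped stages, and an inventory (with MD5 digests) of every file
#' under the output tree. Re-running with identical inputs and seeds
#' reproduces identical analytical outputs.
#'
#' @param root run root from [init_run()].
#' @param inputs named character vector of input file paths.
#' @param parameters named list of run parameters.
#' @param seeds named list or vector of seeds.
#' @param skipped character vector of skipped-stage notes.
#' @param path output path (default `manifest.json` under `root`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(root, inputs = character(0), parameters = list(),
                           seeds = list(), skipped = character(0),
                           path = file.path(root, "manifest.json")) {
  inv <- list.files(root, recursive = TRUE, full.names = TRUE)
  inv <- inv[normalizePath(inv) != normalizePath(path, mustWork = FALSE)]
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tool = "phytonet", version = .phyto_version(),
    root = root,
    inputs = lapply(inputs, function(f)
      list(path = normalizePath(f, mustWork = FALSE),
           md5 = unname(tools::md5sum(f)))),
    parameters = parameters, seeds = seeds, skipped = skipped,
    outputs = lapply(inv, function(f)
      list(path = sub(paste0("^", root, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
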