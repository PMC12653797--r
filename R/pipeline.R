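.log <- function(root, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(line)
  if (!is.null(root))
    cat(line, "\n", file = file.path(root, "run.log"), append = TRUE, sep = "")
}

.write_records <- function(records, dir, entity, method) {
  if (is.null(records) || !nrow(records)) return(invisible(NULL))
  base <- file.path(dir, sprintf("%s_%s", gsub("[^A-Za-z0-9_-]", "_", entity),
                                 tolower(method)))
  utils::write.csv(records, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(records, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' Run the full analysis pipeline
#'
#' Executes validation, cleaning, network construction, topology, Louvain
#' communities with the configuration-model null, the requested enrichment
#' methods (globally and per entity), figures, the Markdown report and the
#' manifest, into the four-directory output tree of [init_run()]. A failing
#' optional stage (e.g. GSVA without an expression matrix) is skipped with a
#' logged reason; a validation failure aborts the run.
#'
#' @param config a `phyto_config` from [validate_config()], or a path/list
#'   accepted by it.
#' @return Invisibly, a list with `status` (0 = success), the run `root`,
#'   and the main in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "phyto_config")) config <- validate_config(config)
  seed <- if (is.null(config$seed)) sample.int(1e6, 1) else as.integer(config$seed)
  root <- init_run(config$output_root, overwrite = config$overwrite)
  skipped <- character(0)
  .log(root, "phytonet ", .phyto_version(), " | seed ", seed)

  raw <- read_relationships(config$relationships)
  report <- validate_relationships(raw)
  write_validation_report(report, file.path(root, "validation_report.json"),
                          log_path = file.path(root, "run.log"))
  if (report$status == "fail") {
    .log(root, "validation FAILED; aborting")
    return(invisible(list(status = 1L, root = root, validation = report)))
  }
  table <- clean_relationships(raw)
  stats <- relationship_stats(table)
  .log(root, sprintf("cleaned table: %d rows, %d genes, %d compounds, %d plants",
                     stats$n_rows, stats$n_genes, stats$n_compounds,
                     stats$n_plants))

  net <- build_network(table, weight = config$weight_mode)
  write_gexf(net, file.path(root, "1_network", "network.gexf"))
  write_graph_json(net, file.path(root, "1_network", "network.json"))
  topo <- topology_summary(net, hub_degree = config$hub_degree)
  cent <- node_centralities(net)
  utils::write.csv(cent, file.path(root, "1_network", "centralities.csv"),
                   row.names = FALSE)

  part <- louvain_partition(net, resolution = config$resolution, seed = seed)
  topo <- topology_summary(net, partition = part,
                           hub_degree = config$hub_degree)
  jsonlite::write_json(
    list(n_nodes = topo$n_nodes, n_edges = topo$n_edges,
         density = topo$density, avg_clustering = topo$avg_clustering,
         composition = as.list(topo$composition),
         hub_fraction = topo$hub_fraction,
         modularity = part$modularity_q,
         n_communities = part$n_communities,
         powerlaw_r2 = topo$powerlaw_r2),
    file.path(root, "1_network", "network_statistics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  nul <- NULL
  if (igraph::ecount(net) > 0 && config$n_random >= 10) {
    nul <- null_test(net, "modularity", n_iter = config$n_random, seed = seed,
                     resolution = config$resolution)
    write_null_ensemble(nul, file.path(root, "1_network", "null_modularity.json"),
                        file.path(root, "1_network", "null_convergence.csv"))
    .log(root, sprintf("null test: observed Q %.4f vs %.4f +/- %.4f (p = %.4g)",
                       nul$observed, mean(nul$samples), stats::sd(nul$samples),
                       nul$empirical_p))
  }

  ranking <- gene_ranking(table)
  utils::write.csv(data.frame(gene = names(ranking), score = ranking,
                              row.names = NULL),
                   file.path(root, "3_gene_selection", "gene_ranking.csv"),
                   row.names = FALSE)

  collections <- lapply(config$gene_sets, read_gmt)
  enrichment <- list()
  if (!length(collections)) {
    skipped <- c(skipped, "enrichment: no gene-set collections supplied")
  } else {
    background <- unique(table$gene)
    for (ci in seq_along(collections)) {
      col <- collections[[ci]]
      label <- attr(col, "database_label")
      if (config$run_ora) {
        bundles <- entity_enrichment(table, col, background,
                                     method = "ORA",
                                     min_size = config$min_set_size,
                                     correction = config$correction)
        for (b in bundles) {
          .write_records(b$records, file.path(root, "4_enrichment"),
                         paste(b$entity, label, sep = "_"), "ora")
          if (b$type != "global")
            writeLines(b$genes, file.path(root, "3_gene_selection",
                                          sprintf("%s_genes.txt",
                                                  gsub("[^A-Za-z0-9_-]", "_",
                                                       b$entity))))
        }
        enrichment$ORA <- bundles$global$records
      }
      if (config$run_gsea) {
        rk <- if (!is.null(config$preranked)) {
          pr <- utils::read.csv(config$preranked, sep = "",
                                header = TRUE, stringsAsFactors = FALSE)
          stats::setNames(as.numeric(pr[[2]]), toupper(pr[[1]]))
        } else ranking
        enrichment$GSEA <- gsea_preranked(rk, col,
                                          n_perm = config$n_perm,
                                          min_size = config$min_set_size,
                                          seed = seed)
        .write_records(enrichment$GSEA, file.path(root, "4_enrichment"),
                       paste("global", label, sep = "_"), "gsea")
      }
      if (config$run_gsva) {
        if (is.null(config$expression)) {
          skipped <- c(skipped,
                       sprintf("GSVA (%s): no expression matrix supplied", label))
        } else {
          expr <- as.matrix(utils::read.csv(config$expression, sep = "\t",
                                            row.names = 1, check.names = FALSE))
          sc <- gsva_scores(expr, col, min_size = config$gsva_min_size,
                            max_size = config$gsva_max_size)
          utils::write.csv(sc, file.path(root, "4_enrichment",
                                         sprintf("global_%s_gsva.csv", label)))
          enrichment$GSVA <- sc
        }
      }
    }
  }

  if (!config$skip_figures) {
    style <- figure_style(layout_seed = seed)
    figdir <- file.path(root, "2_figures", "visualization")
    render_network(net, part, style, file.path(figdir, "global_network.png"))
    render_centrality_panels(cent, style,
                             file.path(figdir, "global_centrality.png"))
    if ("compound" %in% names(table)) {
      gc <- unique(table[!is.na(table$compound), c("gene", "compound")])
      if (nrow(gc)) {
        inc <- table(gc$compound, gc$gene)
        render_heatmap(unclass(inc), style,
                       file.path(figdir, "global_heatmap.png"))
      }
    }
    if (!is.null(enrichment$ORA) && nrow(enrichment$ORA)) {
      render_bubble(enrichment$ORA, style,
                    file.path(figdir, "global_bubble.png"))
      render_bars(enrichment$ORA, style, file.path(figdir, "global_bars.png"))
    }
  } else skipped <- c(skipped, "figures: disabled by configuration")

  write_report(list(validation = report, stats = stats, topology = topo,
                    partition = part, null = nul, enrichment = enrichment[
                      intersect(c("ORA", "GSEA"), names(enrichment))],
                    skipped = skipped),
               file.path(root, "report.md"))
  write_manifest(root,
                 inputs = unlist(c(config$relationships, config$gene_sets,
                                   config$expression, config$preranked)),
                 parameters = config[setdiff(names(config),
                                             c("relationships", "gene_sets",
                                               "expression", "preranked"))],
                 seeds = list(seed = seed), skipped = skipped)
  .log(root, "run complete")
  invisible(list(status = 0L, root = root, validation = report, stats = stats,
                 network = net, topology = topo, partition = part, null = nul,
                 enrichment = enrichment, skipped = skipped, seed = seed))
}
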