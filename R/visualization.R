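#' Figure style for all rendered outputs
#'
#' 300 DPI PNG output, the fixed entity palette (genes blue, compounds green,
#' plants pink), and a seeded spring-force layout whose repulsion adapts to
#' network density (repulsion scale proportional to `1/sqrt(density)`, floored
#' at 1).
#'
#' @param dpi output resolution (dots per inch).
#' @param colors named palette for entity types.
#' @param layout_seed seed fixing layout coordinates.
#' @return A `phyto_style` list.
#' @export
figure_style <- function(dpi = 300,
                         colors = c(gene = "#1f77b4", compound = "#2ca02c",
                                    plant = "#ff69b4"),
                         layout_seed = 42L) {
  stopifnot(all(c("gene", "compound", "plant") %in% names(colors)))
  structure(list(dpi = dpi, colors = colors,
                 layout_seed = as.integer(layout_seed)),
            class = "phyto_style")
}

.save_png <- function(plot, path, style, width = 8, height = 6) {
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  dpi = style$dpi, units = "in")
  invisible(path)
}

#' Render the tripartite network
#'
#' Spring-force (Fruchterman-Reingold) layout, deterministic for a fixed
#' `layout_seed`; nodes colored by `entity_type` only (and shaped by
#' community when a partition is supplied). Networks above 5000 nodes are
#' rendered with a warning and label suppression.
#'
#' @param net a tripartite igraph object.
#' @param partition optional [louvain_partition()] result (community hulls
#'   are not drawn; community is mapped to point shape for up to 6
#'   communities).
#' @param style a [figure_style()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_network <- function(net, partition = NULL, style = figure_style(),
                           path) {
  assert_tripartite(net)
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network")
  if (n > 5000) warning("network has > 5000 nodes; labels suppressed")
  dens <- if (n >= 2) max(net_density(net), 1e-6) else 1
  repulsion <- max(1, 1 / sqrt(dens))
  set.seed(style$layout_seed)
  coords <- igraph::layout_with_fr(net) * repulsion
  nodes <- data.frame(x = coords[, 1], y = coords[, 2],
                      name = igraph::V(net)$name,
                      entity_type = igraph::V(net)$entity_type,
                      stringsAsFactors = FALSE)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (igraph::ecount(net)) {
    ends <- igraph::ends(net, igraph::E(net), names = FALSE)
    segs <- data.frame(x = coords[ends[, 1], 1], y = coords[ends[, 1], 2],
                       xend = coords[ends[, 2], 1], yend = coords[ends[, 2], 2])
    p <- p + ggplot2::geom_segment(
      data = segs, ggplot2::aes(x = .data$x, y = .data$y,
                                xend = .data$xend, yend = .data$yend),
      color = "grey75", linewidth = 0.25, alpha = 0.6)
  }
  aes_pt <- if (!is.null(partition) &&
                length(unique(partition$assignment)) <= 6) {
    nodes$community <- factor(partition$assignment[nodes$name])
    ggplot2::aes(color = .data$entity_type, shape = .data$community)
  } else ggplot2::aes(color = .data$entity_type)
  p <- p + ggplot2::geom_point(aes_pt, size = 2) +
    ggplot2::scale_color_manual(values = style$colors, name = "entity") +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
  .save_png(p, path, style)
}

#' Render a compound-by-gene incidence heatmap
#'
#' @param incidence numeric matrix, compounds in rows, genes in columns.
#' @param style a [figure_style()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(incidence, style = figure_style(), path) {
  stopifnot(is.matrix(incidence), nrow(incidence) > 0, ncol(incidence) > 0)
  df <- expand.grid(compound = rownames(incidence), gene = colnames(incidence),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(incidence)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$compound,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = style$colors[["compound"]]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
  .save_png(p, path, style)
}

#' Render an enrichment bubble plot
#'
#' x = overlap ratio `k/n`, bubble size = overlap `k`, color = adjusted p on
#' a log scale. Records with `p_adj = 1` are rendered, never dropped.
#'
#' @param records an [ora()]-style data frame (needs set_name, overlap_k,
#'   query_size, p_adj).
#' @param style a [figure_style()].
#' @param path output PNG path.
#' @return `path` invisibly, or `NA_character_` (with a message) when
#'   `records` is empty — no empty file is written.
#' @export
render_bubble <- function(records, style = figure_style(), path) {
  if (is.null(records) || !nrow(records)) {
    message("bubble plot skipped: no enrichment records")
    return(invisible(NA_character_))
  }
  df <- records
  df$ratio <- df$overlap_k / df$query_size
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$set_name,
                                        size = .data$overlap_k,
                                        color = .data$p_adj)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "#b2182b", high = "#2166ac",
                                  trans = "log10", name = "adjusted p") +
    ggplot2::labs(x = "overlap ratio (k/n)", y = NULL, size = "overlap k") +
    ggplot2::theme_minimal()
  .save_png(p, path, style)
}

#' Render an enrichment bar chart (top 20 by adjusted p)
#'
#' @inheritParams render_bubble
#' @export
render_bars <- function(records, style = figure_style(), path) {
  if (is.null(records) || !nrow(records)) {
    message("bar chart skipped: no enrichment records")
    return(invisible(NA_character_))
  }
  df <- utils::head(records[order(records$p_adj, records$p_raw), ], 20)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adj),
                                        y = .data$set_name)) +
    ggplot2::geom_col(fill = style$colors[["gene"]]) +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal()
  .save_png(p, path, style)
}

#' Render centrality distribution panels
#'
#' Histograms of degree, betweenness, closeness and eigenvector centrality,
#' faceted in one figure.
#'
#' @param profile a [node_centralities()] data frame.
#' @param style a [figure_style()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_centrality_panels <- function(profile, style = figure_style(), path) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0)
  long <- do.call(rbind, lapply(
    c("degree", "betweenness", "closeness", "eigenvector"),
    function(m) data.frame(measure = m, value = profile[[m]])))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = style$colors[["gene"]]) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "nodes")
  .save_png(p, path, style)
}

#' @importFrom ggplot2 .data
NULL
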