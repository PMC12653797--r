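#' Louvain community detection
#'
#' Runs multilevel (Louvain) modularity optimization at the given resolution.
#' The seed fixes the algorithm's tie-breaking, so the same graph and seed
#' always give the same assignment. Community labels are canonicalized by the
#' smallest member vertex index, and the Newman-Girvan modularity of the
#' resulting partition (at resolution 1) is attached. An edgeless graph gets
#' one singleton community per node with modularity 0.
#'
#' @param net a simple igraph object.
#' @param resolution positive resolution parameter (1 = classic modularity).
#' @param seed integer seed.
#' @return A `phyto_partition` list: `assignment` (named integer vector),
#'   `modularity_q`, `n_communities`, `resolution`, `seed`.
#' @export
louvain_partition <- function(net, resolution = 1, seed = 1L) {
  stopifnot(igraph::is_igraph(net), resolution > 0)
  if (igraph::vcount(net) == 0) stop("empty network")
  nms <- igraph::V(net)$name
  if (igraph::ecount(net) == 0) {
    mem <- stats::setNames(seq_len(igraph::vcount(net)), nms)
    return(structure(list(assignment = mem, modularity_q = 0,
                          n_communities = length(mem),
                          resolution = resolution, seed = as.integer(seed)),
                     class = "phyto_partition"))
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(net, resolution = resolution)
  mem <- igraph::membership(cl)
  # canonical labels: community containing the earliest vertex becomes 1, etc.
  order_by_first <- unique(mem)  # community ids in order of first appearance
  relabel <- stats::setNames(seq_along(order_by_first), order_by_first)
  mem <- stats::setNames(as.integer(relabel[as.character(mem)]), nms)
  structure(list(assignment = mem,
                 modularity_q = modularity_q(net, mem),
                 n_communities = length(unique(mem)),
                 resolution = resolution, seed = as.integer(seed)),
            class = "phyto_partition")
}

#' @export
print.phyto_partition <- function(x, ...) {
  cat(sprintf("Louvain partition: %d communities, Q = %.4f (resolution %.2f, seed %d)\n",
              x$n_communities, x$modularity_q, x$resolution, x$seed))
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` over communities `c`, where `e_c`
#' is the number of edges inside `c`, `d_c` the total degree of its members
#' and `m` the edge count (unweighted form).
#'
#' @param net a simple igraph object with at least one edge.
#' @param assignment community labels: a vector in vertex order, or named by
#'   vertex (as in [louvain_partition()]`$assignment`).
#' @return A single numeric modularity in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, assignment) {
  m <- igraph::ecount(net)
  if (m == 0) stop("modularity undefined for a graph with no edges")
  n <- igraph::vcount(net)
  if (!is.null(names(assignment))) {
    assignment <- assignment[igraph::V(net)$name]
    if (anyNA(assignment)) stop("assignment must cover every vertex")
  }
  if (length(assignment) != n) stop("assignment must cover every vertex")
  mem <- as.character(assignment)
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  internal <- mem[ends[, 1]] == mem[ends[, 2]]
  e_c <- tapply(internal, mem[ends[, 1]], sum)  # internal edges keyed by community
  e_c_full <- stats::setNames(rep(0, length(unique(mem))), unique(mem))
  e_c_full[names(e_c)] <- e_c
  # note: edges internal to community c are counted once under either endpoint
  d_c <- tapply(igraph::degree(net), mem, sum)
  sum(e_c_full[names(d_c)] / m - (d_c / (2 * m))^2)
}

# -- configuration-model randomization ---------------------------------------

# Split edge endpoints per layer with a consistent (side A, side B) order.
.layer_edges <- function(net) {
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  types <- igraph::V(net)$entity_type
  layer <- igraph::E(net)$layer
  out <- list()
  for (lay in c("gene-compound", "compound-plant")) {
    idx <- which(layer == lay)
    if (!length(idx)) next
    sideA <- if (lay == "gene-compound") "gene" else "compound"
    a <- ifelse(types[ends[idx, 1]] == sideA, ends[idx, 1], ends[idx, 2])
    b <- ifelse(types[ends[idx, 1]] == sideA, ends[idx, 2], ends[idx, 1])
    out[[lay]] <- cbind(a, b)
  }
  out
}

#' One degree-preserving randomization of a tripartite network
#'
#' Configuration-model null realized by double-edge swaps constrained within
#' each layer (gene-compound swaps only with gene-compound, compound-plant
#' with compound-plant), so every replicate keeps each node's exact degree,
#' its type, the layer structure, and simplicity. A layer with fewer than 2
#' edges cannot be randomized and is returned unchanged with a warning.
#' Randomness comes from R's RNG stream (`set.seed()` upstream makes
#' replicates reproducible).
#'
#' @param net a tripartite igraph object ([assert_tripartite()] must hold).
#' @param n_attempts attempted swaps per layer; default 10 edge counts.
#' @return A rewired igraph with the same vertices, types and layer tags
#'   (edge weights reset to 1).
#' @export
rewire_tripartite <- function(net, n_attempts = NULL) {
  assert_tripartite(net)
  if (igraph::ecount(net) == 0) return(net)
  layers <- .layer_edges(net)
  edf <- list()
  for (lay in names(layers)) {
    e <- layers[[lay]]
    if (nrow(e) < 2) {
      warning("layer ", lay, " has < 2 edges; left unchanged")
      swapped <- e
    } else {
      att <- if (is.null(n_attempts)) 10L * nrow(e) else as.integer(n_attempts)
      swapped <- .rewire_layer_cpp(as.integer(e[, 1]), as.integer(e[, 2]), att)
    }
    edf[[lay]] <- data.frame(
      from = igraph::V(net)$name[swapped[, 1]],
      to = igraph::V(net)$name[swapped[, 2]],
      layer = lay, weight = 1, stringsAsFactors = FALSE)
  }
  vertices <- data.frame(name = igraph::V(net)$name,
                         entity_type = igraph::V(net)$entity_type,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(do.call(rbind, edf), directed = FALSE,
                                     vertices = vertices)
  assert_tripartite(g)
  g
}

#' Generate an ensemble of randomized networks
#'
#' @param net a tripartite igraph object.
#' @param n_iter number of replicates.
#' @param seed integer seed.
#' @param n_attempts swap attempts per layer per replicate (default 10 edge
#'   counts).
#' @return A list of `n_iter` igraph objects.
#' @export
randomize_network <- function(net, n_iter, seed = 1L, n_attempts = NULL) {
  set.seed(seed)
  lapply(seq_len(n_iter), function(i) rewire_tripartite(net, n_attempts))
}

.null_metric <- function(net, metric, resolution) {
  switch(metric,
    modularity = {
      cl <- igraph::cluster_louvain(net, resolution = resolution)
      modularity_q(net, igraph::membership(cl))
    },
    avg_clustering = {
      x <- igraph::transitivity(net, type = "localaverage", isolates = "zero")
      if (is.nan(x)) 0 else x
    },
    avg_path_length = igraph::mean_distance(net))
}

.empirical_p <- function(samples, observed, tail) {
  n <- length(samples)
  switch(tail,
    upper = (1 + sum(samples >= observed)) / (1 + n),
    lower = (1 + sum(samples <= observed)) / (1 + n),
    two.sided = min(1, 2 * min(
      (1 + sum(samples >= observed)) / (1 + n),
      (1 + sum(samples <= observed)) / (1 + n))))
}

# CV of the cumulative mean at each checkpoint t: sd of the cumulative means
# recorded at checkpoints in (t/2, t], divided by the cumulative mean at t.
# Windows holding fewer than 2 checkpoints report 0.
.convergence_cv <- function(samples, checkpoints) {
  cum_means <- cumsum(samples)[checkpoints] / checkpoints
  cv <- vapply(seq_along(checkpoints), function(i) {
    t <- checkpoints[i]
    win <- which(checkpoints > t / 2 & checkpoints <= t)
    if (length(win) < 2 || cum_means[i] == 0) return(0)
    stats::sd(cum_means[win]) / abs(cum_means[i])
  }, numeric(1))
  data.frame(iteration = checkpoints, cum_mean = cum_means, cv = cv)
}

#' Configuration-model significance test for a network metric
#'
#' Compares an observed metric (Louvain modularity, average clustering, or
#' average path length) against `n_iter` degree-preserving randomizations
#' ([rewire_tripartite()]), returning the sample distribution, a
#' (+1)-corrected empirical p-value, and a convergence trajectory: at
#' checkpoints 100, 200, ..., `n_iter` the cumulative mean and its
#' coefficient of variation over the trailing half-window of checkpoints.
#'
#' @param net a tripartite igraph object.
#' @param metric one of `"modularity"`, `"avg_clustering"`,
#'   `"avg_path_length"`.
#' @param n_iter number of replicates (at least 10).
#' @param seed integer seed driving both the randomizations and Louvain.
#' @param resolution Louvain resolution for the modularity metric.
#' @param tail `"upper"` (default; observed larger than random),
#'   `"lower"`, or `"two.sided"`.
#' @return A `phyto_null` list: `metric_name`, `samples`, `observed`,
#'   `empirical_p`, `convergence` (data frame iteration/cum_mean/cv),
#'   `seed`, `n_iter`, `tail`.
#' @export
null_test <- function(net, metric = c("modularity", "avg_clustering",
                                      "avg_path_length"),
                      n_iter = 1000L, seed = 1L, resolution = 1,
                      tail = c("upper", "lower", "two.sided")) {
  metric <- match.arg(metric)
  tail <- match.arg(tail)
  if (n_iter < 10) stop("n_iter < 10 gives a meaningless null")
  assert_tripartite(net)
  if (metric == "modularity" && igraph::ecount(net) == 0)
    stop("modularity null needs at least one edge")

  set.seed(seed)
  observed <- .null_metric(net, metric, resolution)
  samples <- vapply(seq_len(n_iter), function(i) {
    .null_metric(rewire_tripartite(net), metric, resolution)
  }, numeric(1))

  checkpoints <- if (n_iter >= 100) seq(100L, n_iter, by = 100L) else n_iter
  if (max(checkpoints) < n_iter) checkpoints <- c(checkpoints, n_iter)
  structure(list(metric_name = metric, samples = samples, observed = observed,
                 empirical_p = .empirical_p(samples, observed, tail),
                 convergence = .convergence_cv(samples, checkpoints),
                 seed = as.integer(seed), n_iter = as.integer(n_iter),
                 tail = tail),
            class = "phyto_null")
}

#' @export
print.phyto_null <- function(x, ...) {
  cat(sprintf("Null ensemble (%s, %d replicates): observed %.4f vs %.4f +/- %.4f, p = %.4g\n",
              x$metric_name, x$n_iter, x$observed, mean(x$samples),
              stats::sd(x$samples), x$empirical_p))
  tailcv <- x$convergence$cv[x$convergence$iteration >= x$n_iter / 2]
  cat(sprintf("  max CV over trailing checkpoints: %.4f\n", max(tailcv)))
  invisible(x)
}

#' Serialize a null ensemble to JSON (and its convergence table to CSV)
#'
#' @param ensemble a `phyto_null` object.
#' @param json_path output JSON path.
#' @param convergence_csv optional CSV path for the convergence table.
#' @param max_samples samples are omitted from the JSON above this count.
#' @return `json_path`, invisibly.
#' @export
write_null_ensemble <- function(ensemble, json_path, convergence_csv = NULL,
                                max_samples = 10000L) {
  stopifnot(inherits(ensemble, "phyto_null"))
  payload <- list(metric = ensemble$metric_name, observed = ensemble$observed,
                  empirical_p = ensemble$empirical_p,
                  n_iter = ensemble$n_iter, seed = ensemble$seed,
                  tail = ensemble$tail,
                  null_mean = mean(ensemble$samples),
                  null_sd = stats::sd(ensemble$samples),
                  convergence = ensemble$convergence)
  if (ensemble$n_iter <= max_samples) payload$samples <- ensemble$samples
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(convergence_csv))
    utils::write.csv(ensemble$convergence, convergence_csv, row.names = FALSE)
  invisible(json_path)
}
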