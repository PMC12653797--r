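# Shared builders and independent oracles used across the suite.
# Oracles are written from the definitions, never from the package code.

write_rel_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# Random typed tripartite graph built directly from edge sampling.
random_tripartite <- function(n_gene = 8, n_comp = 5, n_plant = 3,
                              p_gc = 0.4, p_cp = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_gene))
  comps <- sprintf("c%02d", seq_len(n_comp))
  plants <- sprintf("p%02d", seq_len(n_plant))
  gc <- expand.grid(from = genes, to = comps, stringsAsFactors = FALSE)
  gc <- gc[runif(nrow(gc)) < p_gc, , drop = FALSE]
  gc$layer <- rep("gene-compound", nrow(gc))
  cp <- expand.grid(from = comps, to = plants, stringsAsFactors = FALSE)
  cp <- cp[runif(nrow(cp)) < p_cp, , drop = FALSE]
  cp$layer <- rep("compound-plant", nrow(cp))
  edf <- rbind(gc, cp)
  edf$weight <- rep(1, nrow(edf))
  igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = data.frame(name = c(genes, comps, plants),
                          entity_type = rep(c("gene", "compound", "plant"),
                                            c(n_gene, n_comp, n_plant))))
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws.
ora_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K elements form the set
  sum(hits >= k) / ncol(draws)
}

# Modularity by the literal double sum over ordered node pairs.
modularity_double_sum <- function(g, mem) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- igraph::degree(g)
  m <- igraph::ecount(g)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    if (mem[i] == mem[j]) q <- q + A[i, j] - d[i] * d[j] / (2 * m)
  unname(q / (2 * m))
}

# GSEA enrichment score by walking the full ranking step by step.
gsea_walk_oracle <- function(scores, set_genes, weight = 1) {
  genes <- names(scores)
  hit <- genes %in% set_genes
  w <- abs(scores)^weight
  W <- sum(w[hit])
  if (W == 0) { w[] <- 1; W <- sum(w[hit]) }
  step <- ifelse(hit, w / W, -1 / (length(genes) - sum(hit)))
  walk <- cumsum(step)
  walk[which.max(abs(walk))]
}

# GSVA scores coded independently from the method definition:
# Gaussian kcdf (bandwidth sd/4), within-sample ranks, |p/2 - r|^tau weights,
# walk in decreasing kcdf order, score = max positive + min negative deviation.
gsva_direct_oracle <- function(x, sets, tau = 1) {
  p <- nrow(x); n <- ncol(x)
  z <- matrix(0.5, p, n, dimnames = dimnames(x))
  for (i in seq_len(p)) {
    s <- sd(x[i, ])
    if (s > 0) for (j in seq_len(n))
      z[i, j] <- mean(pnorm((x[i, j] - x[i, ]) / (s / 4)))
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(n)) {
    r <- rank(z[, j], ties.method = "average")
    w <- abs(p / 2 - r)^tau
    ord <- order(-z[, j], rownames(x))
    for (k in seq_along(sets)) {
      inset <- rownames(x)[ord] %in% sets[[k]]
      s <- sum(inset)
      wj <- w[ord]
      steps <- ifelse(inset, wj / sum(wj[inset]), -1 / (p - s))
      walk <- cumsum(steps)
      out[k, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  out
}

# Equality of typed networks: same vertex/type table, same edge multiset
# with layer and weight.
graph_equal <- function(a, b) {
  va <- data.frame(name = igraph::V(a)$name, type = igraph::V(a)$entity_type)
  vb <- data.frame(name = igraph::V(b)$name, type = igraph::V(b)$entity_type)
  ek <- function(g) {
    if (igraph::ecount(g) == 0) return(character(0))
    e <- igraph::ends(g, igraph::E(g))
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]),
               igraph::E(g)$layer, igraph::E(g)$weight))
  }
  identical(va[order(va$name), ], vb[order(vb$name), ]) &&
    identical(ek(a), ek(b))
}

# DPI embedded in a PNG pHYs chunk (pixels per metre -> dots per inch).
png_dpi <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  marker <- charToRaw("pHYs")
  for (i in seq_len(length(bytes) - 12)) {
    if (identical(bytes[i:(i + 3)], marker)) {
      ppm <- sum(as.integer(bytes[(i + 4):(i + 7)]) * 256^(3:0))
      return(round(ppm * 0.0254))
    }
  }
  NA_integer_
}
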