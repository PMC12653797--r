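# Enrichment score of the weighted Kolmogorov-Smirnov running sum, computed
# from hit positions only. Walking down the ranking, a hit at position p_i
# adds |score|^weight (normalized over the set's hits) and each miss subtracts
# 1/(N - s). The walk's extrema occur exactly at hits (peaks) and just before
# hits or at the endpoints (troughs), so only those values are evaluated.
# All-zero hit weights (e.g. weight 0 or all-zero scores) fall back to the
# unweighted KS statistic.
.gsea_es <- function(pos, score_abs, N, weight = 1) {
  s <- length(pos)
  w <- score_abs[pos]^weight
  W <- sum(w)
  if (W == 0) { w <- rep(1, s); W <- s }
  cw <- cumsum(w) / W
  miss <- 1 / (N - s)
  i <- seq_len(s)
  peaks <- cw - (pos - i) * miss
  troughs <- c(0, cw[-s]) - (pos - i) * miss
  mp <- max(peaks, 0)
  mn <- min(troughs, 0)
  if (mp >= -mn) mp else mn
}

#' Preranked gene set enrichment analysis
#'
#' Implements the weighted Kolmogorov-Smirnov running-sum enrichment score on
#' a ranked gene list: hits increment proportionally to
#' `|score|^weight` (normalized over the set's hits), misses decrement by
#' `1/(N - |S|)`, and the enrichment score (ES) is the signed maximum
#' deviation of the walk. The null distribution is built by gene-tag
#' permutation: `n_perm` resampled member sets of equal size. The normalized
#' enrichment score is `NES = ES / mean(|null ES| of matching sign)`; the raw
#' p-value is the (+1)-corrected same-sign tail frequency (so it is floored
#' at `1/(n_perm + 1)`), and the FDR (`p_adj`) is computed from the pooled
#' signed null NES distributions across sets, positive and negative sides
#' separately.
#'
#' @param ranking named numeric vector of finite gene scores (names = unique
#'   gene symbols), or a two-column data frame (gene, score). Sorted
#'   descending internally; ties keep their given order.
#' @param collection a [read_gmt()] collection (or named list of sets).
#' @param weight exponent on `|score|` for hit increments (default 1).
#' @param n_perm number of gene-tag permutations (default 1000).
#' @param min_size minimum overlap between set and ranking (default 3, the
#'   same floor used for over-representation analysis).
#' @param seed integer seed.
#' @return A data frame ordered by `p_adj` then `p_raw`: set_name, method,
#'   size, es, nes, p_raw, p_adj, direction.
#' @export
gsea_preranked <- function(ranking, collection, weight = 1, n_perm = 1000L,
                           min_size = 3L, seed = 1L) {
  if (is.data.frame(ranking)) {
    stopifnot(ncol(ranking) >= 2)
    ranking <- stats::setNames(as.numeric(ranking[[2]]), ranking[[1]])
  }
  stopifnot(is.numeric(ranking), !is.null(names(ranking)),
            all(is.finite(ranking)), n_perm >= 1)
  names(ranking) <- toupper(names(ranking))
  if (anyDuplicated(names(ranking))) stop("duplicate genes in ranking")
  ord <- order(-ranking)
  ranking <- ranking[ord]
  genes <- names(ranking)
  N <- length(ranking)
  score_abs <- abs(ranking)

  hit_idx <- lapply(collection, function(s) which(genes %in% toupper(s)))
  sizes <- lengths(hit_idx)
  keep <- sizes >= min_size & sizes < N
  if (!any(keep)) {
    warning("no gene set overlaps the ranking at min_size")
    return(data.frame(set_name = character(0), method = character(0),
                      size = integer(0), es = numeric(0), nes = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      direction = numeric(0)))
  }
  hit_idx <- hit_idx[keep]
  sizes <- sizes[keep]

  set.seed(seed)
  es_obs <- vapply(hit_idx, function(p) .gsea_es(p, score_abs, N, weight),
                   numeric(1))
  # one null ES matrix per distinct set size, shared across same-size sets
  null_by_size <- list()
  for (s in sort(unique(sizes))) {
    null_by_size[[as.character(s)]] <- vapply(seq_len(n_perm), function(b)
      .gsea_es(sort(sample.int(N, s)), score_abs, N, weight), numeric(1))
  }

  nes <- p_raw <- numeric(length(es_obs))
  nes_null <- vector("list", length(es_obs))
  for (j in seq_along(es_obs)) {
    null <- null_by_size[[as.character(sizes[j])]]
    pos_mean <- mean(null[null >= 0])
    neg_mean <- mean(abs(null[null < 0]))
    norm_for <- function(e) ifelse(
      e >= 0,
      e / (if (is.nan(pos_mean)) mean(abs(null)) else pos_mean),
      e / (if (is.nan(neg_mean)) mean(abs(null)) else neg_mean))
    nes[j] <- norm_for(es_obs[j])
    nes_null[[j]] <- norm_for(null)
    same <- if (es_obs[j] >= 0) null[null >= 0] else null[null < 0]
    p_raw[j] <- (1 + sum(abs(same) >= abs(es_obs[j]))) / (1 + length(same))
  }
  p_raw <- pmax(p_raw, 1 / (n_perm + 1))

  pooled <- unlist(nes_null)
  fdr <- vapply(seq_along(nes), function(j) {
    v <- nes[j]
    if (v >= 0) {
      num_d <- sum(pooled >= 0)
      num <- if (num_d) sum(pooled >= v) / num_d else 0
      den <- sum(nes >= v) / max(1, sum(nes >= 0))
    } else {
      num_d <- sum(pooled < 0)
      num <- if (num_d) sum(pooled <= v) / num_d else 0
      den <- sum(nes <= v) / max(1, sum(nes < 0))
    }
    min(1, num / den)
  }, numeric(1))
  fdr <- pmax(fdr, 1 / (n_perm * length(nes) + 1))  # zero-FDR floor

  out <- data.frame(set_name = names(hit_idx), method = "GSEA",
                    size = as.integer(sizes), es = es_obs, nes = nes,
                    p_raw = p_raw, p_adj = fdr,
                    direction = sign(es_obs),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_adj, out$p_raw, -abs(out$nes), out$set_name), , drop = FALSE]
}

#' Rank genes by compound connectivity
#'
#' The default ranking metric for running preranked GSEA on a relationship
#' table (which has no expression values): each gene is scored by its number
#' of distinct targeting compounds (its degree into the compound layer).
#' Ties are broken lexicographically by gene symbol so the ranking is
#' deterministic. Orphan genes score 0.
#'
#' @param table a `phyto_relationships` table.
#' @return A named numeric vector, sorted descending.
#' @export
gene_ranking <- function(table) {
  stopifnot(is.data.frame(table), "gene" %in% names(table), nrow(table) > 0)
  genes <- unique(table$gene)
  score <- stats::setNames(numeric(length(genes)), genes)
  if ("compound" %in% names(table)) {
    gc <- unique(table[!is.na(table$compound), c("gene", "compound")])
    cnt <- table(gc$gene)
    score[names(cnt)] <- as.numeric(cnt)
  }
  score[order(-score, names(score))]
}
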