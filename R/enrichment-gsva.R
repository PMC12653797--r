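# Gaussian kernel cumulative density per gene across samples:
# F_i(x_ij) = mean_k Phi((x_ij - x_ik) / h_i), bandwidth h_i = sd_i / 4.
# A zero-variance gene has no usable bandwidth and is assigned the flat
# value 0.5 for every sample (documented degenerate fallback). Because the
# bandwidth is proportional to the per-gene standard deviation, the result
# is invariant to positive affine transforms of a gene's values.
.gsva_kcdf <- function(x) {
  p <- nrow(x); n <- ncol(x)
  z <- matrix(0.5, p, n, dimnames = dimnames(x))
  for (i in seq_len(p)) {
    s <- stats::sd(x[i, ])
    if (is.na(s) || s == 0) next
    h <- s / 4
    # outer(a, a, "-")[j, k] = x_ij - x_ik; average the kernel over k
    z[i, ] <- rowMeans(stats::pnorm(outer(x[i, ], x[i, ], "-") / h))
  }
  z
}

#' Gene set variation analysis scores
#'
#' Unsupervised, per-sample pathway scoring of a gene-by-sample expression
#' matrix. Each gene's values are transformed to Gaussian-kernel cumulative
#' densities across samples (bandwidth = per-gene sd / 4), converted to
#' within-sample ranks, and symmetrized as `|p/2 - rank|^tau` weights. For
#' each set and sample, genes are walked in decreasing kernel-density order;
#' in-set genes add their normalized weight, out-of-set genes subtract
#' `1/(p - |S|)`, and the score is the maximum positive deviation plus the
#' minimum negative deviation of the walk, giving values in `[-1, 1]`.
#' Sets whose intersection with the matrix falls outside
#' `[min_size, max_size]` are excluded.
#'
#' @param expr numeric matrix, genes in rows (unique rownames), samples in
#'   columns (at least 3).
#' @param collection a [read_gmt()] collection (or named list of sets).
#' @param min_size,max_size inclusive set-size window after intersection
#'   (defaults 15 and 500).
#' @param tau rank-weight exponent (default 1).
#' @return A set-by-sample numeric score matrix (0 rows, with a warning,
#'   when no set survives the size filter).
#' @export
gsva_scores <- function(expr, collection, min_size = 15L, max_size = 500L,
                        tau = 1) {
  stopifnot(is.matrix(expr), is.numeric(expr), ncol(expr) >= 3,
            !is.null(rownames(expr)))
  rownames(expr) <- toupper(rownames(expr))
  if (anyDuplicated(rownames(expr))) stop("duplicate gene rows in expr")
  p <- nrow(expr); n <- ncol(expr)

  members <- lapply(collection, function(s) intersect(toupper(s), rownames(expr)))
  sz <- lengths(members)
  keep <- sz >= min_size & sz <= max_size & sz < p
  if (!any(keep)) {
    warning("no gene set within [min_size, max_size] maps onto the matrix")
    return(matrix(numeric(0), 0, n, dimnames = list(NULL, colnames(expr))))
  }
  members <- members[keep]

  z <- .gsva_kcdf(expr)
  r <- apply(z, 2, rank, ties.method = "average")
  w <- abs(p / 2 - r)^tau

  scores <- matrix(NA_real_, length(members), n,
                   dimnames = list(names(members), colnames(expr)))
  for (j in seq_len(n)) {
    ord <- order(-z[, j], rownames(expr))  # decreasing density, stable ties
    wj <- w[ord, j]
    in_set_all <- rownames(expr)[ord]
    for (k in seq_along(members)) {
      hit <- in_set_all %in% members[[k]]
      s <- sum(hit)
      step <- ifelse(hit, wj / sum(wj[hit]), -1 / (p - s))
      if (sum(wj[hit]) == 0) step[hit] <- 1 / s  # flat-weight degenerate case
      walk <- cumsum(step)
      scores[k, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  scores
}
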