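#' Read a GMT gene-set collection
#'
#' Tab-separated GMT dialect: set name, description, then member gene symbols.
#' Member symbols are uppercased and deduplicated; set names must be unique.
#'
#' @param path GMT file path.
#' @param database_label free-text label attached to the collection (e.g.
#'   `"KEGG_2021"`); defaults to the file name.
#' @return A `phyto_genesets` named list of character vectors, with
#'   attributes `description`, `source`, `database_label`.
#' @export
read_gmt <- function(path, database_label = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    nm <- fields[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " (", nm, ") has no members")
    sets[[nm]] <- members
    desc[nm] <- fields[2]
  }
  structure(sets, description = desc,
            source = normalizePath(path, mustWork = TRUE),
            database_label = database_label,
            class = c("phyto_genesets", "list"))
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up (with monotone enforcement, capped at 1) or
#' Bonferroni (`min(1, m p)`). Input order is preserved.
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  stopifnot(is.numeric(p), all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = method)
}

#' Over-representation analysis by the hypergeometric test
#'
#' For each gene set `S` in the collection, with background universe of size
#' `N`, `K = |S` intersect `background|`, query size `n` and overlap
#' `k = |S` intersect `query|`, the raw p-value is the upper hypergeometric
#' tail `P(X >= k)`. Sets with `K < min_size` are excluded before testing
#' (so the multiple-testing family contains only tested sets). Zero p-values
#' cannot arise from the exact tail; values are floored at the smallest
#' positive double as a guard.
#'
#' @param query character vector of query gene symbols (subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param collection a [read_gmt()] collection (or named list of sets).
#' @param min_size minimum in-background set size (default 3).
#' @param correction `"BH"` or `"bonferroni"`.
#' @return A data frame of `EnrichmentRecord`s ordered by `p_raw`: set_name,
#'   method, overlap_k, set_size, query_size, background_size, p_raw, p_adj.
#' @export
ora <- function(query, background, collection, min_size = 3L,
                correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  if (!length(query)) stop("empty query")
  extra <- setdiff(query, background)
  if (length(extra))
    stop("query genes missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  N <- length(background)
  n <- length(query)

  keep <- vapply(collection, function(s)
    sum(toupper(s) %in% background) >= min_size, logical(1))
  tested <- collection[keep]
  if (!length(tested)) {
    warning("no gene set meets min_size within the background")
    return(data.frame(set_name = character(0), method = character(0),
                      overlap_k = integer(0), set_size = integer(0),
                      query_size = integer(0), background_size = integer(0),
                      p_raw = numeric(0), p_adj = numeric(0)))
  }
  K <- vapply(tested, function(s) sum(toupper(s) %in% background), integer(1))
  k <- vapply(tested, function(s) sum(toupper(s) %in% query), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  out <- data.frame(set_name = names(tested), method = "ORA",
                    overlap_k = k, set_size = K,
                    query_size = n, background_size = N,
                    p_raw = p, p_adj = adjust_pvalues(p, correction),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_raw, out$set_name), , drop = FALSE]
}
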