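#' Specification for a synthetic relationship fixture
#'
#' Defaults mirror the structure of the reference test dataset this package is
#' benchmarked on: 111 genes, 32 compounds and 3 plants, with 32.4% of
#' compounds shared across plants, 28.7% of genes targeted by more than one
#' compound, and 8.1% orphan genes. Counts are placed exactly (rounded
#' targets), not drawn Bernoulli-style, so a fixed seed yields byte-identical
#' files and deterministic statistics.
#'
#' A designated "common core" of genes is guaranteed to be targeted by
#' compounds from every plant, and no other gene is: one core compound carries
#' all plants and only core genes may link to it, while every other gene is
#' assigned a forbidden plant and only links compounds avoiding it. This gives
#' shared-target analysis an exact, recorded ground truth.
#'
#' @param n_genes,n_compounds,n_plants entity counts.
#' @param cross_plant_compound_fraction fraction of compounds appearing in
#'   more than one plant.
#' @param multi_compound_gene_fraction fraction of genes targeted by more than
#'   one compound.
#' @param orphan_gene_fraction fraction of genes with no compound.
#' @param common_core_size number of genes targeted by all plants.
#' @param seed integer seed; drives every random choice.
#' @return A `phyto_fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 111L, n_compounds = 32L, n_plants = 3L,
                         cross_plant_compound_fraction = 0.324,
                         multi_compound_gene_fraction = 0.287,
                         orphan_gene_fraction = 0.081,
                         common_core_size = 10L,
                         seed = 1L) {
  stopifnot(n_genes > 0, n_compounds > 0, n_plants > 0,
            cross_plant_compound_fraction >= 0, cross_plant_compound_fraction <= 1,
            multi_compound_gene_fraction >= 0, multi_compound_gene_fraction <= 1,
            orphan_gene_fraction >= 0, orphan_gene_fraction <= 1,
            common_core_size >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_compounds = as.integer(n_compounds),
                 n_plants = as.integer(n_plants),
                 cross_plant_compound_fraction = cross_plant_compound_fraction,
                 multi_compound_gene_fraction = multi_compound_gene_fraction,
                 orphan_gene_fraction = orphan_gene_fraction,
                 common_core_size = as.integer(common_core_size),
                 seed = as.integer(seed)),
            class = "phyto_fixture_spec")
}

#' Generate a synthetic relationship table with recorded ground truth
#'
#' Emits a relationship CSV in the dialect [read_relationships()] consumes,
#' plus a JSON truth file, and returns both paths together with the truth
#' list. Orphan, cross-plant and multi-compound counts hit the rounded
#' fraction targets exactly; remaining links are drawn uniformly under the
#' structural constraints described in [fixture_spec()].
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return list with `csv` and `truth_json` paths, the cleaned `table`, and
#'   the `truth` list (orphan genes, cross-plant compounds, core genes).
#' @export
generate_relationships <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "phyto_fixture_spec"))
  n_orphan <- round(spec$orphan_gene_fraction * spec$n_genes)
  n_multi <- round(spec$multi_compound_gene_fraction * spec$n_genes)
  n_cross <- round(spec$cross_plant_compound_fraction * spec$n_compounds)
  n_conn <- spec$n_genes - n_orphan
  if (n_conn < 1) stop("infeasible: every gene would be an orphan")
  if (n_multi > n_conn)
    stop("infeasible: more multi-compound genes than connected genes (",
         n_multi, " > ", n_conn, ")")
  if (spec$common_core_size > n_conn)
    stop("infeasible: common core larger than connected gene count")
  if (spec$n_plants < 2 && n_cross > 0)
    stop("infeasible: cross-plant compounds require at least 2 plants")
  if (spec$common_core_size > 0 && n_cross < 1 && spec$n_plants > 1)
    stop("infeasible: an all-plants core needs at least one cross-plant compound")

  set.seed(spec$seed)
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  compounds <- sprintf("C%02d", seq_len(spec$n_compounds))
  plants <- sprintf("Plant_%s", LETTERS[seq_len(spec$n_plants)])

  # plant coverage per compound; compound 1 is the all-plants core compound
  plant_sets <- vector("list", spec$n_compounds)
  names(plant_sets) <- compounds
  if (spec$n_plants >= 2 && n_cross >= 1) {
    plant_sets[[1]] <- plants
    extra_cross <- if (n_cross > 1) 1L + seq_len(n_cross - 1L) else integer(0)
    for (i in extra_cross) plant_sets[[i]] <- sort(sample(plants, 2L))
    for (i in setdiff(seq_len(spec$n_compounds), c(1L, extra_cross)))
      plant_sets[[i]] <- sample(plants, 1L)
  } else {
    for (i in seq_len(spec$n_compounds)) plant_sets[[i]] <- sample(plants, 1L)
  }
  core_compound <- if (spec$common_core_size > 0 && spec$n_plants >= 2)
    compounds[1] else NA_character_

  perm <- sample(genes)
  orphans <- sort(perm[seq_len(n_orphan)])
  connected <- perm[n_orphan + seq_len(n_conn)]
  core <- sort(sample(connected, spec$common_core_size))
  multi <- if (n_multi > 0) {
    # keep at least one core gene unconstrained-and-multi so any uncovered
    # compound can be attached without breaking exact counts
    forced <- if (length(core)) core[1] else character(0)
    c(forced, sample(setdiff(connected, forced), n_multi - length(forced)))
  } else character(0)

  links <- list()  # gene -> character vector of compounds
  non_core_pool <- setdiff(compounds, core_compound)
  for (g in connected) {
    if (g %in% core) {
      cs <- core_compound
      if (g %in% multi) {
        k <- sample(1:3, 1L)
        cs <- c(cs, sample(non_core_pool, min(k, length(non_core_pool))))
      }
    } else {
      forbidden <- sample(plants, 1L)
      allowed <- non_core_pool[!vapply(plant_sets[non_core_pool],
                                       function(p) forbidden %in% p, logical(1))]
      if (!length(allowed)) allowed <- non_core_pool  # degenerate tiny specs
      if (g %in% multi) {
        k <- min(sample(2:5, 1L), length(allowed))
        k <- max(k, min(2L, length(allowed)))
        cs <- sample(allowed, k)
      } else {
        cs <- sample(allowed, 1L)
      }
    }
    links[[g]] <- cs
  }

  covered <- unique(unlist(links))
  for (cmp in setdiff(compounds, covered)) {
    candidates <- intersect(multi, connected)
    # core multi genes are always safe; otherwise any multi gene whose
    # compound plant-union still misses a plant after adding cmp
    pick <- NULL
    for (g in sample(candidates)) {
      if (g %in% core) { pick <- g; break }
      union_p <- unique(unlist(plant_sets[c(links[[g]], cmp)]))
      if (length(union_p) < spec$n_plants) { pick <- g; break }
    }
    if (is.null(pick)) stop("infeasible: cannot cover compound ", cmp,
                            " without breaking the all-plants core")
    links[[pick]] <- c(links[[pick]], cmp)
  }

  rows <- list()
  for (g in sort(connected)) for (cmp in sort(unique(links[[g]])))
    for (p in plant_sets[[cmp]])
      rows[[length(rows) + 1L]] <- c(g, cmp, p)
  for (g in orphans) rows[[length(rows) + 1L]] <- c(g, "", "")
  m <- do.call(rbind, rows)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "relationships.csv")
  con <- file(csv, open = "wb")
  writeLines(c("gene,compound,plant",
               apply(m, 1, paste, collapse = ",")), con, sep = "\n")
  close(con)

  truth <- list(seed = spec$seed,
                n_genes = spec$n_genes, n_compounds = spec$n_compounds,
                n_plants = spec$n_plants,
                orphan_genes = orphans,
                cross_plant_compounds = sort(compounds[vapply(plant_sets, length, 1L) > 1]),
                multi_compound_genes = sort(multi),
                common_core_genes = core,
                core_compound = core_compound)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  table <- clean_relationships(read_relationships(csv))
  list(csv = csv, truth_json = truth_json, table = table, truth = truth)
}

#' Sample a gene set concentrated at the top of a ranking
#'
#' Members are drawn without replacement with weight
#' `exp(-concentration * (position - 1) / length(ranking))`, so larger
#' `concentration` packs the set more tightly into the top of the list.
#'
#' @param ranked_genes character vector of genes, best first.
#' @param size set size.
#' @param concentration nonnegative top-bias strength (0 = uniform).
#' @param seed integer seed.
#' @return Character vector of member genes.
#' @export
planted_top_set <- function(ranked_genes, size, concentration = 10, seed = 1L) {
  stopifnot(size <= length(ranked_genes), concentration >= 0)
  set.seed(seed)
  n <- length(ranked_genes)
  w <- exp(-concentration * (seq_len(n) - 1) / n)
  sample(ranked_genes, size, prob = w)
}

#' Generate a GMT gene-set collection with planted positives
#'
#' Background sets are uniform draws from the universe; planted sets are
#' supplied verbatim (e.g. from [planted_top_set()]) so enrichment engines
#' have known positives to recover.
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of background sets.
#' @param size_range inclusive background set-size range.
#' @param planted named list of character vectors written as-is.
#' @param path output GMT path.
#' @param seed integer seed.
#' @return `path`, invisibly; the file is valid input for [read_gmt()].
#' @export
generate_gmt <- function(universe, n_sets = 15L, size_range = c(10L, 40L),
                         planted = list(), path = tempfile(fileext = ".gmt"),
                         seed = 1L) {
  stopifnot(length(universe) > 0, n_sets >= 0,
            size_range[1] >= 1, size_range[2] >= size_range[1])
  if (size_range[2] > length(universe))
    stop("set size range exceeds universe size")
  for (p in planted) if (length(p) > length(universe))
    stop("planted set larger than universe")
  set.seed(seed)
  lines <- character(0)
  if (length(planted)) {
    nms <- names(planted)
    if (is.null(nms) || any(!nzchar(nms)))
      nms <- sprintf("PLANTED_%d", seq_along(planted))
    for (i in seq_along(planted))
      lines <- c(lines, paste(c(nms[i], "planted positive set",
                                toupper(planted[[i]])), collapse = "\t"))
  }
  if (n_sets > 0) {
    sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
    for (i in seq_len(n_sets))
      lines <- c(lines, paste(c(sprintf("BG_%02d", i), "background set",
                                toupper(sample(universe, sizes[i]))),
                              collapse = "\t"))
  }
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Generate a synthetic expression matrix with planted set shifts
#'
#' Baseline is i.i.d. standard Gaussian per gene and sample. Each planted set
#' is shifted by `delta` in the samples of `group` level 2, giving GSVA a
#' known subgroup signal. `delta != 0` requires an explicit `group`.
#'
#' @param genes character vector of gene symbols (rows).
#' @param n_samples number of samples (columns), at least 3.
#' @param planted_sets named list of gene vectors to shift.
#' @param delta mean shift applied in the second group.
#' @param group optional factor/vector of length `n_samples` with 2 levels.
#' @param path output TSV path (genes in rows, header = sample ids).
#' @param seed integer seed.
#' @return list with `path`, the numeric `matrix`, and `group`.
#' @export
generate_expression <- function(genes, n_samples, planted_sets = list(),
                                delta = 0, group = NULL,
                                path = tempfile(fileext = ".tsv"), seed = 1L) {
  stopifnot(n_samples >= 3, length(genes) > 0)
  if (delta != 0 && is.null(group))
    stop("a nonzero delta requires an explicit sample group")
  set.seed(seed)
  x <- matrix(stats::rnorm(length(genes) * n_samples), nrow = length(genes),
              dimnames = list(toupper(genes),
                              sprintf("S%02d", seq_len(n_samples))))
  if (!is.null(group)) {
    group <- as.factor(group)
    stopifnot(length(group) == n_samples, nlevels(group) == 2L)
    shifted <- group == levels(group)[2]
    for (s in planted_sets) {
      idx <- intersect(toupper(s), rownames(x))
      x[idx, shifted] <- x[idx, shifted] + delta
    }
  }
  con <- file(path, open = "wb")
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con, sep = "\n")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], sprintf("%.12g", x[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con, sep = "\n")
  close(con)
  list(path = path, matrix = x, group = group)
}
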