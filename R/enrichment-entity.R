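#' Per-entity enrichment streams
#'
#' Runs enrichment independently for three levels of the relationship table:
#' globally (all genes), per compound (its distinct target genes) and per
#' plant (the union of its compounds' target genes). Each bundle is its own
#' multiple-testing family, matching per-entity reporting. Entities whose
#' gene list is smaller than `min_genes` are flagged `skipped` (never dropped
#' silently). Orphan genes appear only in the global bundle.
#'
#' @param table a `phyto_relationships` table.
#' @param collection a [read_gmt()] collection.
#' @param background gene universe for ORA; defaults to all genes in `table`.
#' @param method `"ORA"` (default) or `"GSEA"` (compound-connectivity ranking
#'   restricted to the bundle's genes).
#' @param min_genes smallest gene list worth testing (default 3).
#' @param min_size minimum gene-set size (default 3).
#' @param correction multiple-testing correction for ORA.
#' @param n_perm,seed permutation settings for GSEA.
#' @return A list of `phyto_bundle` lists: `entity`, `type`
#'   (global/compound/plant), `genes`, `skipped`, `records` (data frame).
#' @export
entity_enrichment <- function(table, collection, background = NULL,
                              method = c("ORA", "GSEA"), min_genes = 3L,
                              min_size = 3L, correction = "BH",
                              n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (is.null(background)) background <- unique(table$gene)

  has_c <- "compound" %in% names(table)
  gc <- if (has_c) unique(table[!is.na(table$compound), c("gene", "compound")])
        else data.frame(gene = character(0), compound = character(0))
  compound_genes <- if (nrow(gc)) split(gc$gene, gc$compound) else list()

  plant_genes <- list()
  if (has_c && "plant" %in% names(table)) {
    cp <- unique(table[!is.na(table$compound) & !is.na(table$plant),
                       c("compound", "plant")])
    for (p in unique(cp$plant)) {
      cs <- cp$compound[cp$plant == p]
      plant_genes[[p]] <- sort(unique(unlist(compound_genes[cs])))
    }
  }

  run_one <- function(entity, type, genes, idx) {
    genes <- sort(unique(genes))
    skipped <- length(genes) < min_genes
    records <- if (skipped) NULL else switch(method,
      ORA = ora(genes, background, collection, min_size = min_size,
                correction = correction),
      GSEA = {
        sub <- table[table$gene %in% genes, , drop = FALSE]
        gsea_preranked(gene_ranking(sub), collection, n_perm = n_perm,
                       min_size = min_size, seed = seed + idx)
      })
    structure(list(entity = entity, type = type, genes = genes,
                   skipped = skipped, records = records),
              class = "phyto_bundle")
  }

  bundles <- list(run_one("global", "global", unique(table$gene), 0L))
  i <- 0L
  for (cmp in sort(names(compound_genes))) {
    i <- i + 1L
    bundles[[length(bundles) + 1L]] <-
      run_one(cmp, "compound", compound_genes[[cmp]], i)
  }
  for (p in sort(names(plant_genes))) {
    i <- i + 1L
    bundles[[length(bundles) + 1L]] <-
      run_one(p, "plant", plant_genes[[p]], i)
  }
  names(bundles) <- vapply(bundles, `[[`, "", "entity")
  bundles
}

#' Shared-target set algebra across plants
#'
#' Maps each plant to its target-gene set (the union over its compounds'
#' distinct gene targets) and reports the genes targeted by all plants, the
#' genes unique to each plant, and the pairwise overlap matrix.
#'
#' @param table a `phyto_relationships` table with at least 2 plants.
#' @return A list: `plant_targets` (named list), `all_plants` (character),
#'   `unique_per_plant` (named list), `pairwise` (integer matrix).
#' @export
shared_target_analysis <- function(table) {
  stopifnot(is.data.frame(table))
  if (!all(c("compound", "plant") %in% names(table)))
    stop("shared-target analysis needs compound and plant columns")
  cp <- unique(table[!is.na(table$compound) & !is.na(table$plant),
                     c("compound", "plant")])
  plants <- sort(unique(cp$plant))
  if (length(plants) < 2)
    stop("shared-target analysis requires at least 2 plants")
  gc <- unique(table[!is.na(table$compound), c("gene", "compound")])
  targets <- lapply(plants, function(p) {
    cs <- cp$compound[cp$plant == p]
    sort(unique(gc$gene[gc$compound %in% cs]))
  })
  names(targets) <- plants

  all_plants <- Reduce(intersect, targets)
  unique_per_plant <- lapply(plants, function(p)
    setdiff(targets[[p]], unique(unlist(targets[setdiff(plants, p)]))))
  names(unique_per_plant) <- plants
  pairwise <- outer(plants, plants, Vectorize(function(a, b)
    length(intersect(targets[[a]], targets[[b]]))))
  dimnames(pairwise) <- list(plants, plants)

  list(plant_targets = targets, all_plants = sort(all_plants),
       unique_per_plant = unique_per_plant, pairwise = pairwise)
}
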