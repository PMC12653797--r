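# Config schema: key -> list(type, default). NULL default = optional input.
.config_schema <- function() list(
  relationships = list(type = "character", default = NULL, required = TRUE),
  gene_sets = list(type = "character", default = character(0)),
  expression = list(type = "character", default = NULL),
  preranked = list(type = "character", default = NULL),
  run_ora = list(type = "logical", default = TRUE),
  run_gsea = list(type = "logical", default = TRUE),
  run_gsva = list(type = "logical", default = TRUE),
  n_perm = list(type = "numeric", default = 1000),
  n_random = list(type = "numeric", default = 1000),
  min_set_size = list(type = "numeric", default = 3),
  gsva_min_size = list(type = "numeric", default = 15),
  gsva_max_size = list(type = "numeric", default = 500),
  fdr_threshold = list(type = "numeric", default = 0.05),
  nes_threshold = list(type = "numeric", default = 1.0),
  gsea_fdr_threshold = list(type = "numeric", default = 0.25),
  hub_degree = list(type = "numeric", default = 5),
  resolution = list(type = "numeric", default = 1),
  correction = list(type = "character", default = "BH"),
  weight_mode = list(type = "character", default = "unit"),
  seed = list(type = "numeric", default = NULL),
  output_root = list(type = "character", default = "phytonet_run"),
  overwrite = list(type = "logical", default = FALSE),
  skip_figures = list(type = "logical", default = FALSE))

#' Validate a YAML run configuration
#'
#' Fail-closed parsing: unknown keys are rejected (with a nearest-match
#' suggestion) so misspelled parameters are never silently ignored; type
#' mismatches name the key and expected type; defaults are filled in and
#' echoed back. Default parameter values are 1000 permutations, 1000
#' randomized networks, minimum set size 3 (ORA/GSEA) and 15-500 (GSVA),
#' FDR 0.05, |NES| 1.0 with GSEA FDR 0.25, and hub degree 5.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A `phyto_config` list with every schema key populated.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  schema <- .config_schema()

  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      near <- agrep(k, names(schema), max.distance = 2, value = TRUE)
      if (length(near)) sprintf("%s (did you mean '%s'?)", k, near[1]) else k
    }, character(1))
    stop("unknown config key(s): ", paste(hints, collapse = ", "))
  }
  cfg <- list()
  for (key in names(schema)) {
    spec <- schema[[key]]
    val <- if (key %in% names(raw)) raw[[key]] else spec$default
    if (is.null(val)) {
      if (isTRUE(spec$required))
        stop("config key '", key, "' is required")
      cfg[key] <- list(NULL)
      next
    }
    ok <- switch(spec$type,
                 character = is.character(val),
                 numeric = is.numeric(val),
                 logical = is.logical(val))
    if (!ok) stop("config key '", key, "' must be ", spec$type,
                  ", got ", class(val)[1])
    cfg[[key]] <- val
  }
  if (!cfg$correction %in% c("BH", "bonferroni"))
    stop("config key 'correction' must be 'BH' or 'bonferroni'")
  if (!cfg$weight_mode %in% c("unit", "frequency"))
    stop("config key 'weight_mode' must be 'unit' or 'frequency'")
  structure(cfg, class = "phyto_config")
}
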