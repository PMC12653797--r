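#' Default validation rules for relationship tables
#'
#' Length windows are inclusive character counts measured after trimming
#' surrounding whitespace. `max_file_mb` caps input size before a size warning
#' is raised, `max_invalid_fraction` is the proportion of rows failing at least
#' one rule above which the whole file is flagged, and
#' `max_relationships_per_entity` caps how many rows any single gene, compound
#' or plant may occupy before being flagged as a likely data error.
#'
#' @param gene_len integer length-2 vector, inclusive gene-symbol length range.
#' @param compound_len inclusive compound-name length range.
#' @param plant_len inclusive plant-name length range.
#' @param max_file_mb file size (MiB) above which a warning is recorded.
#' @param max_invalid_fraction invalid-row proportion above which a warning is
#'   recorded.
#' @param max_relationships_per_entity per-entity row-count cap.
#' @return A named list of class `phyto_rules`.
#' @export
#' @examples
#' validation_rules()$gene_len
validation_rules <- function(gene_len = c(2L, 50L),
                             compound_len = c(3L, 100L),
                             plant_len = c(1L, 150L),
                             max_file_mb = 100,
                             max_invalid_fraction = 0.5,
                             max_relationships_per_entity = 1000L) {
  stopifnot(length(gene_len) == 2L, gene_len[1] <= gene_len[2],
            length(compound_len) == 2L, compound_len[1] <= compound_len[2],
            length(plant_len) == 2L, plant_len[1] <= plant_len[2],
            max_file_mb > 0, max_invalid_fraction > 0,
            max_relationships_per_entity > 0)
  structure(list(gene_len = as.integer(gene_len),
                 compound_len = as.integer(compound_len),
                 plant_len = as.integer(plant_len),
                 max_file_mb = max_file_mb,
                 max_invalid_fraction = max_invalid_fraction,
                 max_relationships_per_entity = as.integer(max_relationships_per_entity),
                 version = "1"),
            class = "phyto_rules")
}

# Detect the delimiter of a header line among comma / semicolon / tab.
.detect_sep <- function(line) {
  counts <- vapply(c(",", ";", "\t"), function(s)
    lengths(regmatches(line, gregexpr(s, line, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) return(",")
  c(",", ";", "\t")[which.max(counts)]
}

# Map raw header names onto gene/compound/plant after lowercase + trim.
.match_columns <- function(nms) {
  norm <- tolower(trimws(nms))
  idx <- match(c("gene", "compound", "plant"), norm)
  stats::setNames(idx, c("gene", "compound", "plant"))
}

#' Read a relationship CSV preserving raw cell text
#'
#' Parses a relationship table with automatic delimiter detection (comma,
#' semicolon or tab) and case-insensitive matching of the `gene`, `compound`
#' and `plant` columns. Cell text is preserved verbatim; cleaning is a
#' separate, explicit pass ([clean_relationships()]) so that validation and
#' cleaning can both be audited.
#'
#' @param path path to a UTF-8 CSV/TSV file with a header row.
#' @return A data frame of raw character columns (subset of `gene`,
#'   `compound`, `plant`; a column absent from the file is absent from the
#'   result) with attributes `source_path` and `byte_size`.
#' @export
read_relationships <- function(path) {
  if (!file.exists(path)) stop("relationship file not found: ", path)
  byte_size <- file.size(path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    raw <- data.frame(matrix(character(0), nrow = 0, ncol = 0))
  } else {
    sep <- .detect_sep(lines[[1]])
    dt <- data.table::fread(text = lines, sep = sep, header = TRUE,
                            colClasses = "character", strip.white = FALSE,
                            fill = TRUE, na.strings = NULL,
                            data.table = FALSE, showProgress = FALSE)
    idx <- .match_columns(names(dt))
    keep <- idx[!is.na(idx)]
    raw <- dt[, keep, drop = FALSE]
    names(raw) <- names(keep)
  }
  attr(raw, "source_path") <- normalizePath(path, mustWork = TRUE)
  attr(raw, "byte_size") <- as.numeric(byte_size)
  class(raw) <- c("phyto_raw", class(raw))
  raw
}

# Row/field-level rule violations. Returns a data frame
# (row, field, rule, message); zero-row when nothing fails.
.scan_violations <- function(raw, rules) {
  errs <- list()
  add <- function(rows, field, rule, message) {
    if (length(rows))
      errs[[length(errs) + 1L]] <<- data.frame(
        row = rows, field = field, rule = rule, message = message,
        stringsAsFactors = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) return(data.frame(row = integer(0), field = character(0),
                                 rule = character(0), message = character(0)))
  if ("gene" %in% names(raw)) {
    g <- trimws(raw$gene)
    miss <- which(is.na(g) | !nzchar(g))
    add(miss, "gene", "gene_missing", "mandatory gene value is empty")
    len <- nchar(g)
    bad <- setdiff(which(len < rules$gene_len[1] | len > rules$gene_len[2]), miss)
    add(bad, "gene", "gene_length",
        sprintf("gene length outside %d-%d", rules$gene_len[1], rules$gene_len[2]))
  }
  for (fld in c("compound", "plant")) {
    if (!fld %in% names(raw)) next
    v <- trimws(raw[[fld]])
    present <- which(!is.na(v) & nzchar(v))
    rng <- rules[[paste0(fld, "_len")]]
    len <- nchar(v)
    bad <- intersect(present, which(len < rng[1] | len > rng[2]))
    add(bad, fld, paste0(fld, "_length"),
        sprintf("%s length outside %d-%d", fld, rng[1], rng[2]))
  }
  if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(0), field = character(0),
               rule = character(0), message = character(0))
}

#' Validate a raw relationship table
#'
#' Applies the field-level rules in `rules` and records every violation with
#' its row and field. Validation never mutates the data. The overall status is
#' `"fail"` only when gene data is structurally absent (no gene column, or no
#' rows at all); oversized files, majority-invalid content and over-connected
#' entities downgrade the status to `"warn"`.
#'
#' @param raw a table from [read_relationships()].
#' @param rules a [validation_rules()] object.
#' @return A `phyto_validation` list: `status` (pass/warn/fail), `errors`
#'   (data frame row/field/rule/message), `warnings` (character),
#'   `invalid_fraction`, `duplicate_count`, `n_rows`.
#' @export
validate_relationships <- function(raw, rules = validation_rules()) {
  stopifnot(is.data.frame(raw))
  warnings <- character(0)
  n <- nrow(raw)
  structural_fail <- !("gene" %in% names(raw)) || n == 0L

  errors <- .scan_violations(raw, rules)
  invalid_fraction <- if (n > 0) length(unique(errors$row)) / n else 0

  byte_size <- attr(raw, "byte_size")
  if (!is.null(byte_size) && byte_size > rules$max_file_mb * 1024^2)
    warnings <- c(warnings, sprintf(
      "file size %.1f MiB exceeds %.0f MiB", byte_size / 1024^2, rules$max_file_mb))
  if (invalid_fraction > rules$max_invalid_fraction)
    warnings <- c(warnings, sprintf(
      "%.1f%% of rows invalid (threshold %.0f%%)",
      100 * invalid_fraction, 100 * rules$max_invalid_fraction))

  for (fld in intersect(c("gene", "compound", "plant"), names(raw))) {
    v <- trimws(raw[[fld]])
    v <- v[!is.na(v) & nzchar(v)]
    if (!length(v)) next
    tab <- table(v)
    over <- names(tab)[tab > rules$max_relationships_per_entity]
    for (ent in over)
      warnings <- c(warnings, sprintf(
        "%s '%s' appears in %d rows (threshold %d)",
        fld, ent, tab[[ent]], rules$max_relationships_per_entity))
  }

  dup <- if (n > 0) sum(duplicated(raw)) else 0L
  status <- if (structural_fail) "fail" else if (length(warnings)) "warn" else "pass"
  structure(list(status = status, errors = errors, warnings = warnings,
                 invalid_fraction = invalid_fraction, duplicate_count = dup,
                 n_rows = n, rules = rules),
            class = "phyto_validation")
}

#' @export
print.phyto_validation <- function(x, ...) {
  cat(sprintf("Relationship validation: %s\n", toupper(x$status)))
  cat(sprintf("  rows: %d | invalid fraction: %.3f | duplicates: %d\n",
              x$n_rows, x$invalid_fraction, x$duplicate_count))
  if (nrow(x$errors)) cat(sprintf("  %d rule violations (%s)\n", nrow(x$errors),
                                  paste(unique(x$errors$rule), collapse = ", ")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Whitespace normalization: trim ends, collapse internal runs to one space.
.norm_ws <- function(x) gsub("[[:space:]]+", " ", trimws(x))

# Compound cleaning keeps letters, digits, space and _ ( ) + ' -
.clean_compound <- function(x) .norm_ws(gsub("[^A-Za-z0-9 _()+'-]", "", x))

#' Clean a raw relationship table
#'
#' Normalizes whitespace, uppercases gene symbols, strips disallowed
#' characters from compound names (anything outside letters, digits, space and
#' `_()+'-`), drops rows with an empty gene, removes exact post-cleaning
#' duplicates, and replaces blank optional values with `NA` so that "no plant
#' layer" and "blank plant" stay distinguishable.
#'
#' @param raw a table from [read_relationships()] (validation, if wanted,
#'   should run first on the raw table).
#' @return A `phyto_relationships` data frame with columns among `gene`,
#'   `compound`, `plant`, and attributes `duplicate_count`, `dropped_rows`
#'   (empty-gene rows removed) and `provenance`.
#' @export
clean_relationships <- function(raw) {
  stopifnot(is.data.frame(raw))
  if (!"gene" %in% names(raw)) stop("no gene column: nothing to clean")
  out <- data.frame(gene = toupper(.norm_ws(raw$gene)), stringsAsFactors = FALSE)
  if ("compound" %in% names(raw)) out$compound <- .clean_compound(raw$compound)
  if ("plant" %in% names(raw)) out$plant <- .norm_ws(raw$plant)
  for (fld in setdiff(names(out), "gene"))
    out[[fld]][is.na(out[[fld]]) | !nzchar(out[[fld]])] <- NA_character_

  keep <- !is.na(out$gene) & nzchar(out$gene)
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  dup <- duplicated(out)
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop("no usable rows remain after cleaning")

  attr(out, "duplicate_count") <- n_dup
  attr(out, "dropped_rows") <- dropped
  attr(out, "provenance") <- list(
    source_path = attr(raw, "source_path"),
    cleaned_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rule_version = "1")
  class(out) <- c("phyto_relationships", "data.frame")
  out
}

#' Relationship-table summary statistics
#'
#' Entity-level descriptive statistics of a cleaned table: mean distinct genes
#' per compound, the fraction of compounds shared by more than one plant, the
#' fraction of genes targeted by more than one compound, the fraction of
#' orphan genes (no compound in any row), per-entity row counts, and the chain
#' ratio — the fraction of genes reachable from at least one plant through a
#' compound. Plant-dependent fields are `NA` when the table has no plant
#' layer.
#'
#' @param table a `phyto_relationships` table.
#' @return A `phyto_stats` list.
#' @export
relationship_stats <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0, "gene" %in% names(table))
  has_c <- "compound" %in% names(table)
  has_p <- "plant" %in% names(table)
  genes <- unique(table$gene)

  per_entity <- list(gene = table(table$gene))
  if (has_c) per_entity$compound <-
    table(table$compound[!is.na(table$compound)])
  if (has_p) per_entity$plant <- table(table$plant[!is.na(table$plant)])

  if (has_c) {
    gc <- unique(table[!is.na(table$compound), c("gene", "compound")])
    compounds <- unique(gc$compound)
    genes_per_compound <- if (length(compounds))
      mean(tapply(gc$gene, gc$compound, function(g) length(unique(g)))) else NA_real_
    multi <- tapply(gc$compound, gc$gene, function(cc) length(unique(cc)) > 1)
    multi_frac <- sum(unlist(multi)) / length(genes)
    orphan <- setdiff(genes, gc$gene)
    orphan_frac <- length(orphan) / length(genes)
  } else {
    genes_per_compound <- NA_real_
    multi_frac <- NA_real_
    orphan <- genes
    orphan_frac <- 1
  }

  if (has_c && has_p) {
    cp <- unique(table[!is.na(table$compound) & !is.na(table$plant),
                       c("compound", "plant")])
    all_c <- unique(table$compound[!is.na(table$compound)])
    n_plants_per_c <- tapply(cp$plant, cp$compound, function(p) length(unique(p)))
    cross <- names(n_plants_per_c)[n_plants_per_c > 1]
    cross_frac <- length(cross) / length(all_c)
    # chain ratio: genes linked to a compound that itself has a plant
    chained_c <- unique(cp$compound)
    gc <- unique(table[!is.na(table$compound), c("gene", "compound")])
    chain_genes <- unique(gc$gene[gc$compound %in% chained_c])
    chain_ratio <- length(chain_genes) / length(genes)
  } else {
    cross_frac <- NA_real_
    chain_ratio <- NA_real_
    cross <- character(0)
  }

  structure(list(
    n_rows = nrow(table), n_genes = length(genes),
    n_compounds = if (has_c) length(unique(table$compound[!is.na(table$compound)])) else 0L,
    n_plants = if (has_p) length(unique(table$plant[!is.na(table$plant)])) else 0L,
    genes_per_compound_mean = genes_per_compound,
    cross_plant_compound_fraction = cross_frac,
    multi_compound_gene_fraction = multi_frac,
    orphan_gene_fraction = orphan_frac,
    orphan_genes = sort(orphan),
    cross_plant_compounds = sort(cross),
    chain_ratio = chain_ratio,
    per_entity_relationship_counts = per_entity),
    class = "phyto_stats")
}

#' @export
print.phyto_stats <- function(x, ...) {
  cat(sprintf("Relationships: %d rows | %d genes, %d compounds, %d plants\n",
              x$n_rows, x$n_genes, x$n_compounds, x$n_plants))
  cat(sprintf("  genes/compound (mean): %.2f\n", x$genes_per_compound_mean))
  cat(sprintf("  cross-plant compounds: %.1f%% | multi-compound genes: %.1f%% | orphan genes: %.1f%%\n",
              100 * x$cross_plant_compound_fraction,
              100 * x$multi_compound_gene_fraction,
              100 * x$orphan_gene_fraction))
  invisible(x)
}

#' Serialize a validation report to JSON and log lines
#'
#' @param report a `phyto_validation` object.
#' @param json_path output JSON path.
#' @param log_path optional log file appended with human-readable lines
#'   (the same lines are echoed to the console).
#' @return `json_path`, invisibly.
#' @export
write_validation_report <- function(report, json_path, log_path = NULL) {
  stopifnot(inherits(report, "phyto_validation"))
  payload <- list(status = report$status,
                  n_rows = report$n_rows,
                  invalid_fraction = report$invalid_fraction,
                  duplicate_count = report$duplicate_count,
                  errors = report$errors,
                  warnings = report$warnings)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  lines <- c(sprintf("[validation] status=%s rows=%d invalid=%.3f duplicates=%d",
                     report$status, report$n_rows, report$invalid_fraction,
                     report$duplicate_count),
             sprintf("[validation] warning: %s", report$warnings))
  message(paste(lines, collapse = "\n"))
  if (!is.null(log_path)) cat(lines, file = log_path, sep = "\n", append = TRUE)
  invisible(json_path)
}
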