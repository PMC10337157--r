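#' Read a count matrix with sample metadata
#'
#' Loads gene-level raw counts from TSV (first column = gene id, remaining
#' columns = samples) or MatrixMarket (`<path>.mtx` accompanied by
#' `<path>.rows.tsv` and `<path>.cols.tsv` holding gene and sample ids,
#' one per line). Counts must be nonnegative integers; every sample must
#' appear in `metadata` with an age.
#'
#' @param path Path to the counts file.
#' @param metadata Tibble with columns `sample_id`, `species`, `sex`,
#'   `tissue`, `age_months` (or a path to such a TSV).
#' @param format `"tsv"` or `"mtx"`.
#' @return A validated `count_matrix`: list with `counts` (wide tibble),
#'   `metadata`, and `all_zero` (ids of genes with all-zero counts, retained
#'   but flagged).
#' @export
read_counts <- function(path, metadata, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
  }
  if (format == "tsv") {
    counts <- readr::read_tsv(path, show_col_types = FALSE)
    names(counts)[1] <- "gene_id"
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(paste0(path, ".rows.tsv"))
    cols <- readLines(paste0(path, ".cols.tsv"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
      abort("MTX index files do not match matrix dimensions",
            class = "agesig_input_error")
    }
    dimnames(m) <- list(rows, cols)
    counts <- counts_to_tibble(m)
  }
  as_count_matrix(counts, metadata)
}

#' Assemble and validate a count matrix object
#'
#' @param counts Wide tibble: `gene_id` plus one integer column per sample.
#' @param metadata Per-sample tibble with `sample_id` and `age_months`.
#' @return A `count_matrix` list (`counts`, `metadata`, `all_zero`).
#' @export
as_count_matrix <- function(counts, metadata) {
  counts <- as_tibble(counts)
  if (anyDuplicated(counts$gene_id)) {
    abort("duplicate gene ids in counts", class = "agesig_input_error")
  }
  samp <- setdiff(names(counts), "gene_id")
  if (anyDuplicated(samp)) {
    abort("duplicate sample ids in counts", class = "agesig_input_error")
  }
  m <- as.matrix(counts[samp])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(
      sprintf("non-integer or negative count at gene '%s', sample '%s'",
              counts$gene_id[bad[1, 1]], samp[bad[1, 2]]),
      class = "agesig_input_error"
    )
  }
  missing <- setdiff(samp, metadata$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples missing from metadata: ",
                 paste(missing, collapse = ", ")),
          class = "agesig_input_error")
  }
  metadata <- filter(metadata, .data$sample_id %in% samp)
  if (any(is.na(metadata$age_months))) {
    abort("every sample needs an age", class = "agesig_input_error")
  }
  if (length(unique(metadata$age_months)) < 2) {
    abort("need >= 2 distinct ages", class = "agesig_input_error")
  }
  structure(
    list(
      counts = counts,
      metadata = metadata,
      all_zero = counts$gene_id[rowSums(m) == 0]
    ),
    class = "count_matrix"
  )
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. Duplicate members within a set are dropped; duplicate
#' set names are an error. Members need not be present in any expression
#' universe at load time.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn("empty GMT file; returning an empty collection")
    return(setNames(list(), character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate set name in GMT: ", nm[duplicated(nm)][1]),
          class = "agesig_input_error")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  setNames(sets, nm)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column pair table (ortholog map or regulator interactions)
#'
#' For `kind = "ortholog"` only the first occurrence of each source gene is
#' kept (first-candidate reduction) and the number of dropped candidates is
#' reported. For `kind = "interaction"` exact duplicate pairs are dropped.
#'
#' @param path Two-column TSV with a header row.
#' @param kind `"ortholog"` or `"interaction"`.
#' @return A tibble with columns (`gene_a`, `gene_b`) or (`tf`, `target`).
#' @export
read_pairs <- function(path, kind = c("ortholog", "interaction")) {
  kind <- match.arg(kind)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tbl) < 2) {
    abort("pair table needs two columns", class = "agesig_input_error")
  }
  tbl <- tbl[, 1:2]
  bad <- which(is.na(tbl[[1]]) | is.na(tbl[[2]]) |
                 !nzchar(tbl[[1]]) | !nzchar(tbl[[2]]))
  if (length(bad) > 0) {
    abort(sprintf("malformed pair at line %d of %s", bad[1] + 1L, path),
          class = "agesig_input_error")
  }
  if (nrow(tbl) == 0) warn(paste0("no pairs in ", path))
  if (kind == "ortholog") {
    names(tbl) <- c("gene_a", "gene_b")
    keep <- !duplicated(tbl$gene_a)
    dropped <- sum(!keep)
    if (dropped > 0) {
      rlang::inform(sprintf("dropped %d non-first ortholog candidates", dropped))
    }
    out <- tbl[keep, ]
    attr(out, "dropped_candidates") <- dropped
    out
  } else {
    names(tbl) <- c("tf", "target")
    distinct(tbl)
  }
}

#' Write pipeline result tables and a run manifest
#'
#' Every table is written as TSV with its in-memory column order; list
#' columns are collapsed to comma-separated strings. The JSON manifest
#' records a configuration hash, the seed, package version, per-table row
#' counts and a timestamp.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param config Optional configuration object hashed into the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory ", out_dir),
          class = "agesig_io_error")
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    is_list <- vapply(tbl, is.list, logical(1))
    for (cc in names(tbl)[is_list]) {
      tbl[[cc]] <- vapply(tbl[[cc]], function(v) paste(v, collapse = ","),
                          character(1))
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tbl, p)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "agesig",
    version = as.character(utils::packageVersion("agesig")),
    config_hash = rlang::hash(config),
    seed = seed,
    row_counts = lapply(tables, nrow),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a simulated study to disk as plain-text artifacts
#'
#' Materialises a [sim_study()] object the way a real dataset would arrive:
#' per-species counts and truth TSVs, a combined metadata TSV, per-species
#' GMT gene sets and interaction TSVs, whitelists, the pathway-to-system
#' mapping and the ortholog map.
#'
#' @param study An `aging_study` from [sim_study()].
#' @param out_dir Output directory.
#' @return Invisibly, a named list of written paths.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "aging_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (sp in names(study$counts)) {
    p <- file.path(out_dir, paste0("counts_", sp, ".tsv"))
    readr::write_tsv(study$counts[[sp]], p)
    paths[[paste0("counts_", sp)]] <- p
    p <- file.path(out_dir, paste0("truth_", sp, ".tsv"))
    readr::write_tsv(study$truth[[sp]], p)
    paths[[paste0("truth_", sp)]] <- p
    p <- file.path(out_dir, paste0("gene_sets_", sp, ".gmt"))
    write_gmt(study$gene_sets[[sp]], p)
    paths[[paste0("gene_sets_", sp)]] <- p
    p <- file.path(out_dir, paste0("interactions_", sp, ".tsv"))
    readr::write_tsv(study$interactions[[sp]], p)
    paths[[paste0("interactions_", sp)]] <- p
    p <- file.path(out_dir, paste0("tf_whitelist_", sp, ".txt"))
    writeLines(study$whitelist[[sp]], p)
    paths[[paste0("tf_whitelist_", sp)]] <- p
  }
  readr::write_tsv(study$metadata, file.path(out_dir, "metadata.tsv"))
  readr::write_tsv(study$orthologs, file.path(out_dir, "orthologs.tsv"))
  readr::write_tsv(study$systems, file.path(out_dir, "pathway_systems.tsv"))
  paths$metadata <- file.path(out_dir, "metadata.tsv")
  paths$orthologs <- file.path(out_dir, "orthologs.tsv")
  paths$systems <- file.path(out_dir, "pathway_systems.tsv")
  invisible(paths)
}
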