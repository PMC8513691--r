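#' Read a feature (ASV) count table from TSV
#'
#' The canonical on-disk layout is features-as-rows with the first header
#' cell equal to `"#feature_id"`. Tables written by denoising tools that
#' export samples-as-rows (no `#feature_id` token) are detected and
#' transposed on read, so the in-memory orientation is always
#' features x samples.
#'
#' @param path Path to a tab-separated file. First column holds feature
#'   identifiers, remaining columns hold integer read counts per sample.
#' @return An integer matrix (features x samples) with feature ids as row
#'   names and sample ids as column names, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_feature_table(matrix(c(3L, 1L, 0L, 5L), 2,
#'   dimnames = list(c("ASV1", "ASV2"), c("S1", "S2"))), f)
#' read_feature_table(f)
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("feature table file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("feature table must have a header and at least one row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    abort(paste0(
      "feature table row ", which(widths != length(header))[1] + 1L,
      " has ", widths[widths != length(header)][1],
      " fields, expected ", length(header)
    ))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  col_ids <- header[-1]
  .check_dup(row_ids, "feature/sample id")
  .check_dup(col_ids, "feature/sample id")
  cells <- do.call(rbind, lapply(body, `[`, -1L))
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "non-integer or negative count at row ", bad[1, 1] + 1L,
      " column ", bad[1, 2] + 1L, " ('", cells[bad[1, 1], bad[1, 2]], "')"
    ))
  }
  counts <- matrix(as.integer(num), nrow = nrow(num),
                   dimnames = list(row_ids, col_ids))
  if (!identical(header[1], "#feature_id")) {
    # samples-as-rows dialect
    counts <- t(counts)
  }
  validate_feature_table(counts)
}

.check_dup <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d) > 0) {
    abort(paste0("duplicate ", what, ": '", d[1], "'"))
  }
  if (any(!nzchar(ids))) abort(paste0("empty ", what))
  invisible(ids)
}

#' Validate a feature table matrix
#'
#' Checks the feature-table invariants: named integer matrix, unique ids,
#' all counts finite integers >= 0.
#'
#' @param counts A features x samples matrix.
#' @return The validated integer matrix, invisibly unchanged.
#' @export
validate_feature_table <- function(counts) {
  if (!is.matrix(counts)) abort("feature table must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("feature table must have feature ids as rownames and sample ids as colnames")
  }
  .check_dup(rownames(counts), "feature id")
  .check_dup(colnames(counts), "sample id")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("feature table counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Write a feature table to TSV
#'
#' Writes the canonical features-as-rows layout with a `#feature_id`
#' header token, tab separators, UTF-8 and LF line endings, so that
#' `read_feature_table(write_feature_table(x, f))` round-trips exactly.
#'
#' @param counts Features x samples integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(counts, path) {
  counts <- validate_feature_table(counts)
  header <- paste(c("#feature_id", colnames(counts)), collapse = "\t")
  rows <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(rownames(counts)[i], counts[i, ]), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `sample_type`. Optional columns:
#' `core_category`, `depth_m`, `temperature_C`, `is_control`. Missing depth
#' and temperature are kept as `NA`; downstream operations declare their
#' own exclusion rules.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A tibble with columns `sample_id`, `sample_type`,
#'   `core_category`, `depth_m`, `temperature_C`, `is_control`.
#' @export
read_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "sample_type")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  md <- tibble(
    sample_id = raw$sample_id,
    sample_type = raw$sample_type,
    core_category = if ("core_category" %in% names(raw)) raw$core_category else NA_character_,
    depth_m = if ("depth_m" %in% names(raw)) suppressWarnings(as.numeric(raw$depth_m)) else NA_real_,
    temperature_C = if ("temperature_C" %in% names(raw)) suppressWarnings(as.numeric(raw$temperature_C)) else NA_real_,
    is_control = if ("is_control" %in% names(raw)) tolower(raw$is_control) %in% c("true", "t", "1", "yes") else NA
  )
  md$core_category[is.na(md$core_category) | md$core_category == ""] <- "none"
  if (anyNA(md$is_control)) {
    md$is_control <- md$sample_type == "negative_control"
  }
  validate_metadata(md)
}

#' Validate sample metadata
#'
#' Enforces the metadata invariants: known `sample_type` values, unique
#' sample ids, `core_category` only on drill cores, `is_control` true
#' exactly for negative controls, non-negative depths.
#'
#' @param md A metadata data frame.
#' @return The validated metadata tibble.
#' @export
validate_metadata <- function(md) {
  md <- as_tibble(md)
  .check_dup(md$sample_id, "sample id")
  bad_type <- setdiff(unique(md$sample_type), SAMPLE_TYPES)
  if (length(bad_type) > 0) {
    abort(paste0(
      "unknown sample_type '", bad_type[1], "'; allowed values: ",
      paste(SAMPLE_TYPES, collapse = ", ")
    ))
  }
  bad_cat <- setdiff(unique(md$core_category), CORE_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort(paste0("unknown core_category '", bad_cat[1], "'; allowed values: ",
                 paste(CORE_CATEGORIES, collapse = ", ")))
  }
  offender <- md$sample_id[md$core_category != "none" & md$sample_type != "drill_core"]
  if (length(offender) > 0) {
    abort(paste0("core_category set on non-drill-core sample '", offender[1], "'"))
  }
  mismatch <- md$sample_id[md$is_control != (md$sample_type == "negative_control")]
  if (length(mismatch) > 0) {
    abort(paste0("is_control must be true exactly for negative_control samples; see '",
                 mismatch[1], "'"))
  }
  if (any(md$depth_m < 0, na.rm = TRUE)) abort("depth_m must be >= 0")
  md
}

#' Write sample metadata to TSV
#' @param md Metadata tibble as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  md <- validate_metadata(md)
  readr::write_tsv(md, path, progress = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' Two dialects are supported: `seven_column` (feature id followed by seven
#' rank columns kingdom..species) and `lineage_string` (feature id plus one
#' column of `;`-separated names, optionally with `k__`-style rank
#' prefixes). `"auto"` picks by column count. Missing names (`NA`, empty,
#' `unclassified`, `Unknown`) and absent trailing ranks map to the
#' `UNASSIGNED` sentinel.
#'
#' @param path Path to a tab-separated taxonomy file (no header required;
#'   a header row whose first cell is `feature_id` or `#feature_id` is
#'   skipped).
#' @param dialect One of `"auto"`, `"seven_column"`, `"lineage_string"`.
#' @return A tibble with columns `feature_id`, `kingdom` .. `species`.
#' @export
read_taxonomy <- function(path, dialect = c("auto", "seven_column", "lineage_string")) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0 && fields[[1]][1] %in% c("feature_id", "#feature_id")) {
    fields <- fields[-1]
  }
  if (length(fields) == 0) abort("taxonomy file has no records")
  ncols <- lengths(fields)
  if (dialect == "auto") {
    dialect <- if (max(ncols) >= 8) "seven_column" else "lineage_string"
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (any(!nzchar(trimws(ids)))) abort("empty feature id in taxonomy file")
  .check_dup(ids, "feature id")
  parse_one <- function(f) {
    if (dialect == "seven_column") {
      ranks <- f[-1]
      if (length(ranks) > 7) abort("taxonomy row has more than 7 rank columns")
      ranks <- c(ranks, rep(NA_character_, 7 - length(ranks)))
    } else {
      lineage <- if (length(f) >= 2) f[[2]] else ""
      segs <- strsplit(lineage, ";", fixed = TRUE)[[1]]
      if (length(segs) > 7) {
        abort(paste0("lineage for '", f[[1]], "' has ", length(segs),
                     " segments; at most 7 allowed"))
      }
      ranks <- c(segs, rep(NA_character_, 7 - length(segs)))
    }
    vapply(ranks, .clean_rank_name, character(1), USE.NAMES = FALSE)
  }
  mat <- do.call(rbind, lapply(fields, parse_one))
  colnames(mat) <- TAX_RANKS
  dplyr::bind_cols(tibble(feature_id = ids), as_tibble(mat))
}

# strip "k__"-style prefixes and whitespace; map missing-name spellings to
# the single UNASSIGNED sentinel so taxonomy screening is deterministic
.clean_rank_name <- function(x) {
  if (is.na(x)) return(UNASSIGNED)
  x <- trimws(sub("^[a-zA-Z]__", "", trimws(x)))
  if (!nzchar(x) || tolower(x) %in% c("na", "unclassified", "unknown", "unassigned")) {
    return(UNASSIGNED)
  }
  x
}

#' Write a taxonomy table to TSV (seven-column dialect)
#' @param taxonomy Tibble as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(all(c("feature_id", TAX_RANKS) %in% names(taxonomy)))
  readr::write_tsv(taxonomy[, c("feature_id", TAX_RANKS)], path, progress = FALSE)
  invisible(path)
}

#' Assemble a validated dataset from table, metadata and taxonomy
#'
#' Samples missing from the metadata are dropped with a warning; features
#' missing from the taxonomy receive all-`UNASSIGNED` records. The result
#' satisfies the dataset invariants (every sample annotated, every feature
#' classified) and `harmonize()` is idempotent.
#'
#' @param counts Features x samples integer matrix.
#' @param metadata Metadata tibble ([read_metadata()]).
#' @param taxonomy Taxonomy tibble ([read_taxonomy()]), or `NULL`.
#' @return A `tephra_dataset`: list with elements `counts` (matrix),
#'   `metadata` (tibble, one row per retained sample, in table order) and
#'   `taxonomy` (tibble, one row per feature, in table order).
#' @export
harmonize <- function(counts, metadata, taxonomy = NULL) {
  counts <- validate_feature_table(counts)
  metadata <- validate_metadata(metadata)
  keep <- colnames(counts) %in% metadata$sample_id
  if (!all(keep)) {
    warn(paste0("dropping ", sum(!keep), " sample(s) without metadata: ",
                paste(head(colnames(counts)[!keep], 5), collapse = ", ")))
    counts <- counts[, keep, drop = FALSE]
  }
  if (ncol(counts) == 0) abort("no annotated samples")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  if (is.null(taxonomy)) {
    taxonomy <- tibble(feature_id = character(0))
  }
  taxonomy <- as_tibble(taxonomy)
  for (r in TAX_RANKS) {
    if (!r %in% names(taxonomy)) taxonomy[[r]] <- UNASSIGNED
  }
  missing_tax <- setdiff(rownames(counts), taxonomy$feature_id)
  if (length(missing_tax) > 0) {
    fill <- tibble(feature_id = missing_tax)
    for (r in TAX_RANKS) fill[[r]] <- UNASSIGNED
    taxonomy <- dplyr::bind_rows(taxonomy, fill)
  }
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$feature_id),
                       c("feature_id", TAX_RANKS)]
  structure(
    list(counts = counts, metadata = metadata, taxonomy = taxonomy),
    class = "tephra_dataset"
  )
}

#' @export
print.tephra_dataset <- function(x, ...) {
  cat("<tephra_dataset> ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("sample types:",
      paste(sprintf("%s (%d)", names(table(x$metadata$sample_type)),
                    table(x$metadata$sample_type)), collapse = ", "), "\n")
  invisible(x)
}
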